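# SVD decomposition, rank selection, reconstruction, readouts.

test_that("singular values of simple matrices are exact", {
  r1 <- decomposeWaveform(diag(c(3, 2)))
  expect_equal(singularValues(r1), c(3, 2), tolerance = 1e-12)
  r2 <- decomposeWaveform(matrix(1, 2, 2))
  expect_equal(singularValues(r2), c(2, 0), tolerance = 1e-12)
})

test_that("singular values agree with an independent eigensolver of A^T A", {
  set.seed(101)
  a <- matrix(rnorm(30), 6, 5)
  got <- singularValues(decomposeWaveform(a))
  want <- sqrt(pmax(eigen(crossprod(a), symmetric = TRUE, only.values = TRUE)$values, 0))
  expect_equal(got, want, tolerance = 1e-10)
  # all shapes up to 10 x 10
  for (m in 2:10) for (n in 2:10) {
    a <- matrix(rnorm(m * n), m, n)
    got <- singularValues(decomposeWaveform(a))
    want <- sqrt(pmax(eigen(crossprod(a), symmetric = TRUE,
                            only.values = TRUE)$values, 0))[seq_len(min(m, n))]
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("factors are orthonormal and reproduce the input on every decomposition", {
  set.seed(7)
  shapes <- list(c(10, 6), c(6, 10), c(100, 60), c(5, 5))
  for (sh in shapes) {
    a <- matrix(abs(rnorm(prod(sh))), sh[1], sh[2])
    r <- decomposeWaveform(a)
    u <- leftVectors(r); v <- rightVectors(r)
    expect_lt(max(abs(crossprod(u) - diag(sh[1]))), 1e-8)
    expect_lt(max(abs(crossprod(v) - diag(sh[2]))), 1e-8)
    full <- reconstructWaveform(r, min(sh))
    expect_lt(norm(full - a, "F") / norm(a, "F"), 1e-8)
  }
  expect_error(decomposeWaveform(matrix(c(1, NA), 1, 2)), "finite")
})

test_that("sign convention puts the largest-magnitude spatial element positive", {
  set.seed(13)
  a <- matrix(rnorm(48), 8, 6)
  u <- leftVectors(decomposeWaveform(a))
  for (i in seq_len(ncol(u)))
    expect_gt(u[which.max(abs(u[, i])), i], 0)
})

test_that("lag-1 autocorrelation matches its hand-computed and sampling values", {
  expect_equal(lag1Autocorrelation(c(1, 2, 3, 4, 5)), 0.4, tolerance = 1e-12)
  set.seed(31)
  x <- rnorm(40)
  expect_equal(lag1Autocorrelation(3 * x - 7), lag1Autocorrelation(x),
               tolerance = 1e-12)
  set.seed(32)
  expect_lt(abs(lag1Autocorrelation(rnorm(1e4))), 0.05)
  expect_error(lag1Autocorrelation(c(1, 2)), "at least 3")
  expect_error(lag1Autocorrelation(rep(1, 10)), "zero-variance")
})

test_that("rank selection keeps structured components and rejects noise", {
  # noiseless single compartment
  r1 <- selectRank(decomposeWaveform(simulateWaveform(onePlateauScenario())))
  expect_identical(selectedRank(r1), 1L)
  # pure-noise null fixture
  set.seed(42)
  rn <- selectRank(decomposeWaveform(matrix(abs(rnorm(6000)), 100, 60)))
  expect_identical(selectedRank(rn), 0L)
  # default healthy scenario at its default noise level
  rh <- selectRank(decomposeWaveform(simulateWaveform(defaultScenario("healthy-S1"))))
  expect_identical(selectedRank(rh), 3L)
  # manual override
  ro <- selectRank(decomposeWaveform(diag(4)), rank = 2)
  expect_identical(selectedRank(ro), 2L)
  expect_error(selectRank(decomposeWaveform(diag(4)), rank = 9), "out of range")
})

test_that("rank selection recovers the generating rank of noiseless scenarios", {
  for (k in 1:4) {
    r <- selectRank(decomposeWaveform(simulateWaveform(rankScenario(k))))
    expect_identical(selectedRank(r), as.integer(k), label = paste("k =", k))
  }
})

test_that("truncated reconstruction obeys Eckart-Young exactly", {
  set.seed(55)
  a <- matrix(rnorm(48), 8, 6)
  r <- decomposeWaveform(a)
  d <- singularValues(r)
  expect_equal(norm(reconstructWaveform(r, 2) - a, "F"),
               sqrt(sum(d[3:6]^2)), tolerance = 1e-8)
  expect_equal(reconstructWaveform(r, 0), matrix(0, 8, 6))
  expect_lt(norm(reconstructWaveform(r, 6) - a, "F") / norm(a, "F"), 1e-8)
  expect_error(reconstructWaveform(r, 7), "out of range")
  expect_error(reconstructWaveform(r, -1), "out of range")

  for (seed in 1:20) {
    set.seed(seed)
    m <- sample(4:12, 1); n <- sample(4:12, 1)
    a <- matrix(rnorm(m * n), m, n)
    r <- decomposeWaveform(a)
    d <- singularValues(r)
    for (k in c(1, min(m, n) %/% 2)) {
      tail2 <- sum(d[seq_along(d) > k]^2)
      expect_equal(norm(reconstructWaveform(r, k) - a, "F"), sqrt(tail2),
                   tolerance = 1e-8)
    }
  }
})

test_that("component readouts sum back to the truncated reconstruction", {
  w <- simulateWaveform(defaultScenario("healthy-S1"))
  r <- selectRank(decomposeWaveform(w))
  ro <- componentReadouts(r)
  acc <- matrix(0, nrow(ro$spatial), nrow(ro$kinetic))
  for (i in seq_along(ro$component))
    acc <- acc + outer(ro$spatial[, i], ro$kinetic[, i])
  expect_equal(acc, reconstructWaveform(r, selectedRank(r)), tolerance = 1e-8)
})

test_that("permuting time columns permutes kinetic amplitudes, not spatial shapes", {
  w <- simulateWaveform(rankScenario(2))
  a <- intensityMatrix(w)
  perm <- rev(seq_len(ncol(a)))
  r1 <- selectRank(decomposeWaveform(a))
  r2 <- selectRank(decomposeWaveform(a[, perm]))
  ro1 <- componentReadouts(r1); ro2 <- componentReadouts(r2)
  for (i in seq_along(ro1$component)) {
    expect_equal(abs(ro1$spatial[, i]), abs(ro2$spatial[, i]), tolerance = 1e-8)
    expect_equal(abs(ro1$kinetic[perm, i]), abs(ro2$kinetic[, i]), tolerance = 1e-8)
  }
})

test_that("spatial shapes recover the generating compartment profiles", {
  for (k in 2:4) {
    sc <- rankScenario(k)
    w <- simulateWaveform(sc)
    r <- selectRank(decomposeWaveform(w))
    m <- matchComponents(r, generatingProfiles(sc, positionBins(w)))
    expect_true(all(!is.na(m$component)))
    expect_true(all(m$absCorrelation >= 0.9), label = paste("k =", k))
  }
})

test_that("cathepsin inhibition abolishes the lysosome-matched component", {
  ctrl <- defaultScenario("healthy-S1")
  e64 <- defaultScenario("e64-inhibited")  # same seed as control
  energyLys <- function(sc) {
    w <- simulateWaveform(sc)
    r <- selectRank(decomposeWaveform(w))
    G <- generatingProfiles(defaultScenario("healthy-S1"), positionBins(w))
    m <- matchComponents(r, G)
    m$energy[m$compartment == "LYS"]
  }
  expect_lt(energyLys(e64), 0.1 * energyLys(ctrl))
})

test_that("retained shapes are stable across independently seeded replicates", {
  shapes <- lapply(1:3, function(s) {
    r <- selectRank(decomposeWaveform(simulateWaveform(
      defaultScenario("healthy-S1", seed = s))))
    componentReadouts(r)$spatial
  })
  for (i in 1:2) for (j in (i + 1):3) {
    cc <- abs(stats::cor(shapes[[i]], shapes[[j]]))
    # greedy pairwise matching: every shape finds a replicate partner
    expect_true(all(apply(cc, 1, max) >= 0.8))
    expect_true(all(apply(cc, 2, max) >= 0.8))
  }
})
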