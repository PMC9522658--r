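# Onset/delay detection, ROI ordering, uptake length, dispersion metrics.

# zero baseline for three frames, then a linear ramp 0 -> 1 over [2, 22]
rampSeries <- function() TubuleTimeSeries("S1", 0:22, pmax(0:22 - 2, 0) / 20)

test_that("onset time interpolates threshold crossings on a linear ramp", {
  expect_equal(onsetTime(rampSeries(), 0.5), 12, tolerance = 1e-12)   # 2 + 10
  expect_equal(onsetTime(rampSeries(), 0.25), 7, tolerance = 1e-12)   # 2 + 5
  # a sampled step: the crossing lies within one sample interval of the jump
  stepS <- TubuleTimeSeries("S1", 0:20, as.numeric(0:20 >= 10))
  expect_lt(abs(onsetTime(stepS, 0.5) - 10), 1)
  expect_error(onsetTime(TubuleTimeSeries("S1", 0:10, rep(1, 11))), "flat")
  expect_error(onsetTime(rampSeries(), fraction = 1.5), "fraction")
})

test_that("onset delay is zero for identical series and shift-equivariant", {
  a <- rampSeries()
  expect_equal(delayBetween(a, a), 0)
  b <- TubuleTimeSeries("S2", 0:22 + 5, seriesIntensities(a))
  expect_equal(delayBetween(a, b), 5, tolerance = 1e-12)
})

test_that("simulated S2 and DT onsets lag S1 degradation by the transport lags", {
  sc <- defaultScenario("healthy-S1")
  ctrl <- simulateTubuleSeries(sc)
  inh <- simulateTubuleSeries(defaultScenario("e64-inhibited"))
  deg <- TubuleTimeSeries("S1_degradation", seriesTimes(ctrl$S1),
    seriesIntensities(ctrl$S1) - seriesIntensities(inh$S1))
  step <- diff(seriesTimes(ctrl$S1))[1]
  expect_lt(abs(delayBetween(deg, ctrl$S2) - sc@transportLagS2), step)
  expect_lt(abs(delayBetween(deg, ctrl$DT_lumen) - sc@transportLagDT), step)
})

test_that("ROI ordering is a stable descending sort on the reference channel", {
  ax <- orderRois(c(5, 9, 1), c(10, 20, 30))
  expect_equal(ax@referenceIntensity, c(9, 5, 1))
  expect_equal(ax@signalIntensity, c(20, 10, 30))
  expect_equal(ax@rank, 1:3)

  ties <- orderRois(c(2, 2, 2), c(1, 2, 3), roiIds = c("a", "b", "c"))
  expect_equal(ties@roiIds, c("a", "b", "c"))
  expect_equal(ties@signalIntensity, c(1, 2, 3))

  set.seed(17)
  ref <- rnorm(200); sig <- rnorm(200)
  ax2 <- orderRois(ref, sig)
  ord <- sort(ref, decreasing = TRUE)  # independent sort oracle
  expect_equal(ax2@referenceIntensity, ord)
  expect_equal(ax2@signalIntensity, sig[match(ord, ref)])
  expect_error(orderRois(1:3, 1:2), "lengths differ")
})

test_that("uptake length counts ROIs above the threshold fraction of max", {
  ax <- orderRois(c(10, 9, 1, 0.5), c(10, 9, 1, 0.5))
  expect_equal(uptakeLength(ax, 0.5), 2)
  flat <- orderRois(rep(3, 7), rep(3, 7))
  expect_equal(uptakeLength(flat, 0.25), 7)
  zero <- orderRois(rep(0, 4), rep(0, 4))
  expect_error(uptakeLength(zero), "no positive signal")
})

test_that("intracellular dispersion is the population SD, sensitive to condensation", {
  expect_equal(intracellularDispersion(rep(2, 10)), 0)
  expect_equal(intracellularDispersion(c(0, 0, 0, 1)), sqrt(3) / 4,
               tolerance = 1e-12)
  # condensed vs diffuse ROI of equal total intensity
  condensed <- c(rep(10, 10), rep(0, 90))
  diffuse <- rep(1, 100)
  expect_gt(intracellularDispersion(condensed),
            intracellularDispersion(diffuse))
  expect_error(intracellularDispersion(3), "at least 2")
})

test_that("axial dispersion correlation matches the covariance formula", {
  expect_equal(abs(axialDispersionCorrelation(1:10, 10:1)), 1, tolerance = 1e-12)
  set.seed(23)
  disp <- sample(rnorm(1000))
  expect_lt(abs(axialDispersionCorrelation(1:1000, disp)), 0.1)
  rank <- 1:30
  noisy <- 5 - 0.1 * rank + rnorm(30, 0, 0.2)
  oracle <- sum((rank - mean(rank)) * (noisy - mean(noisy))) /
    sqrt(sum((rank - mean(rank))^2) * sum((noisy - mean(noisy))^2))
  expect_equal(axialDispersionCorrelation(
    data.frame(axial_rank = rank, dispersion = noisy)), oracle,
    tolerance = 1e-12)
  expect_error(axialDispersionCorrelation(1:2, 1:2), "at least 3")
  expect_error(axialDispersionCorrelation(1:5, rep(1, 5)), "zero variance")
})

test_that("metrics are scale-invariant except dispersion, which scales linearly", {
  a <- rampSeries()
  a10 <- TubuleTimeSeries("S1", seriesTimes(a), 10 * seriesIntensities(a))
  expect_equal(onsetTime(a10, 0.5), onsetTime(a, 0.5), tolerance = 1e-12)
  ax <- orderRois(c(4, 3, 1), c(4, 3, 1))
  ax10 <- orderRois(10 * c(4, 3, 1), 10 * c(4, 3, 1))
  expect_equal(uptakeLength(ax10), uptakeLength(ax))
  x <- c(1, 5, 2, 8)
  expect_equal(intracellularDispersion(10 * x), 10 * intracellularDispersion(x),
               tolerance = 1e-12)
})

test_that("reduced-uptake scenarios show the axial compensation signature", {
  wt <- defaultScenario("healthy-S1")
  ko <- defaultScenario("OCRL-like")  # same seed
  # S1 uptake amplitude scales with uptakeScale
  s1wt <- max(seriesIntensities(simulateTubuleSeries(wt)$S1))
  s1ko <- max(seriesIntensities(simulateTubuleSeries(ko)$S1))
  expect_equal(s1ko / s1wt, ko@uptakeScale, tolerance = 0.02)
  # uptake length extends distally
  axw <- simulateAxialProfile(wt); axk <- simulateAxialProfile(ko)
  ulw <- uptakeLength(orderRois(axw$reference_intensity, axw$signal_intensity))
  ulk <- uptakeLength(orderRois(axk$reference_intensity, axk$signal_intensity))
  expect_gt(ulk, ulw)
  # flattened dispersion gradient loses the axial linear correlation
  rw <- axialDispersionCorrelation(seq_len(nrow(axw)), axw$dispersion)
  rk <- axialDispersionCorrelation(seq_len(nrow(axk)), axk$dispersion)
  expect_gt(abs(rw), abs(rk))
})
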