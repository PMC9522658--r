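# Forward simulator: unquenching physics, compartment kinetics, waveform
# and tubule-series generation.

test_that("unquenching gain follows q^(1-n) and its limiting cases", {
  expect_identical(unquenchGain(LabelingSpec(nLabels = 1, quenchQ = 0.6)), 1)
  expect_identical(unquenchGain(LabelingSpec(nLabels = 4, quenchQ = 1)), 1)
  expect_equal(unquenchGain(LabelingSpec(nLabels = 4, quenchQ = 0.6)),
               0.6^-3, tolerance = 1e-12)
})

test_that("unquenching gain strictly increases with labeling density for q < 1", {
  for (q in c(0.3, 0.6, 0.9)) {
    gains <- vapply(1:8, function(n) unquenchGain(LabelingSpec(n, q)), numeric(1))
    expect_true(all(diff(gains) > 0), info = paste("q =", q))
  }
})

test_that("compartment time course obeys causality and its closed form", {
  spec0 <- CompartmentSpec("C", 0.5, 0.1,
    list(KineticPhase(onset = 10, riseTau = 2, decayTau = Inf, amplitude = 0)))
  expect_equal(compartmentTimeCourse(spec0, 0:30), rep(0, 31))

  spec <- CompartmentSpec("C", 0.5, 0.1,
    list(KineticPhase(onset = 10, riseTau = 2, decayTau = Inf, amplitude = 1)))
  expect_equal(compartmentTimeCourse(spec, c(0, 3, 6, 9)), rep(0, 4))
  y <- compartmentTimeCourse(spec, c(0, 12))
  expect_equal(y[2], 1 - exp(-1), tolerance = 1e-12)

  expect_error(compartmentTimeCourse(spec, c(5, 5, 6)), "increasing")
  expect_error(compartmentTimeCourse(spec, numeric(0)), "non-empty")
})

test_that("unquenching-gated phases scale with gain and vanish under inhibition", {
  spec <- CompartmentSpec("LYS", 0.45, 0.07,
    list(KineticPhase(onset = 0, riseTau = 1, decayTau = Inf, amplitude = 1,
                      gatedByUnquenching = TRUE)))
  lab <- LabelingSpec(nLabels = 4, quenchQ = 0.6)
  y <- compartmentTimeCourse(spec, c(1, 50), labeling = lab)
  y1 <- compartmentTimeCourse(spec, c(1, 50), labeling = LabelingSpec(1, 0.6))
  expect_equal(y / y1, rep(0.6^-3, 2), tolerance = 1e-12)
  yi <- compartmentTimeCourse(spec, c(1, 50), labeling = lab,
                              cathepsinInhibited = TRUE)
  expect_equal(yi, c(0, 0))
})

test_that("noiseless one-compartment waveform is an exact outer product", {
  w <- simulateWaveform(onePlateauScenario())
  a <- intensityMatrix(w)
  d <- svd(a)$d
  expect_gt(d[1], 0)
  expect_lt(d[2] / d[1], 1e-12)
})

test_that("waveform simulation is deterministic for a fixed scenario seed", {
  sc <- defaultScenario("healthy-S1", seed = 11L)
  expect_identical(intensityMatrix(simulateWaveform(sc)),
                   intensityMatrix(simulateWaveform(sc)))
  p1 <- simulateProfiles(sc, samplesPerProfile = 40L)
  p2 <- simulateProfiles(sc, samplesPerProfile = 40L)
  expect_identical(p1, p2)
})

test_that("noiseless waveforms are additive over compartments", {
  sc <- defaultScenario("healthy-S1"); sc@noiseSigma <- 0
  parts <- lapply(sc@compartments, function(cp) {
    s1 <- sc; s1@compartments <- list(cp)
    intensityMatrix(simulateWaveform(s1))
  })
  expect_equal(Reduce(`+`, parts), intensityMatrix(simulateWaveform(sc)),
               tolerance = 1e-12)
})

test_that("noiseless numerical rank equals the number of distinct compartments", {
  # oracle: eigenvalues of A^T A from an independent eigensolver
  for (k in 1:4) {
    sc <- rankScenario(k)
    a <- intensityMatrix(simulateWaveform(sc))
    ev <- eigen(crossprod(a), symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sum(ev > max(ev) * 1e-12), k, info = paste("k =", k))
  }
  sc <- defaultScenario("healthy-S1"); sc@noiseSigma <- 0
  a <- intensityMatrix(simulateWaveform(sc))
  ev <- eigen(crossprod(a), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(ev > max(ev) * 1e-12), 3)
})

test_that("cathepsin inhibition removes all lysosome energy from the waveform", {
  sc <- defaultScenario("e64-inhibited"); sc@noiseSigma <- 0
  noLys <- sc
  noLys@compartments <- Filter(function(cp) cp@name != "LYS", sc@compartments)
  expect_equal(intensityMatrix(simulateWaveform(sc)),
               intensityMatrix(simulateWaveform(noLys)), tolerance = 1e-12)
})

test_that("tubule series: zero uptake silences every downstream signal", {
  sc <- defaultScenario("healthy-S1"); sc@uptakeScale <- 0
  s <- simulateTubuleSeries(sc)
  for (seg in c("S1", "S2", "DT_lumen"))
    expect_equal(seriesIntensities(s[[seg]]), rep(0, sc@nTimepoints))
})

test_that("tubule series: cathepsin inhibition suppresses S2 and DT by > 90%", {
  ctrl <- simulateTubuleSeries(defaultScenario("healthy-S1"))
  inh <- simulateTubuleSeries(defaultScenario("e64-inhibited"))
  expect_lt(max(seriesIntensities(inh$S2)), 0.1 * max(seriesIntensities(ctrl$S2)))
  expect_lt(max(seriesIntensities(inh$DT_lumen)),
            0.1 * max(seriesIntensities(ctrl$DT_lumen)))
})

test_that("S1 degradation onset reads back the configured delay", {
  sc <- defaultScenario("healthy-S1")
  ctrl <- simulateTubuleSeries(sc)
  inh <- simulateTubuleSeries(defaultScenario("e64-inhibited"))
  deg <- TubuleTimeSeries("S1_degradation", seriesTimes(ctrl$S1),
    seriesIntensities(ctrl$S1) - seriesIntensities(inh$S1))
  step <- diff(seriesTimes(ctrl$S1))[1]
  expect_lt(abs(onsetTime(deg, 0.5) - sc@degradationDelay), step)
})

test_that("axial profiles redistribute uptake distally when uptake is reduced", {
  wt <- simulateAxialProfile(defaultScenario("healthy-S1"))
  ko <- simulateAxialProfile(defaultScenario("OCRL-like"))
  expect_true(all(wt$reference_intensity >= 0))
  expect_gt(max(wt$reference_intensity), max(ko$reference_intensity))
  # the KO profile decays more slowly along the axis
  expect_gt(ko$reference_intensity[10] / ko$reference_intensity[1],
            wt$reference_intensity[10] / wt$reference_intensity[1])
})

test_that("scenario JSON round-trips and rejects unknown keys", {
  sc <- defaultScenario("OCRL-like", seed = 9L)
  path <- withr::local_tempfile(fileext = ".json")
  writeScenario(sc, path)
  back <- readScenario(path)
  expect_equal(back@uptakeScale, 0.45)
  expect_equal(back@seed, 9L)
  expect_identical(intensityMatrix(simulateWaveform(back)),
                   intensityMatrix(simulateWaveform(sc)))

  txt <- jsonlite::read_json(path)
  txt$not_a_field <- 1
  jsonlite::write_json(txt, path, auto_unbox = TRUE)
  expect_error(readScenario(path), "unknown key")
})

test_that("invalid specifications are rejected by validity checks", {
  expect_error(KineticPhase(riseTau = -1), "riseTau")
  expect_error(CompartmentSpec("C", center = 1.5, width = 0.1,
    phases = list(KineticPhase())), "center")
  expect_error(LabelingSpec(nLabels = 0), "nLabels")
  expect_error(Scenario(compartments = list()), "compartment")
})
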