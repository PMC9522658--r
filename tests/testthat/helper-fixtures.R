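# Shared fixtures, all built in code.

# one-compartment scenario with a simple plateau phase
onePlateauScenario <- function(noiseSigma = 0, seed = 1L) {
  Scenario(name = "one-compartment",
    compartments = list(CompartmentSpec("C1", center = 0.4, width = 0.1,
      phases = list(KineticPhase(onset = 5, riseTau = 3, decayTau = Inf,
                                 amplitude = 1)))),
    noiseSigma = noiseSigma, seed = seed)
}

# generating spatial profiles of a scenario, evaluated on bin centres
generatingProfiles <- function(scenario, positions) {
  comps <- scenarioCompartments(scenario)
  G <- vapply(comps, function(cp) spatialProfile(cp, positions),
              numeric(length(positions)))
  colnames(G) <- vapply(comps, function(cp) cp@name, character(1))
  G
}

# smooth multi-frame waveform matrix in which every frame carries signal;
# used to inject isolated artifacts for QC tests
smoothDriftMatrix <- function(bins = 100L, frames = 40L) {
  x <- (seq_len(bins) - 0.5) / bins
  vals <- sapply(seq_len(frames), function(t)
    1 + 2 * exp(-(x - 0.3 - 0.002 * t)^2 / (2 * 0.1^2)))
  WaveformMatrix(vals, seq_len(frames))
}

# independent straightforward re-implementation of pooled mean binning
bruteForceBin <- function(positions, intensities, nBins) {
  centers <- (seq_len(nBins) - 0.5) / nBins
  out <- numeric(nBins)
  for (i in seq_len(nBins)) {
    lo <- (i - 1) / nBins; hi <- i / nBins
    inbin <- if (i < nBins) positions >= lo & positions < hi
             else positions >= lo & positions <= hi
    out[i] <- if (any(inbin)) mean(intensities[inbin]) else NA_real_
  }
  out
}
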