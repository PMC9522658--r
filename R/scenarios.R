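# Named scenarios encoding the study conditions emulated by the simulator.

.defaultCompartments <- function() {
  list(
    CompartmentSpec("EE", center = 0.15, width = 0.08, phases = list(
      KineticPhase(onset = 0.5, riseTau = 1.5, decayTau = 4, amplitude = 7.0))),
    CompartmentSpec("LAV", center = 0.45, width = 0.18, phases = list(
      # early filling of large apical vacuoles by retrograde traffic from EEs
      KineticPhase(onset = 2, riseTau = 4, decayTau = 12, amplitude = 1.0),
      # late anterograde filling from lysosomes: visible only after unquenching
      KineticPhase(onset = 16, riseTau = 8, decayTau = Inf, amplitude = 0.18,
                   gatedByUnquenching = TRUE))),
    CompartmentSpec("LYS", center = 0.45, width = 0.07, phases = list(
      KineticPhase(onset = 10, riseTau = 2.5, decayTau = 6, amplitude = 1.1,
                   gatedByUnquenching = TRUE))))
}

#' Construct a simulation scenario
#'
#' @param name scenario label.
#' @param compartments list of \linkS4class{CompartmentSpec}; default: the
#'   three-compartment healthy-S1 geometry (EE, LAV, LYS).
#' @param labeling a \linkS4class{LabelingSpec}.
#' @param noiseSigma additive noise SD (default 0.1, about 1/30 of the peak
#'   signal of the default compartments).
#' @param noiseModel \code{"gaussian"} or \code{"poisson"}.
#' @param nProfiles,nTimepoints,duration sampling layout (50 ROIs, 60 frames
#'   over 60 min by default).
#' @param cathepsinInhibited,uptakeScale,eeTransitDelay perturbations.
#' @param degradationDelay,transportLagS2,transportLagDT timing constants of
#'   the whole-tubule model (min).
#' @param seed RNG seed.
#' @return A \linkS4class{Scenario}.
#' @export
Scenario <- function(name = "custom", compartments = .defaultCompartments(),
                     labeling = LabelingSpec(), noiseSigma = 0.1,
                     noiseModel = "gaussian", nProfiles = 50L,
                     nTimepoints = 60L, duration = 60,
                     cathepsinInhibited = FALSE, uptakeScale = 1,
                     eeTransitDelay = 0, degradationDelay = 10,
                     transportLagS2 = 3, transportLagDT = 5, seed = 1L) {
  new("Scenario", name = as.character(name), compartments = compartments,
      labeling = labeling, noiseSigma = as.numeric(noiseSigma),
      noiseModel = noiseModel, nProfiles = as.integer(nProfiles),
      nTimepoints = as.integer(nTimepoints), duration = as.numeric(duration),
      cathepsinInhibited = as.logical(cathepsinInhibited),
      uptakeScale = as.numeric(uptakeScale),
      eeTransitDelay = as.numeric(eeTransitDelay),
      degradationDelay = as.numeric(degradationDelay),
      transportLagS2 = as.numeric(transportLagS2),
      transportLagDT = as.numeric(transportLagDT), seed = as.integer(seed))
}

#' Named default scenarios
#'
#' Returns one of the study conditions the simulator emulates:
#' \describe{
#'   \item{healthy-S1}{three compartments (EE, LAV, LYS), intermediate
#'     labeling density (4 fluorophores, quench factor 0.6).}
#'   \item{e64-inhibited}{cathepsin inhibitor: lysosomal proteolysis
#'     disabled, all unquenching-gated phases zeroed.}
#'   \item{low-label}{1 fluorophore per protein: no self-quenching, so no
#'     unquenching gain on degradation.}
#'   \item{high-label}{6 fluorophores: strong quenching of the intact
#'     protein, large gain on degradation.}
#'   \item{OCRL-like}{endocytotic uptake reduced to 45\% of healthy.}
#'   \item{ClC-5-like}{5-min extra dwell in the early-endosome stage.}
#' }
#'
#' @param name one of the scenario names above.
#' @param seed RNG seed (default 1).
#' @return A \linkS4class{Scenario}.
#' @examples
#' sc <- defaultScenario("healthy-S1")
#' @export
defaultScenario <- function(name = c("healthy-S1", "e64-inhibited", "low-label",
                                     "high-label", "OCRL-like", "ClC-5-like"),
                            seed = 1L) {
  name <- match.arg(name)
  base <- Scenario(name = name, seed = seed)
  switch(name,
    "healthy-S1" = base,
    "e64-inhibited" = { base@cathepsinInhibited <- TRUE; base },
    "low-label" = { base@labeling <- LabelingSpec(nLabels = 1L); base },
    "high-label" = { base@labeling <- LabelingSpec(nLabels = 6L); base },
    "OCRL-like" = { base@uptakeScale <- 0.45; base },
    "ClC-5-like" = { base@eeTransitDelay <- 5; base })
}

#' Scenario of a given generating rank for recovery experiments
#'
#' Builds a scenario whose noiseless waveform has numerical rank exactly
#' \code{k}: \code{k} compartments with well-separated Gaussian footprints,
#' staggered non-overlapping kinetic pulses and strictly decreasing
#' amplitudes (distinct singular values, so the spatial base vectors are
#' well conditioned). Used for parameter-recovery tests of the
#' decomposition.
#'
#' @param k generating rank, 1 to 4.
#' @param noiseSigma noise SD (default 0, i.e. noiseless).
#' @param seed RNG seed.
#' @return A \linkS4class{Scenario} with \code{k} compartments.
#' @export
rankScenario <- function(k, noiseSigma = 0, seed = 1L) {
  stopifnot(k >= 1, k <= 4)
  centers <- c(0.12, 0.37, 0.62, 0.87)[seq_len(k)]
  amps <- c(1, 0.75, 0.55, 0.4)[seq_len(k)]
  comps <- lapply(seq_len(k), function(i) {
    CompartmentSpec(paste0("C", i), center = centers[i], width = 0.06,
      phases = list(KineticPhase(onset = 1 + 13 * (i - 1), riseTau = 1.5,
                                 decayTau = 4, amplitude = amps[i])))
  })
  Scenario(name = sprintf("rank-%d", k), compartments = comps,
           noiseSigma = noiseSigma, seed = seed)
}

#' Compartments of a scenario with perturbations applied
#'
#' Applies the scenario-level perturbations to its compartment list:
#' \code{eeTransitDelay} lengthens the EE decay and shifts the onsets of all
#' downstream (non-EE) phases, and \code{uptakeScale} multiplies every phase
#' amplitude (signal in every compartment is uptake-limited).
#'
#' @param scenario a \linkS4class{Scenario}.
#' @return List of adjusted \linkS4class{CompartmentSpec}.
#' @export
scenarioCompartments <- function(scenario) {
  lapply(scenario@compartments, function(cp) {
    cp@phases <- lapply(cp@phases, function(p) {
      if (scenario@eeTransitDelay > 0) {
        if (identical(cp@name, "EE")) {
          if (is.finite(p@decayTau)) p@decayTau <- p@decayTau + scenario@eeTransitDelay
        } else {
          p@onset <- p@onset + scenario@eeTransitDelay
        }
      }
      p@amplitude <- p@amplitude * scenario@uptakeScale
      p
    })
    cp
  })
}

.scenarioToList <- function(sc) {
  list(
    name = sc@name,
    compartments = lapply(sc@compartments, function(cp) list(
      name = cp@name, center = cp@center, width = cp@width,
      phases = lapply(cp@phases, function(p) list(
        onset = p@onset, rise_tau = p@riseTau,
        decay_tau = if (is.finite(p@decayTau)) p@decayTau else "Inf",
        amplitude = p@amplitude, gated_by_unquenching = p@gatedByUnquenching)))),
    labeling = list(n_labels = sc@labeling@nLabels, quench_q = sc@labeling@quenchQ),
    noise_sigma = sc@noiseSigma, noise_model = sc@noiseModel,
    n_profiles = sc@nProfiles, n_timepoints = sc@nTimepoints,
    duration = sc@duration, cathepsin_inhibited = sc@cathepsinInhibited,
    uptake_scale = sc@uptakeScale, ee_transit_delay = sc@eeTransitDelay,
    degradation_delay = sc@degradationDelay,
    transport_lag_s2 = sc@transportLagS2, transport_lag_dt = sc@transportLagDT,
    seed = sc@seed)
}

.assertKnownKeys <- function(x, known, where) {
  extra <- setdiff(names(x), known)
  if (length(extra))
    stop("unknown key(s) in ", where, ": ", paste(extra, collapse = ", "))
}

#' Read and write scenario files
#'
#' Scenarios are stored as JSON. Unknown keys are rejected so that typos in
#' configuration files fail loudly.
#'
#' @param path file path.
#' @param scenario a \linkS4class{Scenario}.
#' @return \code{readScenario} returns a \linkS4class{Scenario};
#'   \code{writeScenario} returns \code{path} invisibly.
#' @export
readScenario <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  .assertKnownKeys(x, c("name", "compartments", "labeling", "noise_sigma",
    "noise_model", "n_profiles", "n_timepoints", "duration",
    "cathepsin_inhibited", "uptake_scale", "ee_transit_delay",
    "degradation_delay", "transport_lag_s2", "transport_lag_dt", "seed"),
    "scenario")
  comps <- lapply(x$compartments, function(cp) {
    .assertKnownKeys(cp, c("name", "center", "width", "phases"), "compartment")
    phases <- lapply(cp$phases, function(p) {
      .assertKnownKeys(p, c("onset", "rise_tau", "decay_tau", "amplitude",
                            "gated_by_unquenching"), "phase")
      dt <- p$decay_tau
      if (identical(dt, "Inf")) dt <- Inf
      KineticPhase(onset = p$onset, riseTau = p$rise_tau, decayTau = dt,
                   amplitude = p$amplitude,
                   gatedByUnquenching = isTRUE(p$gated_by_unquenching))
    })
    CompartmentSpec(cp$name, cp$center, cp$width, phases)
  })
  Scenario(name = x$name %||% "custom", compartments = comps,
           labeling = LabelingSpec(x$labeling$n_labels, x$labeling$quench_q),
           noiseSigma = x$noise_sigma, noiseModel = x$noise_model %||% "gaussian",
           nProfiles = x$n_profiles, nTimepoints = x$n_timepoints,
           duration = x$duration,
           cathepsinInhibited = isTRUE(x$cathepsin_inhibited),
           uptakeScale = x$uptake_scale %||% 1,
           eeTransitDelay = x$ee_transit_delay %||% 0,
           degradationDelay = x$degradation_delay %||% 10,
           transportLagS2 = x$transport_lag_s2 %||% 3,
           transportLagDT = x$transport_lag_dt %||% 5,
           seed = x$seed %||% 1L)
}

#' @rdname readScenario
#' @export
writeScenario <- function(scenario, path) {
  stopifnot(is(scenario, "Scenario"))
  jsonlite::write_json(.scenarioToList(scenario), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
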