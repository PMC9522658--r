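#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

setClassUnion("integerOrNA", c("integer", "logical"))

#' One kinetic phase of a compartment time course
#'
#' A phase contributes
#' \code{amplitude * (1 - exp(-(t - onset)/riseTau)) * exp(-(t - onset)/decayTau)}
#' for \code{t >= onset} and zero before. An infinite \code{decayTau} gives a
#' rise to plateau. Phases flagged \code{gatedByUnquenching} report degraded
#' (unquenched) protein: their amplitude is multiplied by the unquenching gain
#' of the labeling and forced to zero when lysosomal proteolysis is inhibited.
#'
#' @slot onset start time of the phase (min).
#' @slot riseTau rise time constant (min, > 0).
#' @slot decayTau decay time constant (min, > 0; may be \code{Inf}).
#' @slot amplitude peak-scale amplitude (arbitrary fluorescence units, >= 0).
#' @slot gatedByUnquenching logical; see above.
#' @exportClass KineticPhase
setClass("KineticPhase",
  representation(onset = "numeric", riseTau = "numeric", decayTau = "numeric",
                 amplitude = "numeric", gatedByUnquenching = "logical"),
  prototype(onset = 0, riseTau = 1, decayTau = Inf, amplitude = 1,
            gatedByUnquenching = FALSE))

setValidity("KineticPhase", function(object) {
  msg <- character()
  if (length(object@onset) != 1L || !is.finite(object@onset) || object@onset < 0)
    msg <- c(msg, "onset must be a single finite value >= 0")
  if (length(object@riseTau) != 1L || !is.finite(object@riseTau) || object@riseTau <= 0)
    msg <- c(msg, "riseTau must be a single finite value > 0")
  if (length(object@decayTau) != 1L || is.na(object@decayTau) || object@decayTau <= 0)
    msg <- c(msg, "decayTau must be > 0 (Inf allowed)")
  if (length(object@amplitude) != 1L || !is.finite(object@amplitude) || object@amplitude < 0)
    msg <- c(msg, "amplitude must be a single finite value >= 0")
  if (length(object@gatedByUnquenching) != 1L || is.na(object@gatedByUnquenching))
    msg <- c(msg, "gatedByUnquenching must be TRUE or FALSE")
  if (length(msg)) msg else TRUE
})

#' Construct a KineticPhase
#'
#' @param onset,riseTau,decayTau,amplitude,gatedByUnquenching see
#'   \linkS4class{KineticPhase}.
#' @return A \linkS4class{KineticPhase}.
#' @export
KineticPhase <- function(onset = 0, riseTau = 1, decayTau = Inf, amplitude = 1,
                         gatedByUnquenching = FALSE) {
  new("KineticPhase", onset = as.numeric(onset), riseTau = as.numeric(riseTau),
      decayTau = as.numeric(decayTau), amplitude = as.numeric(amplitude),
      gatedByUnquenching = as.logical(gatedByUnquenching))
}

#' An intracellular compartment with a Gaussian spatial footprint
#'
#' The spatial profile is an unnormalised Gaussian
#' \code{exp(-(x - center)^2 / (2 width^2))} on the normalised intracellular
#' axis (0 = apical membrane, 1 = basolateral). Kinetics are the sum of one or
#' more \linkS4class{KineticPhase} objects.
#'
#' @slot name compartment label, e.g. \code{"EE"}, \code{"LAV"}, \code{"LYS"}.
#' @slot center normalised position of the compartment centre, in [0, 1].
#' @slot width standard deviation of the Gaussian footprint (> 0).
#' @slot phases list of \linkS4class{KineticPhase}.
#' @exportClass CompartmentSpec
setClass("CompartmentSpec",
  representation(name = "character", center = "numeric", width = "numeric",
                 phases = "list"))

setValidity("CompartmentSpec", function(object) {
  msg <- character()
  if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
    msg <- c(msg, "name must be a non-empty string")
  if (length(object@center) != 1L || !is.finite(object@center) ||
      object@center < 0 || object@center > 1)
    msg <- c(msg, "center must lie in [0, 1]")
  if (length(object@width) != 1L || !is.finite(object@width) || object@width <= 0)
    msg <- c(msg, "width must be > 0")
  if (length(object@phases) < 1L)
    msg <- c(msg, "at least one kinetic phase is required")
  if (!all(vapply(object@phases, is, logical(1), "KineticPhase")))
    msg <- c(msg, "phases must all be KineticPhase objects")
  if (length(msg)) msg else TRUE
})

#' Construct a CompartmentSpec
#'
#' @param name,center,width,phases see \linkS4class{CompartmentSpec}.
#' @return A \linkS4class{CompartmentSpec}.
#' @export
CompartmentSpec <- function(name, center, width, phases) {
  if (is(phases, "KineticPhase")) phases <- list(phases)
  new("CompartmentSpec", name = as.character(name), center = as.numeric(center),
      width = as.numeric(width), phases = phases)
}

#' Fluorophore labeling of the injected protein
#'
#' Carrying \code{nLabels} fluorophores, an intact protein self-quenches: each
#' additional fluorophore multiplies per-fluorophore emission by
#' \code{quenchQ}. Proteolysis releases single-dye fragments and relieves
#' quenching, so the degraded-over-intact brightness ratio (the unquenching
#' gain) is \code{quenchQ^(1 - nLabels)}; see \code{\link{unquenchGain}}.
#'
#' @slot nLabels integer number of fluorophores per protein (>= 1).
#' @slot quenchQ per-additional-fluorophore quenching factor in (0, 1].
#' @exportClass LabelingSpec
setClass("LabelingSpec",
  representation(nLabels = "integer", quenchQ = "numeric"),
  prototype(nLabels = 4L, quenchQ = 0.6))

setValidity("LabelingSpec", function(object) {
  msg <- character()
  if (length(object@nLabels) != 1L || is.na(object@nLabels) || object@nLabels < 1L)
    msg <- c(msg, "nLabels must be an integer >= 1")
  if (length(object@quenchQ) != 1L || !is.finite(object@quenchQ) ||
      object@quenchQ <= 0 || object@quenchQ > 1)
    msg <- c(msg, "quenchQ must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a LabelingSpec
#'
#' @param nLabels,quenchQ see \linkS4class{LabelingSpec}.
#' @return A \linkS4class{LabelingSpec}.
#' @export
LabelingSpec <- function(nLabels = 4L, quenchQ = 0.6) {
  new("LabelingSpec", nLabels = as.integer(nLabels), quenchQ = as.numeric(quenchQ))
}

#' A complete simulation scenario
#'
#' Bundles the compartments, labeling, noise model, perturbations and seed
#' that define one synthetic experiment. Named default scenarios are built by
#' \code{\link{defaultScenario}}.
#'
#' @slot name scenario label.
#' @slot compartments list of \linkS4class{CompartmentSpec}.
#' @slot labeling a \linkS4class{LabelingSpec}.
#' @slot noiseSigma additive noise standard deviation (fluorescence units).
#' @slot noiseModel \code{"gaussian"} (additive, clipped at zero) or
#'   \code{"poisson"} (shot noise with variance \code{noiseSigma^2 * signal}).
#' @slot nProfiles number of line-scan ROIs per tubule.
#' @slot nTimepoints number of frames.
#' @slot duration total imaging time (min).
#' @slot cathepsinInhibited logical; TRUE disables lysosomal proteolysis
#'   (e64), zeroing all unquenching-gated phases and the degradation flux.
#' @slot uptakeScale multiplier in [0, 1] on endocytotic uptake (disease
#'   models; 1 = healthy).
#' @slot eeTransitDelay extra dwell time in the early-endosome stage (min;
#'   disease models).
#' @slot degradationDelay time from injection to onset of lysosomal
#'   degradation (min; default 10).
#' @slot transportLagS2 lag from S1 fragment release to S2 uptake (min).
#' @slot transportLagDT lag from S1 fragment release to the distal-tubule
#'   lumen signal (min).
#' @slot seed integer RNG seed; identical scenarios give identical output.
#' @exportClass Scenario
setClass("Scenario",
  representation(name = "character", compartments = "list",
                 labeling = "LabelingSpec", noiseSigma = "numeric",
                 noiseModel = "character", nProfiles = "integer",
                 nTimepoints = "integer", duration = "numeric",
                 cathepsinInhibited = "logical", uptakeScale = "numeric",
                 eeTransitDelay = "numeric", degradationDelay = "numeric",
                 transportLagS2 = "numeric", transportLagDT = "numeric",
                 seed = "integer"))

setValidity("Scenario", function(object) {
  msg <- character()
  if (length(object@compartments) < 1L)
    msg <- c(msg, "at least one compartment is required")
  if (!all(vapply(object@compartments, is, logical(1), "CompartmentSpec")))
    msg <- c(msg, "compartments must all be CompartmentSpec objects")
  if (object@nProfiles < 1L) msg <- c(msg, "nProfiles must be >= 1")
  if (object@nTimepoints < 2L) msg <- c(msg, "nTimepoints must be >= 2")
  if (!is.finite(object@noiseSigma) || object@noiseSigma < 0)
    msg <- c(msg, "noiseSigma must be >= 0")
  if (!object@noiseModel %in% c("gaussian", "poisson"))
    msg <- c(msg, "noiseModel must be 'gaussian' or 'poisson'")
  if (!is.finite(object@duration) || object@duration <= 0)
    msg <- c(msg, "duration must be > 0")
  if (!is.finite(object@uptakeScale) || object@uptakeScale < 0 || object@uptakeScale > 1)
    msg <- c(msg, "uptakeScale must lie in [0, 1]")
  if (!is.finite(object@eeTransitDelay) || object@eeTransitDelay < 0)
    msg <- c(msg, "eeTransitDelay must be >= 0")
  if (!is.finite(object@degradationDelay) || object@degradationDelay < 0)
    msg <- c(msg, "degradationDelay must be >= 0")
  if (length(msg)) msg else TRUE
})

#' A single line-scan intensity profile
#'
#' One intensity trace sampled along a line drawn across a proximal-tubule
#' cell at one time point. Positions may be raw (pixels) or normalised;
#' \code{\link{rescalePositions}} maps them onto [0, 1] with 0 = apical.
#'
#' @slot tubuleId tubule label.
#' @slot profileId ROI label within the tubule.
#' @slot time acquisition time (min).
#' @slot positions strictly increasing sample coordinates.
#' @slot intensities non-negative fluorescence values, one per position.
#' @exportClass LineScanProfile
setClass("LineScanProfile",
  representation(tubuleId = "character", profileId = "character",
                 time = "numeric", positions = "numeric",
                 intensities = "numeric"))

setValidity("LineScanProfile", function(object) {
  msg <- character()
  n <- length(object@positions)
  if (n < 2L) msg <- c(msg, "at least 2 samples are required")
  if (length(object@intensities) != n)
    msg <- c(msg, "positions and intensities must have equal length")
  if (n >= 2L && any(diff(object@positions) <= 0))
    msg <- c(msg, "positions must be strictly increasing")
  if (any(!is.finite(object@intensities)) || any(object@intensities < 0))
    msg <- c(msg, "intensities must be finite and >= 0")
  if (length(object@time) != 1L || !is.finite(object@time))
    msg <- c(msg, "time must be a single finite value")
  if (length(msg)) msg else TRUE
})

#' Construct a LineScanProfile
#'
#' @param tubuleId,profileId,time,positions,intensities see
#'   \linkS4class{LineScanProfile}.
#' @return A \linkS4class{LineScanProfile}.
#' @export
LineScanProfile <- function(tubuleId, profileId, time, positions, intensities) {
  new("LineScanProfile", tubuleId = as.character(tubuleId),
      profileId = as.character(profileId), time = as.numeric(time),
      positions = as.numeric(positions), intensities = as.numeric(intensities))
}

#' Space-by-time intensity waveform of one tubule
#'
#' The binned, normalised line-scan data of one tubule: a B x T matrix whose
#' rows are uniform position bins spanning [0, 1] (0 = apical) and whose
#' columns are time points. Extends
#' \linkS4class{SummarizedExperiment}; the single assay is named
#' \code{"intensity"}, bin centres live in \code{rowData(x)$position} and
#' times in \code{colData(x)$time}.
#'
#' @exportClass WaveformMatrix
setClass("WaveformMatrix", contains = "SummarizedExperiment")

setValidity("WaveformMatrix", function(object) {
  msg <- character()
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    return("assay 'intensity' is missing")
  a <- SummarizedExperiment::assay(object, "intensity")
  if (any(!is.finite(a))) msg <- c(msg, "intensities must be finite")
  if (any(a < 0)) msg <- c(msg, "intensities must be >= 0")
  pos <- SummarizedExperiment::rowData(object)$position
  if (is.null(pos)) {
    msg <- c(msg, "rowData(x)$position is missing")
  } else {
    b <- length(pos)
    expected <- (seq_len(b) - 0.5) / b
    if (b >= 2L && max(abs(pos - expected)) > 1e-8)
      msg <- c(msg, "position bins must be uniform centres on [0, 1]")
  }
  tm <- SummarizedExperiment::colData(object)$time
  if (is.null(tm)) msg <- c(msg, "colData(x)$time is missing")
  else if (is.unsorted(tm, strictly = TRUE))
    msg <- c(msg, "times must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Construct a WaveformMatrix
#'
#' @param values B x T numeric matrix of non-negative intensities.
#' @param times length-T vector of strictly increasing times (min).
#' @param tubuleId tubule label.
#' @return A \linkS4class{WaveformMatrix}. Position bin centres are implied
#'   by the row count: bin i is centred at \code{(i - 0.5)/B}.
#' @export
WaveformMatrix <- function(values, times, tubuleId = "tubule") {
  values <- as.matrix(values)
  b <- nrow(values)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = unname(values)),
    rowData = S4Vectors::DataFrame(position = (seq_len(b) - 0.5) / b),
    colData = S4Vectors::DataFrame(time = as.numeric(times)),
    metadata = list(tubuleId = as.character(tubuleId)))
  new("WaveformMatrix", se)
}

#' Singular value decomposition of a waveform
#'
#' Holds the full factors of A = U diag(S) V^T together with the selected
#' rank and per-component diagnostics (singular value, energy share, lag-1
#' autocorrelation of the U and V columns, retained flag). A deterministic
#' sign convention is applied: each U column is flipped, together with its
#' paired V column, so that its largest-magnitude element is positive.
#'
#' @slot u m x m orthonormal spatial factor.
#' @slot d min(m, n) singular values, non-increasing.
#' @slot v n x n orthonormal temporal factor.
#' @slot selectedRank integer rank chosen by \code{\link{selectRank}}
#'   (\code{NA} before selection).
#' @slot diagnostics per-component \code{data.frame}.
#' @slot positions bin centres of the decomposed waveform.
#' @slot times time points of the decomposed waveform.
#' @slot tubuleId tubule label carried from the waveform.
#' @exportClass SVDResult
setClass("SVDResult",
  representation(u = "matrix", d = "numeric", v = "matrix",
                 selectedRank = "integerOrNA", diagnostics = "data.frame",
                 positions = "numeric", times = "numeric",
                 tubuleId = "character"))

setValidity("SVDResult", function(object) {
  msg <- character()
  m <- nrow(object@u); n <- nrow(object@v)
  if (ncol(object@u) != m) msg <- c(msg, "u must be square (m x m)")
  if (ncol(object@v) != n) msg <- c(msg, "v must be square (n x n)")
  if (length(object@d) != min(m, n))
    msg <- c(msg, "d must have min(m, n) entries")
  if (any(object@d < -1e-12)) msg <- c(msg, "singular values must be >= 0")
  if (is.unsorted(rev(object@d))) msg <- c(msg, "singular values must be non-increasing")
  if (max(abs(crossprod(object@u) - diag(m))) > 1e-8)
    msg <- c(msg, "u is not orthonormal within 1e-8")
  if (max(abs(crossprod(object@v) - diag(n))) > 1e-8)
    msg <- c(msg, "v is not orthonormal within 1e-8")
  k <- object@selectedRank
  if (!is.na(k) && (k < 0L || k > min(m, n)))
    msg <- c(msg, "selectedRank out of range")
  if (length(msg)) msg else TRUE
})

#' Per-ROI axial profile along the proximal tubule
#'
#' ROIs drawn around successive tubule segments, ordered by a reference
#' channel from highest to lowest intensity, with the measured signal carried
#' along; built by \code{\link{orderRois}}.
#'
#' @slot roiIds ROI labels in ranked order.
#' @slot referenceIntensity reference-channel value, non-increasing.
#' @slot signalIntensity measured-channel value, permuted identically.
#' @slot rank 1-based rank after sorting.
#' @exportClass AxialProfile
setClass("AxialProfile",
  representation(roiIds = "character", referenceIntensity = "numeric",
                 signalIntensity = "numeric", rank = "integer"))

setValidity("AxialProfile", function(object) {
  msg <- character()
  n <- length(object@roiIds)
  if (length(object@referenceIntensity) != n || length(object@signalIntensity) != n ||
      length(object@rank) != n)
    msg <- c(msg, "all slots must have equal length")
  if (n && !identical(sort(object@rank), seq_len(n)))
    msg <- c(msg, "rank must be a permutation of 1..n")
  if (n && is.unsorted(rev(object@referenceIntensity)))
    msg <- c(msg, "referenceIntensity must be non-increasing along rank")
  if (length(msg)) msg else TRUE
})

#' Whole-ROI fluorescence time series for one tubular segment
#'
#' @slot segment one of \code{"plasma"}, \code{"S1"}, \code{"S2"},
#'   \code{"DT_lumen"} (free-text labels are allowed for real data).
#' @slot channel fluorescence channel label.
#' @slot times strictly increasing times (min).
#' @slot intensities non-negative intensities, one per time.
#' @exportClass TubuleTimeSeries
setClass("TubuleTimeSeries",
  representation(segment = "character", channel = "character",
                 times = "numeric", intensities = "numeric"))

setValidity("TubuleTimeSeries", function(object) {
  msg <- character()
  if (length(object@times) != length(object@intensities))
    msg <- c(msg, "times and intensities must have equal length")
  if (length(object@times) >= 2L && is.unsorted(object@times, strictly = TRUE))
    msg <- c(msg, "times must be strictly increasing")
  if (any(!is.finite(object@intensities)) || any(object@intensities < -1e-12))
    msg <- c(msg, "intensities must be finite and >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a TubuleTimeSeries
#'
#' @param segment,channel,times,intensities see
#'   \linkS4class{TubuleTimeSeries}.
#' @return A \linkS4class{TubuleTimeSeries}.
#' @export
TubuleTimeSeries <- function(segment, times, intensities, channel = "At532") {
  new("TubuleTimeSeries", segment = as.character(segment),
      channel = as.character(channel), times = as.numeric(times),
      intensities = pmax(as.numeric(intensities), 0))
}
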