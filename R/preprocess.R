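# Line-scan preprocessing: position rescaling, mean binning, waveform
# assembly, quality control and cumulative normalisation.

#' Rescale line-scan positions onto the normalised intracellular axis
#'
#' Affinely maps the sample positions onto [0, 1] so that the endpoints map
#' exactly to 0 and 1. For ROIs drawn basal-to-apical, the axis is flipped so
#' that 0 is always the apical side. Intensities are unchanged (only their
#' order flips with the axis). Idempotent on already-normalised profiles.
#'
#' @param profile a \linkS4class{LineScanProfile}.
#' @param orientation \code{"apical_first"} if position 0 is apical (the
#'   stored convention), \code{"basal_first"} if the ROI was drawn from the
#'   basal side. No autodetection is attempted.
#' @return A normalised \linkS4class{LineScanProfile}.
#' @export
rescalePositions <- function(profile,
                             orientation = c("apical_first", "basal_first")) {
  stopifnot(is(profile, "LineScanProfile"))
  orientation <- match.arg(orientation)
  pos <- profile@positions
  if (length(pos) < 2L) stop("at least 2 samples are required")
  rng <- range(pos)
  if (rng[2] == rng[1]) stop("positions span zero length")
  x <- (pos - rng[1]) / (rng[2] - rng[1])
  y <- profile@intensities
  if (orientation == "basal_first") {
    x <- rev(1 - x)
    y <- rev(y)
  }
  LineScanProfile(profile@tubuleId, profile@profileId, profile@time, x, y)
}

# Mean binning of pooled (position, intensity) samples onto B uniform bins;
# empty bins are linearly interpolated from neighbouring bins and flagged.
.binSamples <- function(positions, intensities, nBins) {
  if (!length(positions)) stop("no samples to bin")
  if (any(positions < 0 | positions > 1))
    stop("positions must be normalised to [0, 1] before binning")
  # half-open bins [i/B, (i+1)/B), last bin closed
  idx <- pmin(floor(positions * nBins) + 1L, nBins)
  grouped <- rowsum(intensities, idx)
  sums <- numeric(nBins)
  sums[as.integer(rownames(grouped))] <- grouped[, 1L]
  counts <- tabulate(idx, nBins)
  value <- ifelse(counts > 0, sums / pmax(counts, 1L), NA_real_)
  filled <- counts == 0L
  if (any(filled)) {
    if (all(filled)) stop("all bins are empty")
    centers <- (seq_len(nBins) - 0.5) / nBins
    value[filled] <- stats::approx(centers[!filled], value[!filled],
                                   xout = centers[filled], rule = 2)$y
  }
  structure(value, interpolated = filled)
}

#' Mean-bin a set of normalised profiles at one time point
#'
#' Pools all intensity samples of all profiles and averages them per uniform
#' position bin (\code{[i/B, (i+1)/B)}, last bin closed). Empty bins are
#' filled by linear interpolation from neighbouring bins and flagged in the
#' \code{"interpolated"} attribute; they are never silently invented data.
#'
#' @param profiles list of normalised \linkS4class{LineScanProfile} sharing
#'   tubule and time.
#' @param nBins number of bins (default 100).
#' @return Numeric vector of length \code{nBins} with attribute
#'   \code{"interpolated"} (logical).
#' @export
binProfiles <- function(profiles, nBins = 100L) {
  if (is(profiles, "LineScanProfile")) profiles <- list(profiles)
  if (!length(profiles)) stop("no profiles supplied")
  stopifnot(all(vapply(profiles, is, logical(1), "LineScanProfile")))
  nBins <- as.integer(nBins)
  if (nBins < 2L) stop("nBins must be >= 2")
  tub <- unique(vapply(profiles, function(p) p@tubuleId, character(1)))
  tm <- unique(vapply(profiles, function(p) p@time, numeric(1)))
  if (length(tub) != 1L) stop("profiles span multiple tubules")
  if (length(tm) != 1L) stop("profiles span multiple time points")
  .binSamples(unlist(lapply(profiles, function(p) p@positions)),
              unlist(lapply(profiles, function(p) p@intensities)), nBins)
}

#' Assemble binned vectors into a waveform matrix
#'
#' @param vectors list of equal-length binned vectors (or a B x T matrix),
#'   one per time point.
#' @param times distinct time stamps, one per vector; columns are sorted by
#'   time.
#' @param tubuleId tubule label.
#' @return A \linkS4class{WaveformMatrix}.
#' @export
assembleWaveform <- function(vectors, times, tubuleId = "tubule") {
  if (is.matrix(vectors)) vectors <- lapply(seq_len(ncol(vectors)), function(i) vectors[, i])
  lens <- vapply(vectors, length, integer(1))
  if (length(unique(lens)) != 1L) stop("binned vectors have unequal lengths")
  if (length(vectors) != length(times)) stop("one time stamp per vector is required")
  if (anyDuplicated(times)) stop("duplicate time points")
  ord <- order(times)
  WaveformMatrix(do.call(cbind, vectors)[, ord, drop = FALSE], times[ord],
                 tubuleId = tubuleId)
}

#' Build a waveform from a long-format profile table
#'
#' Convenience wrapper over \code{\link{rescalePositions}},
#' \code{\link{binProfiles}} and \code{\link{assembleWaveform}}: groups the
#' table by profile and time, normalises each profile, pools and mean-bins
#' per time point, and assembles the matrix.
#'
#' @param profileTable \code{data.frame} with columns \code{tubule_id},
#'   \code{profile_id}, \code{time_min}, \code{position}, \code{intensity}
#'   (as emitted by \code{\link{simulateProfiles}} or read by
#'   \code{\link{readProfiles}}).
#' @param nBins number of position bins (default 100).
#' @param orientation see \code{\link{rescalePositions}}.
#' @return A \linkS4class{WaveformMatrix}.
#' @export
buildWaveform <- function(profileTable, nBins = 100L,
                          orientation = c("apical_first", "basal_first")) {
  orientation <- match.arg(orientation)
  need <- c("tubule_id", "profile_id", "time_min", "position", "intensity")
  miss <- setdiff(need, names(profileTable))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  tub <- unique(profileTable$tubule_id)
  if (length(tub) != 1L) stop("profile table spans multiple tubules")
  times <- sort(unique(profileTable$time_min))
  vectors <- lapply(times, function(tm) {
    sub <- profileTable[profileTable$time_min == tm, , drop = FALSE]
    profs <- lapply(split(sub, sub$profile_id), function(d) {
      rescalePositions(
        LineScanProfile(tub, d$profile_id[1], tm, d$position, d$intensity),
        orientation = orientation)
    })
    binProfiles(profs, nBins = nBins)
  })
  assembleWaveform(vectors, times, tubuleId = as.character(tub))
}

#' Flag suspect time points of a waveform
#'
#' Two checks per time point: (a) Pearson correlation of its binned vector
#' with the element-wise median-over-time vector, flagged below
#' \code{corMin}; (b) total intensity outside
#' \code{intensityFactor * (running median of totals)}. Flagged points are
#' reported, never dropped.
#'
#' @param x a \linkS4class{WaveformMatrix} or numeric matrix (bins x times).
#' @param corMin correlation threshold (default 0.5).
#' @param intensityFactor length-2 multiplier band around the running median
#'   of column totals (default \code{c(0.2, 5)}).
#' @param window running-median window, odd (default 5).
#' @return \code{data.frame} with one row per time point: \code{time},
#'   \code{correlation}, \code{totalIntensity}, \code{runningMedian},
#'   \code{flaggedCorrelation}, \code{flaggedIntensity}, \code{flagged}.
#' @export
qcFlags <- function(x, corMin = 0.5, intensityFactor = c(0.2, 5), window = 5L) {
  if (is(x, "WaveformMatrix")) {
    times <- scanTimes(x)
    a <- intensityMatrix(x)
  } else {
    a <- as.matrix(x)
    times <- seq_len(ncol(a))
  }
  if (ncol(a) < 2L) stop("at least 2 time points are required")
  med <- apply(a, 1, stats::median)
  cors <- apply(a, 2, function(col) {
    if (stats::sd(col) == 0 || stats::sd(med) == 0) 0
    else stats::cor(col, med)
  })
  totals <- colSums(a)
  window <- min(window, ncol(a) - (1 - ncol(a) %% 2))  # odd, <= T
  run <- stats::runmed(totals, k = max(window, 1L), endrule = "median")
  fc <- cors < corMin
  fi <- totals < intensityFactor[1] * run | totals > intensityFactor[2] * run
  data.frame(time = times, correlation = cors, totalIntensity = totals,
             runningMedian = run, flaggedCorrelation = fc,
             flaggedIntensity = fi, flagged = fc | fi)
}

#' Normalise intensities to unit cumulative sum
#'
#' Divides a non-negative intensity vector by its total so the output sums
#' to 1, as used to place marker amplitudes from different channels on a
#' common scale.
#'
#' @param intensities numeric vector with at least one positive entry.
#' @return Vector summing to 1.
#' @export
cumulativeNormalize <- function(intensities) {
  if (!length(intensities) || any(!is.finite(intensities)))
    stop("intensities must be finite and non-empty")
  if (any(intensities < 0)) stop("intensities must be >= 0")
  s <- sum(intensities)
  if (s <= 0) stop("all intensities are zero")
  intensities / s
}
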