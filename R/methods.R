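# Accessors and show methods.

#' @rdname accessors
#' @export
setMethod("singularValues", "SVDResult", function(x) x@d)
#' @rdname accessors
#' @export
setMethod("leftVectors", "SVDResult", function(x) x@u)
#' @rdname accessors
#' @export
setMethod("rightVectors", "SVDResult", function(x) x@v)
#' @rdname accessors
#' @export
setMethod("selectedRank", "SVDResult", function(x) {
  if (is.na(x@selectedRank)) NA_integer_ else as.integer(x@selectedRank)
})
#' @rdname accessors
#' @export
setMethod("componentDiagnostics", "SVDResult", function(x) x@diagnostics)

#' @rdname accessors
#' @export
setMethod("positionBins", "WaveformMatrix", function(x)
  SummarizedExperiment::rowData(x)$position)
#' @rdname accessors
#' @export
setMethod("scanTimes", "WaveformMatrix", function(x)
  SummarizedExperiment::colData(x)$time)
#' @rdname accessors
#' @export
setMethod("intensityMatrix", "WaveformMatrix", function(x)
  unname(SummarizedExperiment::assay(x, "intensity")))
#' @rdname accessors
#' @export
setMethod("tubuleId", "WaveformMatrix", function(x) {
  id <- S4Vectors::metadata(x)$tubuleId
  if (is.null(id)) "tubule" else id
})

#' @rdname accessors
#' @export
setMethod("seriesTimes", "TubuleTimeSeries", function(x) x@times)
#' @rdname accessors
#' @export
setMethod("seriesIntensities", "TubuleTimeSeries", function(x) x@intensities)
#' @rdname accessors
#' @export
setMethod("segmentLabel", "TubuleTimeSeries", function(x) x@segment)

setMethod("show", "SVDResult", function(object) {
  m <- nrow(object@u); n <- nrow(object@v)
  cat("SVDResult:", m, "position bins x", n, "time points\n")
  k <- object@selectedRank
  cat("  selected rank:", if (is.na(k)) "not selected" else k, "\n")
  top <- utils::head(object@diagnostics, 5L)
  top$singularValue <- signif(top$singularValue, 4)
  top$energyShare <- signif(top$energyShare, 3)
  top$acU <- signif(top$acU, 2)
  top$acV <- signif(top$acV, 2)
  print(top, row.names = FALSE)
  if (length(object@d) > 5L) cat("  ...", length(object@d) - 5L, "more components\n")
})

setMethod("show", "Scenario", function(object) {
  cat("Scenario:", object@name, "\n")
  cat("  compartments:", paste(vapply(object@compartments,
      function(cp) cp@name, character(1)), collapse = ", "), "\n")
  cat("  labeling:", object@labeling@nLabels, "fluorophores, q =",
      object@labeling@quenchQ, "\n")
  cat(sprintf("  %d profiles x %d time points over %g min; noise sigma %g (%s)\n",
      object@nProfiles, object@nTimepoints, object@duration,
      object@noiseSigma, object@noiseModel))
  pert <- c(
    if (object@cathepsinInhibited) "cathepsin inhibited",
    if (object@uptakeScale < 1) sprintf("uptake x%g", object@uptakeScale),
    if (object@eeTransitDelay > 0) sprintf("EE transit +%g min", object@eeTransitDelay))
  if (length(pert)) cat("  perturbations:", paste(pert, collapse = "; "), "\n")
  cat("  seed:", object@seed, "\n")
})

setMethod("show", "TubuleTimeSeries", function(object) {
  cat(sprintf("TubuleTimeSeries %s (%s): %d points, t = %g..%g min, peak %.3g\n",
      object@segment, object@channel, length(object@times),
      min(object@times), max(object@times),
      if (length(object@intensities)) max(object@intensities) else NA))
})

setMethod("show", "AxialProfile", function(object) {
  cat("AxialProfile:", length(object@roiIds), "ROIs ordered by reference intensity\n")
  print(utils::head(data.frame(rank = object@rank, roi = object@roiIds,
    reference = signif(object@referenceIntensity, 3),
    signal = signif(object@signalIntensity, 3)), 6L), row.names = FALSE)
})
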