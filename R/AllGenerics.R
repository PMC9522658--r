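#' @rdname decomposeWaveform
#' @export
setGeneric("decomposeWaveform", function(x, ...) standardGeneric("decomposeWaveform"))

#' @rdname selectRank
#' @export
setGeneric("selectRank", function(x, ...) standardGeneric("selectRank"))

#' @rdname reconstructWaveform
#' @export
setGeneric("reconstructWaveform", function(x, k, ...) standardGeneric("reconstructWaveform"))

#' @rdname componentReadouts
#' @export
setGeneric("componentReadouts", function(x, ...) standardGeneric("componentReadouts"))

#' @rdname onsetTime
#' @export
setGeneric("onsetTime", function(x, fraction = 0.5, ...) standardGeneric("onsetTime"))

#' Accessors
#'
#' Small accessor generics for the package's S4 classes: singular values,
#' factor matrices, selected rank and diagnostics of an
#' \linkS4class{SVDResult}; position bins, times, intensity matrix and tubule
#' label of a \linkS4class{WaveformMatrix}; times/intensities/segment of a
#' \linkS4class{TubuleTimeSeries}.
#'
#' @param x the object.
#' @return The extracted component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("singularValues", function(x) standardGeneric("singularValues"))
#' @rdname accessors
#' @export
setGeneric("leftVectors", function(x) standardGeneric("leftVectors"))
#' @rdname accessors
#' @export
setGeneric("rightVectors", function(x) standardGeneric("rightVectors"))
#' @rdname accessors
#' @export
setGeneric("selectedRank", function(x) standardGeneric("selectedRank"))
#' @rdname accessors
#' @export
setGeneric("componentDiagnostics", function(x) standardGeneric("componentDiagnostics"))
#' @rdname accessors
#' @export
setGeneric("positionBins", function(x) standardGeneric("positionBins"))
#' @rdname accessors
#' @export
setGeneric("scanTimes", function(x) standardGeneric("scanTimes"))
#' @rdname accessors
#' @export
setGeneric("intensityMatrix", function(x) standardGeneric("intensityMatrix"))
#' @rdname accessors
#' @export
setGeneric("tubuleId", function(x) standardGeneric("tubuleId"))
#' @rdname accessors
#' @export
setGeneric("seriesTimes", function(x) standardGeneric("seriesTimes"))
#' @rdname accessors
#' @export
setGeneric("seriesIntensities", function(x) standardGeneric("seriesIntensities"))
#' @rdname accessors
#' @export
setGeneric("segmentLabel", function(x) standardGeneric("segmentLabel"))
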