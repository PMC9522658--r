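# CSV/JSON readers and writers for profiles, waveforms, tubule series and
# component tables. Dialect: comma-separated, UTF-8, '.' decimal, header row.

.profileColumns <- c("tubule_id", "profile_id", "time_min", "position", "intensity")

#' Read a long-format line-scan profile table
#'
#' Validates the schema (columns \code{tubule_id}, \code{profile_id},
#' \code{time_min}, \code{position}, \code{intensity}), numeric types and
#' non-negative intensities; errors name the offending row and column. Row
#' order is preserved.
#'
#' @param path CSV file path.
#' @return Validated \code{data.frame}.
#' @export
readProfiles <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.profileColumns, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!nrow(df)) stop("no records in ", path)
  for (col in c("time_min", "position", "intensity")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1L]
      stop("non-numeric value in column '", col, "', row ", bad)
    }
    if (anyNA(v)) stop("missing value in column '", col, "', row ",
                       which(is.na(v))[1L])
  }
  neg <- which(df$intensity < 0)
  if (length(neg)) stop("negative intensity in row ", neg[1L])
  df[.profileColumns]
}

#' @rdname readProfiles
#' @param profileTable a profile \code{data.frame}.
#' @export
writeProfiles <- function(profileTable, path) {
  utils::write.csv(profileTable[.profileColumns], path, row.names = FALSE)
  invisible(path)
}

#' Read and write waveform matrices
#'
#' The CSV holds bin centres in the first column (\code{position}) and one
#' timestamped column (\code{t_<minutes>}) per frame. \code{writeWaveform}
#' optionally writes a JSON sidecar with orientation, tubule id and a QC
#' report.
#'
#' @param path CSV file path.
#' @return \code{readWaveform} returns a \linkS4class{WaveformMatrix}.
#' @export
readWaveform <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1L] != "position") stop("first column must be 'position'")
  times <- as.numeric(sub("^t_", "", names(df)[-1L]))
  if (anyNA(times)) stop("time columns must be named t_<minutes>")
  WaveformMatrix(as.matrix(df[, -1L, drop = FALSE]), times)
}

#' @rdname readWaveform
#' @param waveform a \linkS4class{WaveformMatrix}.
#' @param qc optional QC report from \code{\link{qcFlags}} for the sidecar.
#' @param sidecar logical; write \code{<path>.json} metadata (default TRUE).
#' @export
writeWaveform <- function(waveform, path, qc = NULL, sidecar = TRUE) {
  stopifnot(is(waveform, "WaveformMatrix"))
  df <- data.frame(position = positionBins(waveform),
                   intensityMatrix(waveform), check.names = FALSE)
  names(df)[-1L] <- paste0("t_", scanTimes(waveform))
  utils::write.csv(df, path, row.names = FALSE)
  if (sidecar) {
    meta <- list(tubule_id = tubuleId(waveform), orientation = "apical_first",
                 n_bins = length(positionBins(waveform)),
                 times_min = scanTimes(waveform))
    if (!is.null(qc)) meta$qc <- qc
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Write tubule time series to CSV
#'
#' Long format: \code{segment}, \code{channel}, \code{time_min},
#' \code{intensity}.
#'
#' @param seriesList named list of \linkS4class{TubuleTimeSeries}.
#' @param path CSV file path.
#' @return \code{readTubuleSeries} returns a named list of
#'   \linkS4class{TubuleTimeSeries}.
#' @export
writeTubuleSeries <- function(seriesList, path) {
  rows <- lapply(seriesList, function(s) data.frame(
    segment = s@segment, channel = s@channel, time_min = s@times,
    intensity = s@intensities))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTubuleSeries
#' @export
readTubuleSeries <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("segment", "channel", "time_min", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  out <- lapply(split(df, df$segment), function(d)
    TubuleTimeSeries(d$segment[1L], d$time_min, d$intensity,
                     channel = d$channel[1L]))
  out[unique(df$segment)]
}

#' Write the component table of a decomposition
#'
#' One row per component: index, singular value, energy share,
#' autocorrelations and retained flag, followed by the spatial shape
#' (\code{x_<bin centre>}) and singular-value-weighted kinetic amplitude
#' (\code{t_<minutes>}) columns.
#'
#' @param result an \linkS4class{SVDResult} after \code{\link{selectRank}}.
#' @param path CSV file path.
#' @return \code{path}, invisibly.
#' @export
writeComponents <- function(result, path) {
  stopifnot(is(result, "SVDResult"))
  dg <- result@diagnostics
  r <- nrow(dg)
  sp <- t(result@u[, seq_len(r), drop = FALSE])
  ki <- t(sweep(result@v[, seq_len(r), drop = FALSE], 2,
                result@d[seq_len(r)], "*"))
  colnames(sp) <- if (length(result@positions)) paste0("x_", result@positions)
                  else paste0("x_bin", seq_len(ncol(sp)))
  colnames(ki) <- if (length(result@times)) paste0("t_", result@times)
                  else paste0("t_idx", seq_len(ncol(ki)))
  utils::write.csv(cbind(dg, sp, ki), path, row.names = FALSE)
  invisible(path)
}
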