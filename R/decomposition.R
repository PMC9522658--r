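# Model-free decomposition of a waveform into spatial and kinetic base
# vectors, rank selection by singular-value energy and singular-vector
# autocorrelation, denoised reconstruction and component readouts.

# Tolerances for the linear-algebra identities (relative Frobenius for
# reconstruction, absolute for orthonormality).
.svdTol <- 1e-8

#' Lag-1 autocorrelation of a vector
#'
#' Centred, biased estimator:
#' \code{sum (x_t - xbar)(x_{t+1} - xbar) / sum (x_t - xbar)^2}. Smooth
#' structured vectors score near 1, white noise near 0. Affine-invariant.
#'
#' @param x numeric vector, length >= 3, non-zero variance.
#' @return Value in [-1, 1].
#' @examples
#' lag1Autocorrelation(1:5)  # 0.4
#' @export
lag1Autocorrelation <- function(x) {
  if (length(x) < 3L) stop("at least 3 values are required")
  x <- x - mean(x)
  den <- sum(x^2)
  if (den == 0) stop("zero-variance vector: degenerate component")
  sum(x[-1L] * x[-length(x)]) / den
}

# Deterministic sign convention: flip each paired (U, V) column so the
# largest-magnitude element of the U column is positive; surplus columns of
# the square factors (null space) are flipped on their own.
.fixSigns <- function(u, v) {
  r <- min(ncol(u), ncol(v))
  for (i in seq_len(ncol(u))) {
    s <- sign(u[which.max(abs(u[, i])), i])
    if (s < 0) {
      u[, i] <- -u[, i]
      if (i <= r) v[, i] <- -v[, i]
    }
  }
  for (i in seq_len(ncol(v))) {
    if (i > r && sign(v[which.max(abs(v[, i])), i]) < 0) v[, i] <- -v[, i]
  }
  list(u = u, v = v)
}

.safeAc <- function(x) tryCatch(lag1Autocorrelation(x), error = function(e) NA_real_)

#' Singular value decomposition of a waveform matrix
#'
#' Computes the full factorisation A = U diag(S) V^T of the bins x times
#' intensity matrix, applies the sign convention (largest-magnitude element
#' of each spatial vector positive), and tabulates per-component diagnostics:
#' singular value, energy share S_i^2 / sum S^2, and lag-1 autocorrelations
#' of the paired U and V columns.
#'
#' @param x a \linkS4class{WaveformMatrix} or numeric matrix.
#' @return An \linkS4class{SVDResult} with \code{selectedRank} unset
#'   (\code{NA}) until \code{\link{selectRank}} is called.
#' @rdname decomposeWaveform
#' @export
setMethod("decomposeWaveform", "WaveformMatrix", function(x, ...) {
  res <- decomposeWaveform(intensityMatrix(x))
  res@positions <- positionBins(x)
  res@times <- scanTimes(x)
  res@tubuleId <- tubuleId(x)
  res
})

#' @rdname decomposeWaveform
#' @param ... unused.
#' @export
setMethod("decomposeWaveform", "matrix", function(x, ...) {
  if (!length(x)) stop("empty matrix")
  if (any(!is.finite(x))) stop("non-finite entries in waveform")
  m <- nrow(x); n <- ncol(x)
  sv <- svd(x, nu = m, nv = n)
  fx <- .fixSigns(sv$u, sv$v)
  r <- min(m, n)
  d2 <- sv$d^2
  total <- sum(d2)
  diag_ <- data.frame(
    component = seq_len(r),
    singularValue = sv$d,
    energyShare = if (total > 0) d2 / total else rep(0, r),
    acU = vapply(seq_len(r), function(i) .safeAc(fx$u[, i]), numeric(1)),
    acV = vapply(seq_len(r), function(i) .safeAc(fx$v[, i]), numeric(1)),
    retained = NA)
  new("SVDResult", u = fx$u, d = sv$d, v = fx$v, selectedRank = NA,
      diagnostics = diag_, positions = numeric(0), times = numeric(0),
      tubuleId = "")
})

#' Select the number of relevant base vectors
#'
#' Components are scanned in order of decreasing singular value. Component i
#' is retained iff its energy share S_i^2 / sum S^2 is at least
#' \code{svEnergyMin} and the lag-1 autocorrelations of both its spatial (U)
#' and kinetic (V) vectors are at least \code{acMin}; scanning stops at the
#' first rejected component, so the retained set is always the leading one.
#' Degenerate (zero-variance) singular vectors are rejected.
#'
#' @param x an \linkS4class{SVDResult}.
#' @param svEnergyMin minimum energy share (default 0.01).
#' @param acMin minimum lag-1 autocorrelation (default 0.5).
#' @param rank optional manual override; skips the scan.
#' @param ... unused.
#' @return The \linkS4class{SVDResult} with \code{selectedRank} set and the
#'   \code{retained} column of the diagnostics filled;
#'   \code{selectedRank()} extracts k.
#' @rdname selectRank
#' @export
setMethod("selectRank", "SVDResult", function(x, svEnergyMin = 0.01,
                                              acMin = 0.5, rank = NULL, ...) {
  r <- length(x@d)
  if (!is.null(rank)) {
    rank <- as.integer(rank)
    if (rank < 0L || rank > r) stop("rank override out of range")
    x@diagnostics$retained <- seq_len(r) <= rank
    x@selectedRank <- rank
    return(x)
  }
  dg <- x@diagnostics
  retained <- logical(r)
  for (i in seq_len(r)) {
    ok <- dg$energyShare[i] >= svEnergyMin &&
      !is.na(dg$acU[i]) && !is.na(dg$acV[i]) &&
      dg$acU[i] >= acMin && dg$acV[i] >= acMin
    if (!ok) break
    retained[i] <- TRUE
  }
  x@diagnostics$retained <- retained
  x@selectedRank <- sum(retained)
  x
})

#' Truncated (denoised) reconstruction
#'
#' Reconstructs the waveform with all singular values beyond the first
#' \code{k} set to zero. The Frobenius error against the input equals the
#' tail norm \code{sqrt(sum_{i>k} S_i^2)} (Eckart-Young).
#'
#' @param x an \linkS4class{SVDResult}.
#' @param k rank, 0 to min(m, n); defaults to the selected rank.
#' @param ... unused.
#' @return Numeric matrix (bins x times).
#' @rdname reconstructWaveform
#' @export
setMethod("reconstructWaveform", "SVDResult", function(x, k, ...) {
  r <- length(x@d)
  if (missing(k)) {
    k <- x@selectedRank
    if (is.na(k)) stop("no rank selected; supply k or call selectRank()")
  }
  k <- as.integer(k)
  if (k < 0L || k > r) stop("k out of range [0, ", r, "]")
  m <- nrow(x@u); n <- nrow(x@v)
  if (k == 0L) return(matrix(0, m, n))
  idx <- seq_len(k)
  x@u[, idx, drop = FALSE] %*% (x@d[idx] * t(x@v[, idx, drop = FALSE]))
})

#' Per-component spatial shapes and kinetic amplitudes
#'
#' For each retained component i: the spatial shape is the (sign-fixed) U
#' column, and the kinetic amplitude is S_i times the V column, so that the
#' sum over retained components of shape x amplitude outer products equals
#' the rank-k reconstruction.
#'
#' @param x an \linkS4class{SVDResult} after \code{\link{selectRank}}.
#' @param ... unused.
#' @return List with elements \code{component} (indices), \code{spatial}
#'   (bins x k matrix), \code{kinetic} (times x k matrix, singular-value
#'   weighted), \code{positions}, \code{times}.
#' @rdname componentReadouts
#' @export
setMethod("componentReadouts", "SVDResult", function(x, ...) {
  k <- x@selectedRank
  if (is.na(k)) stop("no rank selected; call selectRank() first")
  idx <- seq_len(k)
  list(component = idx,
       spatial = x@u[, idx, drop = FALSE],
       kinetic = sweep(x@v[, idx, drop = FALSE], 2, x@d[idx], "*"),
       positions = x@positions, times = x@times)
})

#' Match retained components to generating compartment profiles
#'
#' Greedy assignment maximising the absolute Pearson correlation between
#' each retained spatial shape and each (mean-removed) generating
#' compartment profile. Compartments left without a component (e.g. a
#' perturbation removed their signal) get \code{NA} and zero energy.
#'
#' @param result an \linkS4class{SVDResult} after \code{\link{selectRank}}.
#' @param profiles bins x compartments matrix of generating spatial
#'   profiles, with column names.
#' @return \code{data.frame} with one row per compartment: \code{compartment},
#'   \code{component} (or \code{NA}), \code{absCorrelation}, \code{energy}
#'   (squared singular value; 0 if unmatched).
#' @export
matchComponents <- function(result, profiles) {
  stopifnot(is(result, "SVDResult"))
  k <- result@selectedRank
  if (is.na(k)) stop("no rank selected; call selectRank() first")
  profiles <- as.matrix(profiles)
  p <- ncol(profiles)
  nm <- colnames(profiles)
  if (is.null(nm)) nm <- paste0("compartment", seq_len(p))
  out <- data.frame(compartment = nm, component = NA_integer_,
                    absCorrelation = NA_real_, energy = 0)
  if (k == 0L) return(out)
  cc <- abs(stats::cor(result@u[, seq_len(k), drop = FALSE], profiles))
  cc[!is.finite(cc)] <- 0
  repeat {
    if (!length(cc) || all(cc < 0)) break
    best <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    comp <- best[1]; prof <- best[2]
    if (cc[comp, prof] < 0) break
    out$component[prof] <- comp
    out$absCorrelation[prof] <- cc[comp, prof]
    out$energy[prof] <- result@d[comp]^2
    cc[comp, ] <- -1
    cc[, prof] <- -1
    if (all(cc < 0)) break
  }
  out
}
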