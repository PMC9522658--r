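# In silico tryptic digestion, monoisotopic [M+H]+ masses and size-class
# routing of peptide fragments.

# Monoisotopic residue masses (Da) of the 20 standard amino acids.
.residueMass <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)

.massWater <- 18.010565
.massProton <- 1.007276

.checkSequence <- function(sequence) {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence))
    stop("sequence must be a single non-empty string")
  res <- strsplit(toupper(sequence), "")[[1L]]
  bad <- setdiff(res, names(.residueMass))
  if (length(bad))
    stop("invalid residue(s): ", paste(unique(bad), collapse = ", "))
  res
}

# round-half-up to integer Da, the display convention for printed masses
.roundMass <- function(x) floor(x + 0.5)

#' Tryptic digestion of a peptide sequence
#'
#' Cleaves C-terminal to lysine (K) or arginine (R), except when the next
#' residue is proline (Keil rule). With \code{missedCleavages > 0}, all
#' merges of up to that many adjacent fragments are appended after the fully
#' cleaved set.
#'
#' @param sequence one-letter amino-acid string (standard 20 residues).
#' @param missedCleavages maximum number of missed cleavage sites
#'   (default 0).
#' @return Character vector of fragments; for \code{missedCleavages = 0}
#'   they concatenate exactly to the input.
#' @examples
#' trypticDigest("AKRGLK")                  # "AK" "R" "GLK"
#' trypticDigest("VYVEELKPTPEGDLEILLQK")    # one fragment: K|P is not cleaved
#' @export
trypticDigest <- function(sequence, missedCleavages = 0L) {
  res <- .checkSequence(sequence)
  n <- length(res)
  cut <- which(res[-n] %in% c("K", "R") & res[-1L] != "P")
  starts <- c(1L, cut + 1L)
  ends <- c(cut, n)
  frags <- vapply(seq_along(starts),
                  function(i) paste(res[starts[i]:ends[i]], collapse = ""),
                  character(1))
  mc <- as.integer(missedCleavages)
  if (mc > 0L && length(frags) > 1L) {
    merged <- unlist(lapply(seq_len(min(mc, length(frags) - 1L)), function(m) {
      vapply(seq_len(length(frags) - m), function(i)
        paste(frags[i:(i + m)], collapse = ""), character(1))
    }))
    frags <- c(frags, merged)
  }
  frags
}

#' Singly protonated monoisotopic peptide mass
#'
#' Sum of the standard monoisotopic residue masses plus monoisotopic water
#' (18.010565 Da) and one proton (1.007276 Da), i.e. the [M+H]+ ion mass.
#'
#' @param sequence one-letter amino-acid string.
#' @param rounded if TRUE, round half-up to integer Da (the display
#'   convention); default FALSE returns full precision.
#' @return Mass in Da.
#' @examples
#' peptideMH("ALK")                 # 331.234
#' peptideMH("ALK", rounded = TRUE) # 331
#' @export
peptideMH <- function(sequence, rounded = FALSE) {
  res <- .checkSequence(sequence)
  m <- sum(.residueMass[res]) + .massWater + .massProton
  if (rounded) .roundMass(m) else m
}

#' Size class of a peptide fragment
#'
#' Peptides of up to \code{lengthCutoff} residues behave as small (they
#' bypass S1 and are reabsorbed downstream); longer fragments behave as
#' whole proteins and trigger S1 uptake. The cutoff is inclusive.
#'
#' @param sequence one-letter amino-acid string.
#' @param lengthCutoff inclusive residue-count cutoff (default 6).
#' @return \code{"small"} or \code{"large"}.
#' @examples
#' classifyFragment("ALK")                   # small
#' classifyFragment("VYVEELKPTPEGDLEILLQK")  # large
#' @export
classifyFragment <- function(sequence, lengthCutoff = 6L) {
  res <- .checkSequence(sequence)
  if (length(res) <= lengthCutoff) "small" else "large"
}

#' Digest sequences into an annotated fragment table
#'
#' @param sequences named character vector of protein/peptide sequences, or
#'   an \code{AAStringSet}, or the path of a FASTA file (read with
#'   \code{Biostrings::readAAStringSet}).
#' @param missedCleavages,lengthCutoff see \code{\link{trypticDigest}} and
#'   \code{\link{classifyFragment}}.
#' @return \code{data.frame} with columns \code{protein}, \code{sequence},
#'   \code{length}, \code{mh_mono}, \code{mh_rounded}, \code{size_class}.
#' @export
digestTable <- function(sequences, missedCleavages = 0L, lengthCutoff = 6L) {
  if (is.character(sequences) && length(sequences) == 1L &&
      is.null(names(sequences)) && file.exists(sequences)) {
    sequences <- Biostrings::readAAStringSet(sequences)
  }
  if (is(sequences, "AAStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  rows <- lapply(names(sequences), function(nm) {
    frags <- trypticDigest(sequences[[nm]], missedCleavages)
    data.frame(protein = nm, sequence = frags, length = nchar(frags),
               mh_mono = vapply(frags, peptideMH, numeric(1), USE.NAMES = FALSE),
               mh_rounded = vapply(frags, peptideMH, numeric(1),
                                   rounded = TRUE, USE.NAMES = FALSE),
               size_class = vapply(frags, classifyFragment, character(1),
                                   lengthCutoff = lengthCutoff,
                                   USE.NAMES = FALSE))
  })
  do.call(rbind, rows)
}
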