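# Built-in PWM library. These are synthetic, generic consensus-style motifs
# (Sox/Six/Fox/Gata-like cores), not database PFMs: real scans should supply
# JASPAR files via read_jaspar_pfm().

#' @noRd
pwm_from_consensus <- function(consensus, dominant = 0.85) {
  bases <- c("A", "C", "G", "T")
  cols <- strsplit(consensus, "")[[1L]]
  stopifnot(all(cols %in% bases))
  m <- matrix((1 - dominant) / 3, nrow = 4L, ncol = length(cols),
              dimnames = list(bases, NULL))
  m[cbind(match(cols, bases), seq_along(cols))] <- dominant
  m
}

#' Built-in synthetic motif library
#'
#' Four 9 bp column-stochastic PWMs with ~10.4 bits of information each
#' (dominant base probability 0.85): an HMG-box Sox-like motif, a Six
#' homeodomain-like motif, and two decoys (forkhead-like, GATA-like). The
#' Sox-like and Six-like motifs are the default co-occurring pair planted by
#' the synthetic generator; the two decoys are planted mutually exclusively.
#'
#' @return named list of 4 x 9 probability matrices (rows A, C, G, T).
#' @export
default_motif_library <- function() {
  list(
    soxlike  = pwm_from_consensus("CATTGTTAT"),
    sixlike  = pwm_from_consensus("TCAGGTTTC"),
    foxlike  = pwm_from_consensus("TGTTTACTT"),
    gatalike = pwm_from_consensus("AGATAAGAC")
  )
}

#' @noRd
pwm_consensus <- function(pwm) {
  paste0(rownames(pwm)[apply(pwm, 2L, which.max)], collapse = "")
}

#' Reverse complement of a PWM
#' @param pwm 4 x width matrix with rows A, C, G, T.
#' @return 4 x width matrix: rows swapped A<->T, C<->G, columns reversed.
#' @export
pwm_reverse_complement <- function(pwm) {
  out <- pwm[c("T", "G", "C", "A"), rev(seq_len(ncol(pwm))), drop = FALSE]
  rownames(out) <- c("A", "C", "G", "T")
  out
}

#' Information content of a PWM in bits
#' @param pwm column-stochastic 4 x width matrix.
#' @return total bits summed over columns (2 - entropy per column).
#' @export
pwm_information_content <- function(pwm) {
  p <- pmax(pwm, 1e-12)
  sum(2 + colSums(p * log2(p)))
}
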