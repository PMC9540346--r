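# PWM scanning of RRE sequences and the four-way Sox/Six enhancer
# categorization (sox_only / six_only / both / neither), cross-tabulated
# with linked differentially expressed genes.

#' Scan a sequence with a PWM (both strands)
#'
#' Log-odds against a uniform 0.25 background, log2, with a pseudocount of
#' 1e-3 added to the motif probabilities. Positions with N contribute the
#' background log-odds (0). A hit is reported wherever the score reaches
#' `threshold_fraction` of the PWM's maximum achievable score. Minus-strand
#' hits are found by scanning the reverse-complement PWM; `start` is always
#' the leftmost position on the forward sequence (0-based).
#'
#' @param sequence a single DNA string over A, C, G, T, N.
#' @param pwm column-stochastic 4 x width matrix (rows A, C, G, T).
#' @param threshold_fraction fraction of the maximum achievable score
#'   (default 0.8).
#' @param motif_id label stored in the hit table.
#' @param background base background probability (uniform, default 0.25).
#' @return data.frame (motif_id, start, strand, score); empty if the PWM is
#'   wider than the sequence.
#' @export
scan_pwm <- function(sequence, pwm, threshold_fraction = 0.8,
                     motif_id = "motif", background = 0.25) {
  stopifnot(length(sequence) == 1L)
  w <- ncol(pwm)
  n <- nchar(sequence)
  empty <- data.frame(motif_id = character(), start = integer(),
                      strand = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (w > n) return(empty)
  lookup <- integer(256)
  lookup[utf8ToInt("A")] <- 1L; lookup[utf8ToInt("C")] <- 2L
  lookup[utf8ToInt("G")] <- 3L; lookup[utf8ToInt("T")] <- 4L
  code <- lookup[utf8ToInt(toupper(sequence))]
  score_matrix <- function(p) {
    s <- log2((p + 1e-3) / background)
    rbind(s, N = 0)[c(5L, 1L:4L), , drop = FALSE]  # row 1 = N (code 0)
  }
  scan_one <- function(p) {
    L <- score_matrix(p)
    npos <- n - w + 1L
    sc <- numeric(npos)
    for (j in seq_len(w))
      sc <- sc + L[code[j:(j + npos - 1L)] + 1L, j]
    sc
  }
  max_score <- sum(apply(log2((pwm + 1e-3) / background), 2L, max))
  thr <- threshold_fraction * max_score
  fwd <- scan_one(pwm)
  rev <- scan_one(pwm_reverse_complement(pwm))
  hf <- which(fwd >= thr); hr <- which(rev >= thr)
  out <- rbind(
    if (length(hf)) data.frame(motif_id = motif_id, start = hf - 1L,
                               strand = "+", score = fwd[hf],
                               stringsAsFactors = FALSE),
    if (length(hr)) data.frame(motif_id = motif_id, start = hr - 1L,
                               strand = "-", score = rev[hr],
                               stringsAsFactors = FALSE))
  if (is.null(out)) return(empty)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition peaks into Sox/Six motif categories
#'
#' A peak contains Sox iff any Sox-family PWM hits its sequence (and
#' likewise Six); the four categories are `sox_only`, `six_only`, `both`,
#' `neither`. Every peak receives exactly one category; counts sum to the
#' number of peaks.
#'
#' @param sequences named character vector, one sequence per peak (names =
#'   peak ids).
#' @param sox_pwms,six_pwms lists of column-stochastic PWMs (one of the two
#'   families may be empty, not both).
#' @param threshold_fraction passed to [scan_pwm()].
#' @return list with `categories` (data.frame peak_id, category) and
#'   `counts` (named integer vector over the four categories).
#' @export
categorize_peaks <- function(sequences, sox_pwms, six_pwms,
                             threshold_fraction = 0.8) {
  if (!length(sox_pwms) && !length(six_pwms))
    stop("need at least one PWM in sox_pwms or six_pwms")
  has_hit <- function(seq, pwms) {
    for (p in pwms)
      if (nrow(scan_pwm(seq, p, threshold_fraction)) > 0L) return(TRUE)
    FALSE
  }
  ids <- names(sequences) %||% paste0("peak_", seq_along(sequences))
  sox <- vapply(sequences, has_hit, logical(1), pwms = sox_pwms)
  six <- vapply(sequences, has_hit, logical(1), pwms = six_pwms)
  category <- ifelse(sox & six, "both",
                     ifelse(sox, "sox_only",
                            ifelse(six, "six_only", "neither")))
  lv <- c("sox_only", "six_only", "both", "neither")
  counts <- stats::setNames(as.integer(table(factor(category, levels = lv))),
                            lv)
  list(categories = data.frame(peak_id = ids, category = unname(category),
                               stringsAsFactors = FALSE),
       counts = counts)
}

#' Count DE genes linked to peaks of each motif category
#'
#' A DE gene counts for a category when it is linked (per the peak-to-gene
#' linker) to at least one peak of that category; a gene may therefore count
#' in several categories. Fractions are relative to the total number of DE
#' genes linked to any categorized peak.
#'
#' @param categories data.frame (peak_id, category) from
#'   [categorize_peaks()].
#' @param links data.frame (peak_id, gene_id) from
#'   [link_peaks_to_genes()].
#' @param de_genes character vector of DE gene ids.
#' @return data.frame (category, n_genes, fraction), all four categories
#'   present.
#' @export
category_gene_counts <- function(categories, links, de_genes) {
  lv <- c("sox_only", "six_only", "both", "neither")
  de_links <- links[links$gene_id %in% de_genes, , drop = FALSE]
  merged <- merge(de_links, categories, by = "peak_id")
  total <- length(unique(merged$gene_id))
  n <- vapply(lv, function(cat)
    length(unique(merged$gene_id[merged$category == cat])), integer(1))
  data.frame(category = lv, n_genes = unname(n),
             fraction = if (total > 0) unname(n) / total else rep(0, 4L),
             stringsAsFactors = FALSE)
}
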