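# Differential accessibility: per-peak two-sided Wilcoxon rank-sum with
# midranks, tie-corrected variance and continuity correction, a pseudocount
# log2 fold change on group means, and the joint pass filter
# p < 0.1, avg_log2FC >= 0.25, max(pct1, pct2) >= 0.025.

#' Two-sided Wilcoxon rank-sum test (normal approximation)
#'
#' Midranks for ties; normal approximation with tie-corrected variance and a
#' 0.5 continuity correction; p clipped to [0, 1]. When every value across
#' both groups is identical the test is degenerate and p = 1.
#'
#' @param x,y numeric vectors for the two groups (both non-empty).
#' @return list with `U` (rank-sum statistic for `x`) and `p_value`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  N <- n1 + n2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0) return(list(U = U, p_value = 1))
  mu <- n1 * n2 / 2
  z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)
  p <- min(1, max(0, 2 * stats::pnorm(-z)))
  list(U = U, p_value = p)
}

#' Average log2 fold change with pseudocount 1
#'
#' `log2((mean(group1) + 1) / (mean(group2) + 1))` on raw per-cell counts.
#'
#' @param counts peaks x cells numeric matrix.
#' @param groups factor/character of length ncol(counts) with two levels.
#' @param group1,group2 level names; default the first two levels in order.
#' @return numeric vector, one avg_log2FC per peak (positive = higher in
#'   group1).
#' @export
average_log_fc <- function(counts, groups, group1 = NULL, group2 = NULL) {
  groups <- as.character(groups)
  lv <- unique(groups)
  group1 <- group1 %||% lv[1L]
  group2 <- group2 %||% lv[2L]
  m1 <- rowMeans(counts[, groups == group1, drop = FALSE])
  m2 <- rowMeans(counts[, groups == group2, drop = FALSE])
  log2((m1 + 1) / (m2 + 1))
}

#' Call differential peaks between two cell groups
#'
#' One Wilcoxon rank-sum test per peak (group1 vs group2 cells), the
#' pseudocount log2 fold change of group means, and detection fractions
#' pct1/pct2 (share of cells with count > 0). A peak passes iff
#' p < `p_cutoff` AND avg_log2FC >= `logfc_cutoff` AND
#' max(pct1, pct2) >= `min_pct`.
#'
#' @param counts peaks x cells matrix of non-negative counts with rownames
#'   (peak ids) and colnames (cell ids).
#' @param groups vector of group labels per cell, exactly two distinct values.
#' @param group1 the condition of interest (fold change numerator); defaults
#'   to the first label encountered.
#' @param p_cutoff,logfc_cutoff,min_pct pass thresholds (defaults 0.1, 0.25,
#'   0.025).
#' @return data.frame (peak_id, p_value, avg_log2FC, pct1, pct2, passes)
#'   sorted by ascending p_value.
#' @export
call_differential_peaks <- function(counts, groups, group1 = NULL,
                                    p_cutoff = 0.1, logfc_cutoff = 0.25,
                                    min_pct = 0.025) {
  if (is.null(dim(counts))) stop("counts must be a peaks x cells matrix")
  if (length(groups) != ncol(counts))
    stop("groups length must equal the number of cells (columns)")
  if (any(counts < 0)) {
    bad <- which(rowSums(counts < 0) > 0)[1L]
    stop("negative count in peak row ",
         rownames(counts)[bad] %||% bad)
  }
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2L) stop("exactly two groups are required, got ",
                             length(lv))
  group1 <- group1 %||% lv[1L]
  group2 <- setdiff(lv, group1)
  i1 <- groups == group1
  i2 <- groups == group2
  if (sum(i1) < 2L || sum(i2) < 2L) stop("need >= 2 cells per group")
  n_peaks <- nrow(counts)
  if (n_peaks == 0L)
    return(data.frame(peak_id = character(), p_value = numeric(),
                      avg_log2FC = numeric(), pct1 = numeric(),
                      pct2 = numeric(), passes = logical(),
                      stringsAsFactors = FALSE))
  p <- vapply(seq_len(n_peaks), function(i) {
    wilcoxon_rank_sum(counts[i, i1], counts[i, i2])$p_value
  }, numeric(1))
  lfc <- average_log_fc(counts, groups, group1, group2)
  pct1 <- rowMeans(counts[, i1, drop = FALSE] > 0)
  pct2 <- rowMeans(counts[, i2, drop = FALSE] > 0)
  out <- data.frame(
    peak_id = rownames(counts) %||% paste0("peak_", seq_len(n_peaks)),
    p_value = p, avg_log2FC = unname(lfc),
    pct1 = unname(pct1), pct2 = unname(pct2),
    stringsAsFactors = FALSE
  )
  out$passes <- out$p_value < p_cutoff & out$avg_log2FC >= logfc_cutoff &
    pmax(out$pct1, out$pct2) >= min_pct
  out <- out[order(out$p_value, out$peak_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
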