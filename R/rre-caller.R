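# RRE calling: peaks from treated (regenerating) tissue that have no
# untreated peak center within the merge distance d (default 100 bp,
# HOMER mergePeaks -d semantics read as center-to-center distance).
# Peaks on different chromosomes never match.

#' @noRd
peak_centers <- function(peaks) {
  as.integer(floor((peaks$start + peaks$end) / 2))
}

#' @noRd
validate_peaks <- function(peaks, what = "peaks") {
  needed <- c("chrom", "start", "end", "peak_id")
  miss <- setdiff(needed, names(peaks))
  if (length(miss))
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "))
  if (any(peaks$start >= peaks$end))
    stop(what, " contains an interval with start >= end")
  peaks
}

#' A set of regeneration-responsive elements
#'
#' Lightweight container for a deduplicated per-cell-type peak set: the peak
#' table, the cell type, and the organs it was derived from.
#'
#' @param peaks data.frame with chrom, start, end, peak_id (0-based
#'   half-open) and optionally p_value.
#' @param cell_type cell-type label (e.g. "SC", "PC", "HC").
#' @param provenance character vector of organs combined into this set.
#' @return object of class `rre_set`.
#' @export
rre_set <- function(peaks, cell_type = NA_character_,
                    provenance = character()) {
  validate_peaks(peaks, "RRE set")
  structure(list(peaks = peaks, cell_type = cell_type,
                 provenance = provenance),
            class = "rre_set")
}

#' @export
print.rre_set <- function(x, ...) {
  cat(sprintf("<rre_set> %d peaks, cell type %s, organs: %s\n",
              nrow(x$peaks), x$cell_type,
              if (length(x$provenance)) paste(x$provenance, collapse = "+")
              else "(unspecified)"))
  invisible(x)
}

#' @noRd
as_peak_df <- function(x) {
  if (inherits(x, "rre_set")) x$peaks else validate_peaks(x)
}

#' Peaks shared between two sets at center distance <= d
#'
#' A pair (a, b) is reported iff both peaks sit on the same chromosome and
#' their centers are at most `d` bp apart. A peak may appear in several
#' pairs.
#'
#' @param set_a,set_b peak data.frames or `rre_set` objects.
#' @param d maximum center-to-center distance in bp (default 100).
#' @return data.frame (peak_a, peak_b, chrom, center_a, center_b, distance).
#' @export
shared_peaks <- function(set_a, set_b, d = 100) {
  if (d < 0) stop("d must be non-negative")
  a <- as_peak_df(set_a); b <- as_peak_df(set_b)
  empty <- data.frame(peak_a = character(), peak_b = character(),
                      chrom = character(), center_a = integer(),
                      center_b = integer(), distance = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(a) || !nrow(b)) return(empty)
  ca <- peak_centers(a); cb <- peak_centers(b)
  out <- vector("list", 0L)
  for (chr in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- which(a$chrom == chr); ib <- which(b$chrom == chr)
    ob <- ib[order(cb[ib])]
    sb <- cb[ob]
    lo <- findInterval(ca[ia] - d, sb, left.open = TRUE) + 1L
    hi <- findInterval(ca[ia] + d, sb)
    keep <- which(hi >= lo)
    if (!length(keep)) next
    reps <- hi[keep] - lo[keep] + 1L
    aa <- rep(ia[keep], reps)
    bb <- ob[unlist(mapply(seq.int, lo[keep], hi[keep], SIMPLIFY = FALSE))]
    out[[length(out) + 1L]] <- data.frame(
      peak_a = a$peak_id[aa], peak_b = b$peak_id[bb],
      chrom = chr, center_a = ca[aa], center_b = cb[bb],
      distance = abs(ca[aa] - cb[bb]),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Emerging peaks: treated peaks absent from the untreated condition
#'
#' Removes every treated peak whose center lies within `d` bp of any
#' untreated peak center on the same chromosome, leaving the cell-type
#' specific emerging peaks (RREs).
#'
#' @inheritParams shared_peaks
#' @param treated,untreated peak data.frames or `rre_set`s; if both carry a
#'   `cell_type` column/label they must agree.
#' @return `rre_set` of emerging peaks.
#' @export
emerging_peaks <- function(treated, untreated, d = 100) {
  ct_t <- peak_cell_type(treated); ct_u <- peak_cell_type(untreated)
  if (!is.na(ct_t) && !is.na(ct_u) && ct_t != ct_u)
    stop("cell-type mismatch: treated is ", ct_t, ", untreated is ", ct_u)
  t_df <- as_peak_df(treated); u_df <- as_peak_df(untreated)
  if (!nrow(u_df)) return(rre_set(t_df, cell_type = ct_t))
  hits <- shared_peaks(t_df, u_df, d)
  keep <- !(t_df$peak_id %in% hits$peak_a)
  rre_set(t_df[keep, , drop = FALSE], cell_type = ct_t)
}

#' @noRd
peak_cell_type <- function(x) {
  if (inherits(x, "rre_set")) return(x$cell_type)
  ct <- unique(x$cell_type %||% NA_character_)
  if (length(ct) == 1L) ct else NA_character_
}

# Connected components of the 1-D center-proximity graph, per chromosome.
# On sorted centers, components are maximal runs with consecutive gaps <= d
# (an edge between non-adjacent peaks implies every intermediate gap <= d).
#' @noRd
proximity_components <- function(chrom, centers, d) {
  comp <- integer(length(centers))
  next_id <- 0L
  for (chr in unique(chrom)) {
    idx <- which(chrom == chr)
    o <- idx[order(centers[idx])]
    gap_new <- c(TRUE, diff(centers[o]) > d)
    comp[o] <- next_id + cumsum(gap_new)
    next_id <- max(comp[o])
  }
  comp
}

#' Combine RRE sets from two organs
#'
#' Union of the saccule and utricle RRE sets for one cell type. Peaks whose
#' centers fall within `d` bp of each other (connected components of the
#' proximity graph) are collapsed to the single peak with the smallest
#' p-value (ties: smaller start). The result satisfies the RRE-set
#' deduplication invariant: no two retained centers within `d` bp.
#'
#' @param rres_a,rres_b `rre_set`s or peak data.frames of the same cell type.
#' @param d merge distance in bp.
#' @return `rre_set` with combined provenance.
#' @export
combine_organs <- function(rres_a, rres_b, d = 100) {
  ct_a <- peak_cell_type(rres_a); ct_b <- peak_cell_type(rres_b)
  if (!is.na(ct_a) && !is.na(ct_b) && ct_a != ct_b)
    stop("cell-type mismatch between organs: ", ct_a, " vs ", ct_b)
  a <- as_peak_df(rres_a); b <- as_peak_df(rres_b)
  pooled <- rbind(a[intersect(names(a), names(b))],
                  b[intersect(names(a), names(b))])
  if (!nrow(pooled)) return(rre_set(pooled, cell_type = ct_a))
  cen <- peak_centers(pooled)
  comp <- proximity_components(pooled$chrom, cen, d)
  pv <- pooled$p_value %||% rep(NA_real_, nrow(pooled))
  pv[is.na(pv)] <- 1
  ord <- order(comp, pv, pooled$start)
  keep <- ord[!duplicated(comp[ord])]
  out <- pooled[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  prov <- unique(c(
    if (inherits(rres_a, "rre_set")) rres_a$provenance else "organ_a",
    if (inherits(rres_b, "rre_set")) rres_b$provenance else "organ_b"))
  rre_set(out, cell_type = ct_a, provenance = prov)
}

#' Venn partition of RRE sets across cell types
#'
#' Pools the peaks of all sets and forms connected components of the
#' center-proximity graph (same chromosome, center distance <= `d`). Each
#' component is assigned to the combination of cell types represented in it;
#' the returned counts are per-combination component counts and sum to the
#' number of connected components.
#'
#' @param rre_sets named list (>= 2) of `rre_set`s or peak data.frames; names
#'   are the cell-type labels.
#' @param d merge distance in bp.
#' @return named integer vector of component counts, names like
#'   `"SC"`, `"PC&SC"` (labels sorted within a combination).
#' @export
venn_partition <- function(rre_sets, d = 100) {
  if (length(rre_sets) < 2L) stop("venn_partition needs >= 2 sets")
  if (is.null(names(rre_sets)) || any(!nzchar(names(rre_sets))))
    stop("rre_sets must be a named list")
  dfs <- lapply(names(rre_sets), function(nm) {
    df <- as_peak_df(rre_sets[[nm]])
    if (!nrow(df)) return(NULL)
    data.frame(chrom = df$chrom, center = peak_centers(df), set = nm,
               stringsAsFactors = FALSE)
  })
  pooled <- do.call(rbind, dfs)
  if (is.null(pooled) || !nrow(pooled)) return(integer(0))
  comp <- proximity_components(pooled$chrom, pooled$center, d)
  combos <- vapply(split(pooled$set, comp), function(s)
    paste(sort(unique(s)), collapse = "&"), character(1))
  tab <- table(combos)
  stats::setNames(as.integer(tab), names(tab))
}
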