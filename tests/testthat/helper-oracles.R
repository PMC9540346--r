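# Independent brute-force oracles used to freeze expected values. These are
# deliberately naive (exhaustive enumeration, all-pairs scans) and never
# share code with the implementation they check.

# exact two-sided Wilcoxon p by enumeration of all choose(N, n1) group
# assignments (midranks for ties)
oracle_wilcox_exact <- function(x, y) {
  n1 <- length(x); N <- n1 + length(y)
  r <- rank(c(x, y))
  mu <- n1 * (N - n1) / 2
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  subs <- utils::combn(N, n1)
  u_all <- apply(subs, 2L, function(s) sum(r[s]) - n1 * (n1 + 1) / 2)
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# upper-tail hypergeometric by enumeration of every size-n2 subset
oracle_hyper_enum <- function(n, n1, n2, m) {
  set1 <- seq_len(n1)
  subs <- utils::combn(n, n2)
  mean(apply(subs, 2L, function(s) sum(s %in% set1)) >= m)
}

# all-pairs center-distance match oracle
oracle_shared_pairs <- function(a, b, d) {
  ca <- floor((a$start + a$end) / 2); cb <- floor((b$start + b$end) / 2)
  out <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] == b$chrom[j] && abs(ca[i] - cb[j]) <= d)
      out[[length(out) + 1L]] <- c(a$peak_id[i], b$peak_id[j])
  }
  if (!length(out)) return(data.frame(peak_a = character(),
                                      peak_b = character()))
  m <- do.call(rbind, out)
  data.frame(peak_a = m[, 1L], peak_b = m[, 2L], stringsAsFactors = FALSE)
}

# union-find connected components over the pooled proximity graph
oracle_venn <- function(sets, d) {
  pooled <- do.call(rbind, lapply(names(sets), function(nm) {
    s <- sets[[nm]]
    data.frame(chrom = s$chrom,
               center = floor((s$start + s$end) / 2), set = nm,
               stringsAsFactors = FALSE)
  }))
  n <- nrow(pooled)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (pooled$chrom[i] == pooled$chrom[j] &&
        abs(pooled$center[i] - pooled$center[j]) <= d) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  combos <- vapply(split(pooled$set, roots), function(s)
    paste(sort(unique(s)), collapse = "&"), character(1))
  tab <- table(combos)
  stats::setNames(as.integer(tab), names(tab))
}

# all-pairs half-open interval overlap oracle for peak-to-window links
oracle_links <- function(peaks, windows) {
  out <- list()
  for (i in seq_len(nrow(peaks))) for (j in seq_len(nrow(windows))) {
    if (peaks$chrom[i] == windows$chrom[j] &&
        peaks$start[i] < windows$window_end[j] &&
        windows$window_start[j] < peaks$end[i])
      out[[length(out) + 1L]] <- c(peaks$peak_id[i], windows$gene_id[j])
  }
  if (!length(out)) return(data.frame(peak_id = character(),
                                      gene_id = character()))
  m <- do.call(rbind, out)
  data.frame(peak_id = m[, 1L], gene_id = m[, 2L], stringsAsFactors = FALSE)
}

# random peak table on a toy genome
random_peaks <- function(n, chroms = c("chr1", "chr2"), span = 100000L,
                         width_range = c(100L, 400L), prefix = "p") {
  w <- sample(width_range[1L]:width_range[2L], n, replace = TRUE)
  s <- sample.int(span, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = s, end = s + w,
             peak_id = sprintf("%s%04d", prefix, seq_len(n)),
             stringsAsFactors = FALSE)
}

# per-position log-odds rescan oracle for scan_pwm
oracle_scan <- function(sequence, pwm, threshold_fraction, background = 0.25) {
  bases <- c("A", "C", "G", "T")
  w <- ncol(pwm)
  chars <- strsplit(sequence, "")[[1L]]
  score_at <- function(p, pos) {
    s <- 0
    for (j in seq_len(w)) {
      b <- match(chars[pos + j - 1L], bases)
      s <- s + if (is.na(b)) 0 else log2((p[b, j] + 1e-3) / background)
    }
    s
  }
  maxs <- sum(apply(log2((pwm + 1e-3) / background), 2L, max))
  hits <- list()
  for (strand in c("+", "-")) {
    p <- if (strand == "+") pwm else pwm_reverse_complement(pwm)
    for (pos in seq_len(nchar(sequence) - w + 1L)) {
      sc <- score_at(p, pos)
      if (sc >= threshold_fraction * maxs)
        hits[[length(hits) + 1L]] <- data.frame(
          start = pos - 1L, strand = strand, score = sc,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) return(data.frame(start = integer(),
                                       strand = character(),
                                       score = numeric()))
  do.call(rbind, hits)
}

# small deterministic config used across module tests; any field may be
# overridden
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_chromosomes = 4L, chromosome_length = 500000L, n_genes = 40L,
         n_peaks_shared = 60L, n_peaks_emerging_per_celltype = 15L,
         cell_types = c("SC", "HC"), n_cells_per_group = 30L, seed = 7L),
    list(...))
  do.call(synthetic_config, args)
}

random_dna_str <- function(n, gc = 0.4) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
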