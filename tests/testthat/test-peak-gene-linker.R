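# Peak-to-gene linking and hypergeometric enrichment. The enumeration
# oracle walks every size-n2 subset; the log-space tail is also checked
# against R's phyper evaluated in log space (the formula the field uses).

test_that("gene_windows extends, swaps by strand, and clips", {
  sizes <- c(chr1 = 1000000L)
  g <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                  start = 100000L, end = 101000L, tss = 100000L,
                  stringsAsFactors = FALSE)
  w <- gene_windows(g, sizes)
  expect_equal(w$window_start, 50000L)
  expect_equal(w$window_end, 151000L)
  # symmetric extension: strand has no effect
  g2 <- g; g2$strand <- "-"; g2$tss <- 100999L
  expect_equal(gene_windows(g2, sizes)[c("window_start", "window_end")],
               w[c("window_start", "window_end")])
  # asymmetric extension swaps for '-'
  wp <- gene_windows(g, sizes, left = 10000L, right = 2000L)
  wm <- gene_windows(g2, sizes, left = 10000L, right = 2000L)
  expect_equal(wp$window_start, 90000L); expect_equal(wp$window_end, 103000L)
  expect_equal(wm$window_start, 98000L); expect_equal(wm$window_end, 111000L)
  # clipping at chromosome bounds
  g3 <- g; g3$start <- 10000L; g3$end <- 12000L
  expect_equal(gene_windows(g3, sizes)$window_start, 0L)
  expect_error(gene_windows(g, c(chr2 = 100L)), "chromosome size")
})

test_that("link_peaks_to_genes obeys the half-open convention", {
  sizes <- c(chr1 = 1000000L)
  g <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                  start = 100000L, end = 101000L, tss = 100000L,
                  stringsAsFactors = FALSE)
  w <- gene_windows(g, sizes)   # [50000, 151000)
  mk <- function(s, e) data.frame(chrom = "chr1", start = s, end = e,
                                  peak_id = "p1", stringsAsFactors = FALSE)
  expect_equal(nrow(link_peaks_to_genes(mk(149500L, 149600L), w)), 1)
  expect_equal(nrow(link_peaks_to_genes(mk(400000L, 400100L), w)), 0)
  # bookended: peak starting exactly at window end does not overlap
  expect_equal(nrow(link_peaks_to_genes(mk(151000L, 151100L), w)), 0)
  expect_equal(nrow(link_peaks_to_genes(mk(150999L, 151100L), w)), 1)
  # distance sign: peak upstream of a '+' gene is negative (TSS side)
  l_up <- link_peaks_to_genes(mk(60000L, 60100L), w)
  expect_lt(l_up$distance, 0)
  l_dn <- link_peaks_to_genes(mk(120000L, 140000L), w)
  expect_gt(l_dn$distance, 0)     # downstream of the '+' gene body
  l_ov <- link_peaks_to_genes(mk(100500L, 100700L), w)
  expect_equal(l_ov$distance, 0)  # inside the gene body
})

test_that("link_peaks_to_genes equals the all-pairs oracle", {
  set.seed(601)
  sizes <- c(chr1 = 200000L, chr2 = 200000L)
  for (rep in 1:20) {
    genes <- data.frame(
      gene_id = sprintf("g%02d", 1:10),
      chrom = sample(names(sizes), 10, replace = TRUE),
      strand = sample(c("+", "-"), 10, replace = TRUE),
      start = sample.int(150000L, 10), stringsAsFactors = FALSE)
    genes$end <- genes$start + sample(500:5000, 10)
    genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
    w <- gene_windows(genes, sizes, left = 20000L, right = 20000L)
    peaks <- random_peaks(50, chroms = names(sizes), span = 190000L)
    got <- link_peaks_to_genes(peaks, w)
    want <- oracle_links(peaks, w)
    expect_setequal(paste(got$peak_id, got$gene_id),
                    paste(want$peak_id, want$gene_id))
  }
})

test_that("hypergeom_upper_tail matches exhaustive enumeration", {
  # frozen worked examples (verified by the combn oracle)
  expect_equal(oracle_hyper_enum(10, 5, 4, 3), 55 / 210)
  expect_equal(10^hypergeom_upper_tail(10, 5, 4, 3), 55 / 210,
               tolerance = 1e-12)
  expect_equal(oracle_hyper_enum(4, 2, 2, 2), 1 / 6)
  expect_equal(10^hypergeom_upper_tail(4, 2, 2, 2), 1 / 6,
               tolerance = 1e-12)
  expect_equal(hypergeom_upper_tail(100, 10, 20, 0), 0)
  expect_error(hypergeom_upper_tail(10, 3, 4, 5), "min")

  for (n in c(5L, 8L, 11L)) {
    for (n1 in 0:n) for (n2 in 1:n) {
      for (m in 0:min(n1, n2)) {
        expect_equal(10^hypergeom_upper_tail(n, n1, n2, m),
                     oracle_hyper_enum(n, n1, n2, m), tolerance = 1e-9)
      }
    }
  }
})

test_that("log-space tail equals the difference-of-CDF form at moderate p", {
  set.seed(602)
  for (rep in 1:50) {
    n <- sample(50:500, 1)
    n1 <- sample.int(n, 1); n2 <- sample.int(n, 1)
    m <- sample(0:min(n1, n2), 1)
    formula_p <- phyper(min(n1, n2), n1, n - n1, n2) -
      phyper(m - 1, n1, n - n1, n2)
    if (formula_p > 1e-12)
      expect_equal(10^hypergeom_upper_tail(n, n1, n2, m), formula_p,
                   tolerance = 1e-8)
  }
})

test_that("extreme tails stay finite in log space", {
  lp <- hypergeom_upper_tail(25592, 13000, 3000, 3000)
  expect_true(is.finite(lp))
  expect_lte(lp, -300)
  oracle <- phyper(2999, 13000, 25592 - 13000, 3000,
                   lower.tail = FALSE, log.p = TRUE) / log(10)
  expect_equal(lp, oracle, tolerance = 1e-6)
})

test_that("tail is monotone non-increasing in m", {
  for (m in 1:20)
    expect_lte(hypergeom_upper_tail(100, 30, 40, m),
               hypergeom_upper_tail(100, 30, 40, m - 1))
})

test_that("de_gene_rre_enrichment counts and warns correctly", {
  links <- data.frame(peak_id = c("p1", "p2", "p3"),
                      gene_id = c("g1", "g2", "g2"),
                      stringsAsFactors = FALSE)
  universe <- sprintf("g%d", 1:50)
  # disjoint DE set
  r0 <- de_gene_rre_enrichment(c("g10", "g11"), links, universe)
  expect_equal(r0$m, 0); expect_equal(r0$log10_p, 0)
  # overlap of 1
  r1 <- de_gene_rre_enrichment(c("g1", "g10"), links, universe)
  expect_equal(r1$n1, 2); expect_equal(r1$n2, 2); expect_equal(r1$m, 1)
  expect_equal(r1$n, 50)
  # saturation: DE set = universe
  rs <- de_gene_rre_enrichment(universe, links, universe)
  expect_equal(rs$m, rs$n1)
  expect_equal(rs$log10_p, 0)
  # DE gene missing from the universe is excluded with a warning
  expect_warning(de_gene_rre_enrichment(c("g1", "not_a_gene"), links,
                                        universe), "excluded")
})

test_that("cne_overlap_enrichment counts single-base overlaps only", {
  rres <- data.frame(chrom = "chr1", start = c(100L, 500L), end = c(200L, 600L),
                     peak_id = c("r1", "r2"), stringsAsFactors = FALSE)
  # bookended CNE (ends exactly at peak start) must not count
  cnes <- data.frame(chrom = "chr1", start = 50L, end = 100L)
  r <- cne_overlap_enrichment(rres, cnes, "r1")
  expect_equal(r$overlap_count, 0)
  # 1 bp overlap counts
  cnes2 <- data.frame(chrom = "chr1", start = 50L, end = 101L)
  expect_equal(cne_overlap_enrichment(rres, cnes2, "r1")$overlap_count, 1)
  # no CNEs
  r0 <- cne_overlap_enrichment(rres, cnes[0, ], "r1")
  expect_equal(r0$overlap_count, 0)
  expect_equal(r0$enrichment$log10_p, 0)
})

test_that("null DE draws give approximately uniform enrichment p-values", {
  set.seed(603)
  n <- 2000L; n1 <- 500L; n2 <- 200L
  linked <- sprintf("g%04d", 1:n1)
  universe <- sprintf("g%04d", 1:n)
  links <- data.frame(peak_id = paste0("p", seq_len(n1)), gene_id = linked,
                      stringsAsFactors = FALSE)
  pvals <- replicate(500, {
    de <- sample(universe, n2)
    10^de_gene_rre_enrichment(de, links, universe)$log10_p
  })
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
})
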