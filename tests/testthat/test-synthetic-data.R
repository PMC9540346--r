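# Synthetic-data generator: config validation, determinism, packing,
# planted structure, and manifest conservation.

test_that("synthetic_config validates its fields", {
  expect_error(synthetic_config(gc_content = 1.2), "probabilities")
  expect_error(synthetic_config(de_background_rate = -0.1), "probabilities")
  expect_error(synthetic_config(chromosome_length = 5000), "10,000")
  expect_error(synthetic_config(accessibility_fold_change = 0.5), ">= 1")
  expect_error(synthetic_config(cooccur_distance_bp = 120), "<= 90")
})

test_that("make_genome handles empty, bounded and infeasible cases", {
  g0 <- make_genome(synthetic_config(n_chromosomes = 2, n_genes = 0))
  expect_equal(nrow(g0$genes), 0)
  expect_length(g0$chrom_sizes, 2)

  cfg <- synthetic_config(n_genes = 50, chromosome_length = 1000000L,
                          n_chromosomes = 2)
  g <- make_genome(cfg)
  expect_equal(nrow(g$genes), 50)
  expect_true(all(g$genes$start >= 0))
  expect_true(all(g$genes$end <= 1000000L))
  expect_true(all(g$genes$start < g$genes$end))
  # non-overlapping within chromosome
  for (chr in unique(g$genes$chrom)) {
    gg <- g$genes[g$genes$chrom == chr, ]
    gg <- gg[order(gg$start), ]
    if (nrow(gg) > 1) expect_true(all(gg$start[-1] >= head(gg$end, -1)))
  }
  # tss convention
  expect_equal(g$genes$tss,
               ifelse(g$genes$strand == "+", g$genes$start,
                      g$genes$end - 1L))
  # too many genes for the length
  expect_error(make_genome(synthetic_config(n_chromosomes = 1,
                                            n_genes = 20,
                                            chromosome_length = 10000L)),
               "infeasible")
})

test_that("identical config and seed give byte-identical output files", {
  cfg <- tiny_config()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_all(cfg, outdir = d1)
  simulate_all(cfg, outdir = d2)
  files <- list.files(d1)
  expect_true(length(files) >= 10)
  for (f in files) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))),
                 label = paste("md5 of", f))
  }
})

test_that("simulate_peaks_and_counts builds the stated peak universe", {
  cfg <- synthetic_config(n_peaks_shared = 100,
                          n_peaks_emerging_per_celltype = 20,
                          cell_types = "SC", n_cells_per_group = 10,
                          seed = 3)
  g <- make_genome(cfg)
  pk <- simulate_peaks_and_counts(cfg, g)
  expect_equal(nrow(pk$treated_peaks), 120)
  expect_equal(nrow(pk$control_peaks), 100)
  expect_length(pk$truth$emerging_peak_ids$SC, 20)
  expect_equal(dim(pk$counts_treated), c(120, 10))
  # null case: no emerging peaks, fold change 1
  cfg0 <- synthetic_config(n_peaks_shared = 50,
                           n_peaks_emerging_per_celltype = 0,
                           cell_types = "SC",
                           accessibility_fold_change = 1, seed = 3)
  pk0 <- simulate_peaks_and_counts(cfg0, make_genome(cfg0))
  expect_equal(pk0$treated_peaks[c("chrom", "start", "end", "peak_id")],
               pk0$control_peaks[c("chrom", "start", "end", "peak_id")])
  # validation
  badcfg <- synthetic_config(seed = 3)
  badcfg$accessibility_fold_change <- 0.5
  expect_error(simulate_peaks_and_counts(badcfg, g), ">= 1")
})

test_that("make_de_genes limit cases and near-RRE logic", {
  cfg <- tiny_config()
  g <- make_genome(cfg)
  pk <- simulate_peaks_and_counts(cfg, g)

  cfg0 <- tiny_config(de_gene_fraction_near_rre = 0, de_background_rate = 0)
  de0 <- make_de_genes(g, pk$truth, cfg0)
  expect_equal(nrow(de0$de_genes), 0)

  cfg1 <- tiny_config(de_gene_fraction_near_rre = 1, de_background_rate = 0)
  de1 <- make_de_genes(g, pk$truth, cfg1)
  expect_setequal(de1$de_genes$gene_id, de1$truth$genes_near_rre_ids)
  # near set is exactly the genes within 50 kb of an emerging peak
  emg <- pk$truth$emerging_peaks
  near_oracle <- unique(unlist(lapply(seq_len(nrow(g$genes)), function(i) {
    gg <- g$genes[i, ]
    hit <- any(emg$chrom == gg$chrom &
                 emg$start - 50000 < gg$end & gg$start < emg$end + 50000)
    if (hit) gg$gene_id else NULL
  })))
  expect_setequal(de1$truth$genes_near_rre_ids, near_oracle)
})

test_that("make_cnes places the configured overlap fraction", {
  cfg <- tiny_config()
  g <- make_genome(cfg)
  pk <- simulate_peaks_and_counts(cfg, g)
  de <- make_de_genes(g, pk$truth, cfg)
  emg <- pk$truth$emerging_peaks
  overlap_count <- function(cnes) {
    sum(vapply(seq_len(nrow(emg)), function(i) {
      any(cnes$chrom == emg$chrom[i] & cnes$start < emg$end[i] &
            cnes$end > emg$start[i])
    }, logical(1)))
  }
  # fraction 0: nothing overlaps
  c0 <- make_cnes(g, de$truth, tiny_config(cne_overlap_fraction = 0))
  expect_equal(overlap_count(c0$cnes), 0)
  # fraction 1: every emerging peak overlaps a CNE
  c1 <- make_cnes(g, de$truth, tiny_config(cne_overlap_fraction = 1))
  expect_equal(overlap_count(c1$cnes), nrow(emg))
  # fraction 0.5 of 30 emerging peaks -> 15 overlapping, by interval oracle
  chalf <- make_cnes(g, de$truth, tiny_config(cne_overlap_fraction = 0.5))
  expect_equal(length(chalf$truth$cne_overlapping_rre_ids),
               round(0.5 * nrow(emg)))
  expect_equal(overlap_count(chalf$cnes),
               length(chalf$truth$cne_overlapping_rre_ids))
})

test_that("make_sequences plants what the manifest records", {
  cfg <- tiny_config()
  g <- make_genome(cfg)
  pk <- simulate_peaks_and_counts(cfg, g)
  sq <- make_sequences(pk$truth, cfg, n_controls = 20)
  expect_true(all(nchar(sq$positives) == 400))
  expect_true(all(nchar(sq$controls) == 400))
  expect_true(all(grepl("^[ACGT]+$", sq$positives)))
  inst <- sq$truth$planted_motif_instances
  # every planted instance lies inside the central 300 bp
  expect_true(all(inst$start >= 50 & inst$start + 9 <= 350))
  # every referenced sequence id exists
  expect_true(all(inst$sequence_id %in% names(sq$positives)))
  # co-occurring pair distance <= configured limit, per sequence
  pair <- sq$truth$planted_cooccurring_pairs
  for (sid in unique(inst$sequence_id)) {
    si <- inst[inst$sequence_id == sid, ]
    a <- si$start[si$motif_name == pair$motif_name_a]
    b <- si$start[si$motif_name == pair$motif_name_b]
    if (length(a) && length(b))
      expect_lte(abs(a - b), cfg$cooccur_distance_bp)
  }
  # decoys are mutually exclusive within a sequence
  for (sid in unique(inst$sequence_id)) {
    si <- inst[inst$sequence_id == sid, ]
    expect_lte(sum(sq$truth$planted_decoy_pair %in% si$motif_name), 1)
  }
  # zero plant frequency -> pure background positives
  sq0 <- make_sequences(pk$truth, tiny_config(motif_plant_frequency = 0),
                        n_controls = 5)
  expect_equal(nrow(sq0$truth$planted_motif_instances), 0)
})

test_that("plant counts follow the binomial at frequency 0.3", {
  # 1,000 positives at plant frequency 0.3: the number of sequences
  # carrying the pair is Binomial(1000, 0.3); check the 99% interval
  cfg <- synthetic_config(motif_plant_frequency = 0.3, seed = 13)
  truth <- list(emerging_peaks = data.frame(
    chrom = rep("chr1", 1000),
    start = seq(1000, by = 1000, length.out = 1000),
    end = seq(1400, by = 1000, length.out = 1000),
    peak_id = sprintf("emg_%04d", 1:1000),
    stringsAsFactors = FALSE))
  sq <- make_sequences(truth, cfg, n_controls = 5)
  inst <- sq$truth$planted_motif_instances
  n_pair <- sum(inst$motif_name == "soxlike")
  expect_gte(n_pair, qbinom(0.005, 1000, 0.3))
  expect_lte(n_pair, qbinom(0.995, 1000, 0.3))
})
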