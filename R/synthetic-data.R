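# Synthetic-data generator: emits every pipeline input (genome, gene models,
# control/treated peak sets, per-cell count matrices, DE gene table, CNEs,
# and 400 bp positive/control sequence sets with planted PWM instances)
# together with a ground-truth manifest, so every downstream stage can be
# validated by parameter recovery. All coordinates are 0-based half-open.

#' Configuration for the synthetic-data generator
#'
#' Defaults describe a small genome (10 x 2 Mb chromosomes, 150 genes — a
#' gene density leaving a proper subset of peaks outside +/-50 kb gene
#' windows, as in a vertebrate genome) with
#' three inner-ear cell types, Poisson accessibility counts, a regeneration
#' fold change of 4, DE genes enriched near planted emerging peaks, CNEs
#' overlapping half the emerging peaks (preferring DE-linked ones), and
#' sequence elements carrying a co-occurring Sox-like/Six-like motif pair
#' plus mutually exclusive decoy motifs.
#'
#' @param n_chromosomes number of chromosomes (chr1..chrN); the CNN holdout
#'   is the last two.
#' @param chromosome_length length of every chromosome in bp (>= 10,000).
#' @param n_genes total gene count across the genome.
#' @param n_peaks_shared peaks present in both conditions.
#' @param n_peaks_emerging_per_celltype emerging (treated-only) peaks per
#'   cell type.
#' @param cell_types cell-type labels.
#' @param n_cells_per_group cells per condition in the count matrices (>= 2).
#' @param accessibility_rate_background mean Poisson count per cell for an
#'   accessible peak.
#' @param accessibility_fold_change treated/background rate ratio for
#'   emerging peaks (>= 1).
#' @param control_leak_fraction emerging-peak rate in control cells, as a
#'   fraction of background (default 0.05, keeps the rank test
#'   non-degenerate).
#' @param de_gene_fraction_near_rre probability that a gene within 50 kb of
#'   an emerging peak is declared differentially expressed.
#' @param de_background_rate DE probability for all other genes.
#' @param cne_overlap_fraction fraction of emerging peaks given an
#'   overlapping CNE.
#' @param motif_plant_frequency per-positive probability of planting the
#'   co-occurring motif pair (and, independently, one decoy motif).
#' @param cooccur_distance_bp maximum start-to-start distance of the planted
#'   pair (<= 90 so both instances fit one 90 bp receptive field).
#' @param gc_content background GC fraction (order-0 model).
#' @param peak_width_range min/max sampled peak width in bp.
#' @param control_factor control sequences emitted per positive (default 11:
#'   enough for the 10:1 training ratio plus the 1:1 test set).
#' @param seed master seed; every stage derives its own stream from it.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_chromosomes = 10L,
                             chromosome_length = 2000000L,
                             n_genes = 150L,
                             n_peaks_shared = 300L,
                             n_peaks_emerging_per_celltype = 40L,
                             cell_types = c("SC", "PC", "HC"),
                             n_cells_per_group = 60L,
                             accessibility_rate_background = 0.5,
                             accessibility_fold_change = 4,
                             control_leak_fraction = 0.05,
                             de_gene_fraction_near_rre = 0.6,
                             de_background_rate = 0.05,
                             cne_overlap_fraction = 0.5,
                             motif_plant_frequency = 0.9,
                             cooccur_distance_bp = 60L,
                             gc_content = 0.40,
                             peak_width_range = c(200L, 500L),
                             control_factor = 11,
                             seed = 1L) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chromosome_length = as.integer(chromosome_length),
              n_genes = as.integer(n_genes),
              n_peaks_shared = as.integer(n_peaks_shared),
              n_peaks_emerging_per_celltype =
                as.integer(n_peaks_emerging_per_celltype),
              cell_types = as.character(cell_types),
              n_cells_per_group = as.integer(n_cells_per_group),
              accessibility_rate_background = accessibility_rate_background,
              accessibility_fold_change = accessibility_fold_change,
              control_leak_fraction = control_leak_fraction,
              de_gene_fraction_near_rre = de_gene_fraction_near_rre,
              de_background_rate = de_background_rate,
              cne_overlap_fraction = cne_overlap_fraction,
              motif_plant_frequency = motif_plant_frequency,
              cooccur_distance_bp = as.integer(cooccur_distance_bp),
              gc_content = gc_content,
              peak_width_range = as.integer(peak_width_range),
              control_factor = control_factor,
              seed = as.integer(seed))
  probs <- c(de_gene_fraction_near_rre = cfg$de_gene_fraction_near_rre,
             de_background_rate = cfg$de_background_rate,
             cne_overlap_fraction = cfg$cne_overlap_fraction,
             motif_plant_frequency = cfg$motif_plant_frequency,
             gc_content = cfg$gc_content,
             control_leak_fraction = cfg$control_leak_fraction)
  bad <- names(probs)[probs < 0 | probs > 1]
  if (length(bad))
    stop("probabilities must lie in [0, 1]: ", paste(bad, collapse = ", "))
  counts <- c(n_chromosomes = cfg$n_chromosomes, n_genes = cfg$n_genes,
              n_peaks_shared = cfg$n_peaks_shared,
              n_peaks_emerging_per_celltype =
                cfg$n_peaks_emerging_per_celltype,
              n_cells_per_group = cfg$n_cells_per_group)
  if (any(counts < 0)) stop("counts must be >= 0")
  if (cfg$chromosome_length < 10000L)
    stop("chromosome_length must be >= 10,000")
  if (cfg$cooccur_distance_bp > 90L)
    stop("cooccur_distance_bp must be <= 90")
  if (cfg$accessibility_fold_change < 1)
    stop("accessibility_fold_change must be >= 1")
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate the synthetic genome: chromosome sizes and gene models
#'
#' Genes get uniform-random non-overlapping bodies (lengths 1-5 kb, placed by
#' stick-breaking of the free space), random strands, and
#' tss = start ('+') / end - 1 ('-').
#'
#' @param config a [synthetic_config()].
#' @return list with `chrom_sizes` (named integer vector) and `genes`
#'   (data.frame gene_id, chrom, strand, start, end, tss).
#' @export
make_genome <- function(config) {
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  sizes <- stats::setNames(rep(config$chromosome_length,
                               config$n_chromosomes), chroms)
  genes <- with_seed(derive_seed(config$seed, 1L), {
    n <- config$n_genes
    if (n == 0L) {
      data.frame(gene_id = character(), chrom = character(),
                 strand = character(), start = integer(), end = integer(),
                 tss = integer(), stringsAsFactors = FALSE)
    } else {
      per_chrom <- tabulate(rep_len(seq_along(chroms), n),
                            nbins = length(chroms))
      rows <- vector("list", length(chroms))
      gi <- 0L
      for (ci in seq_along(chroms)) {
        k <- per_chrom[ci]
        if (k == 0L) next
        lens <- sample(1000:5000, k, replace = TRUE)
        slack <- config$chromosome_length - sum(lens)
        if (slack < 0)
          stop("infeasible packing: ", k, " genes of total length ",
               sum(lens), " exceed chromosome length ",
               config$chromosome_length)
        cuts <- sort(sample.int(slack + 1L, k, replace = TRUE) - 1L)
        starts <- cuts + c(0L, cumsum(lens[-k]))
        ids <- sprintf("gene_%04d", gi + seq_len(k))
        gi <- gi + k
        rows[[ci]] <- data.frame(
          gene_id = ids, chrom = chroms[ci],
          strand = sample(c("+", "-"), k, replace = TRUE),
          start = as.integer(starts), end = as.integer(starts + lens),
          stringsAsFactors = FALSE)
      }
      out <- do.call(rbind, rows)
      out$tss <- ifelse(out$strand == "+", out$start, out$end - 1L)
      rownames(out) <- NULL
      out
    }
  })
  list(chrom_sizes = sizes, genes = genes)
}

# Rejection-sample peak centers keeping >= min_sep bp from already-placed
# centers on the same chromosome.
#' @noRd
place_centers <- function(n, proposal, existing_chrom, existing_center,
                          min_sep = 250L, max_tries = 2000L) {
  chrom <- character(n); center <- integer(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- proposal()
      near <- existing_chrom == cand$chrom &
        abs(existing_center - cand$center) < min_sep
      if (!any(near)) { ok <- TRUE; break }
    }
    if (!ok) stop("could not place a peak without collisions; ",
                  "genome too dense for the requested peak count")
    chrom[i] <- cand$chrom; center[i] <- cand$center
    existing_chrom <- c(existing_chrom, cand$chrom)
    existing_center <- c(existing_center, cand$center)
  }
  list(chrom = chrom, center = center)
}

#' Simulate peak sets and accessibility count matrices
#'
#' Shared peaks appear in both conditions at the background Poisson rate.
#' Emerging peaks (per cell type) appear only in the treated peak set; in the
#' count matrices treated cells draw them at background x fold_change and
#' control cells at `control_leak_fraction` x background (near-zero, keeping
#' the rank test non-degenerate). 60% of emerging peaks are placed within
#' 50 kb of a gene body so peak-to-gene linkage is recoverable while a
#' proper subset of peaks stays unlinked.
#'
#' @param config a [synthetic_config()].
#' @param genome output of [make_genome()].
#' @return list with `control_peaks`, `treated_peaks` (data.frames),
#'   `counts_control`, `counts_treated` (peaks x cells integer matrices over
#'   the treated peak universe), `peak_stats` (true rates per peak), and
#'   `truth` (manifest; `emerging_peak_ids` per cell type plus the emerging
#'   peak table).
#' @export
simulate_peaks_and_counts <- function(config, genome) {
  if (config$accessibility_fold_change < 1)
    stop("accessibility_fold_change must be >= 1")
  if (config$n_cells_per_group < 2L) stop("need >= 2 cells per group")
  chroms <- names(genome$chrom_sizes)
  L <- config$chromosome_length
  wmin <- config$peak_width_range[1L]; wmax <- config$peak_width_range[2L]
  margin <- wmax %/% 2L + 1L

  placed <- with_seed(derive_seed(config$seed, 2L), {
    uniform_prop <- function() list(chrom = sample(chroms, 1L),
                                    center = sample.int(L - 2L * margin, 1L) + margin)
    sh <- place_centers(config$n_peaks_shared, uniform_prop,
                        character(), integer())
    ex_chrom <- sh$chrom; ex_center <- sh$center
    emg <- list()
    for (ct in config$cell_types) {
      n_e <- config$n_peaks_emerging_per_celltype
      n_near <- ceiling(0.6 * n_e)
      near_prop <- function() {
        g <- genome$genes[sample.int(nrow(genome$genes), 1L), ]
        lo <- max(margin, g$start - 40000L)
        hi <- min(L - margin, g$end + 40000L)
        list(chrom = g$chrom, center = runif_int(lo, hi))
      }
      if (n_near > 0L && nrow(genome$genes) == 0L) {
        n_near <- 0L  # no genes to anchor to; fall back to uniform
      }
      pl_near <- place_centers(n_near, near_prop, ex_chrom, ex_center)
      ex_chrom <- c(ex_chrom, pl_near$chrom)
      ex_center <- c(ex_center, pl_near$center)
      pl_far <- place_centers(n_e - n_near, uniform_prop, ex_chrom, ex_center)
      ex_chrom <- c(ex_chrom, pl_far$chrom)
      ex_center <- c(ex_center, pl_far$center)
      emg[[ct]] <- list(chrom = c(pl_near$chrom, pl_far$chrom),
                        center = c(pl_near$center, pl_far$center))
    }
    widths_sh <- if (config$n_peaks_shared)
      sample(wmin:wmax, config$n_peaks_shared, replace = TRUE) else integer()
    widths_emg <- lapply(emg, function(e)
      if (length(e$center)) sample(wmin:wmax, length(e$center),
                                   replace = TRUE) else integer())
    list(shared = sh, emerging = emg,
         widths_shared = widths_sh, widths_emerging = widths_emg)
  })

  mk_peaks <- function(chrom, center, width, ids, cell_type, condition) {
    start <- as.integer(center - width %/% 2L)
    data.frame(chrom = chrom, start = start,
               end = as.integer(start + width), peak_id = ids,
               cell_type = cell_type, condition = condition,
               stringsAsFactors = FALSE)
  }
  shared <- mk_peaks(placed$shared$chrom, placed$shared$center,
                     placed$widths_shared,
                     sprintf("shared_%04d", seq_len(config$n_peaks_shared)),
                     NA_character_, "shared")
  emerging <- do.call(rbind, lapply(config$cell_types, function(ct) {
    e <- placed$emerging[[ct]]
    if (!length(e$center)) return(NULL)
    mk_peaks(e$chrom, e$center, placed$widths_emerging[[ct]],
             sprintf("emg_%s_%04d", ct, seq_along(e$center)), ct, "treated")
  }))
  control_peaks <- shared
  control_peaks$condition <- "control"
  treated_peaks <- rbind(shared, emerging)
  treated_peaks$condition <- "treated"
  if (is.null(emerging))
    emerging <- shared[0, , drop = FALSE]

  n_cells <- config$n_cells_per_group
  bg <- config$accessibility_rate_background
  fc <- config$accessibility_fold_change
  leak <- config$control_leak_fraction
  is_emg <- treated_peaks$peak_id %in% emerging$peak_id
  lam_ctrl <- ifelse(is_emg, bg * leak, bg)
  lam_trt <- ifelse(is_emg, bg * fc, bg)

  counts <- with_seed(derive_seed(config$seed, 3L), {
    np <- nrow(treated_peaks)
    cc <- matrix(stats::rpois(np * n_cells, rep(lam_ctrl, n_cells)),
                 nrow = np, ncol = n_cells)
    ct <- matrix(stats::rpois(np * n_cells, rep(lam_trt, n_cells)),
                 nrow = np, ncol = n_cells)
    dimnames(cc) <- list(treated_peaks$peak_id,
                         sprintf("ctrl_%03d", seq_len(n_cells)))
    dimnames(ct) <- list(treated_peaks$peak_id,
                         sprintf("trt_%03d", seq_len(n_cells)))
    list(control = cc, treated = ct)
  })

  truth <- list(
    emerging_peak_ids = lapply(stats::setNames(config$cell_types,
                                               config$cell_types),
                               function(ct)
                                 emerging$peak_id[emerging$cell_type == ct]),
    emerging_peaks = emerging
  )
  peak_stats <- data.frame(peak_id = treated_peaks$peak_id,
                           chrom = treated_peaks$chrom,
                           start = treated_peaks$start,
                           end = treated_peaks$end,
                           cell_type = treated_peaks$cell_type,
                           lambda_control = lam_ctrl,
                           lambda_treated = lam_trt,
                           stringsAsFactors = FALSE)
  list(control_peaks = control_peaks, treated_peaks = treated_peaks,
       counts_control = counts$control, counts_treated = counts$treated,
       peak_stats = peak_stats, truth = truth)
}

# Genes whose body lies within `dist` bp of any emerging peak interval.
#' @noRd
genes_near_peaks <- function(genes, peaks, dist = 50000L) {
  if (!nrow(genes) || is.null(peaks) || !nrow(peaks)) return(character())
  gr <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start + 1L, genes$end))
  pr <- GenomicRanges::GRanges(
    peaks$chrom,
    IRanges::IRanges(pmax(0L, peaks$start - dist) + 1L, peaks$end + dist))
  hit <- GenomicRanges::countOverlaps(gr, pr, ignore.strand = TRUE) > 0L
  genes$gene_id[hit]
}

#' Declare differentially expressed genes
#'
#' Genes within 50 kb of a planted emerging peak become DE with probability
#' `de_gene_fraction_near_rre`; all other genes with `de_background_rate`.
#' DE p-values and fold changes are cosmetic draws (the enrichment stage only
#' uses membership).
#'
#' @param genome output of [make_genome()].
#' @param truth manifest from [simulate_peaks_and_counts()] (updated and
#'   returned).
#' @param config a [synthetic_config()].
#' @return list with `de_genes` (data.frame gene_id, p_value, avg_log2FC)
#'   and the updated `truth` (gains `de_gene_ids`, `genes_near_rre_ids`).
#' @export
make_de_genes <- function(genome, truth, config) {
  genes <- genome$genes
  if (!nrow(genes)) stop("genome has no genes")
  near <- genes_near_peaks(genes, truth$emerging_peaks)
  de <- with_seed(derive_seed(config$seed, 4L), {
    is_near <- genes$gene_id %in% near
    p_de <- ifelse(is_near, config$de_gene_fraction_near_rre,
                   config$de_background_rate)
    sel <- stats::runif(nrow(genes)) < p_de
    ids <- genes$gene_id[sel]
    data.frame(gene_id = ids,
               p_value = stats::runif(length(ids), 1e-6, 0.009),
               avg_log2FC = sample(c(-1, 1), length(ids), replace = TRUE) *
                 stats::runif(length(ids), 0.5, 3),
               stringsAsFactors = FALSE)
  })
  truth$de_gene_ids <- de$gene_id
  truth$genes_near_rre_ids <- near
  list(de_genes = de, truth = truth)
}

#' Place conserved non-coding elements
#'
#' `round(cne_overlap_fraction * n_emerging)` emerging peaks receive a CNE
#' overlapping them by >= 1 bp; DE-linked emerging peaks (within 50 kb of a
#' DE gene) are chosen first, emulating conservation concentrating on
#' functional enhancers. The remaining CNEs are placed in peak-free
#' background.
#'
#' @param genome output of [make_genome()].
#' @param truth manifest carrying `emerging_peaks` and (if [make_de_genes()]
#'   ran) `de_gene_ids`.
#' @param config a [synthetic_config()].
#' @param cne_length CNE length in bp.
#' @return list with `cnes` (data.frame chrom, start, end, name) and updated
#'   `truth` (gains `cne_overlapping_rre_ids`).
#' @export
make_cnes <- function(genome, truth, config, cne_length = 150L) {
  emg <- truth$emerging_peaks
  if (is.null(emg) || !nrow(emg)) stop("no emerging peaks in the manifest")
  n_total <- nrow(emg)
  n_overlap <- round(config$cne_overlap_fraction * n_total)
  de_genes <- genome$genes[genome$genes$gene_id %in%
                             (truth$de_gene_ids %||% character()), ,
                           drop = FALSE]
  de_linked <- if (nrow(de_genes))
    emg$peak_id[emg$peak_id %in% with( # peaks within 50 kb of a DE gene
      list(pr = GenomicRanges::GRanges(
        emg$chrom, IRanges::IRanges(emg$start + 1L, emg$end)),
        gr = GenomicRanges::GRanges(
          de_genes$chrom,
          IRanges::IRanges(pmax(0L, de_genes$start - 50000L) + 1L,
                           de_genes$end + 50000L))),
      emg$peak_id[GenomicRanges::countOverlaps(pr, gr,
                                               ignore.strand = TRUE) > 0L])]
  else character()

  res <- with_seed(derive_seed(config$seed, 5L), {
    pool1 <- intersect(emg$peak_id, de_linked)
    pool2 <- setdiff(emg$peak_id, de_linked)
    take1 <- min(length(pool1), n_overlap)
    chosen <- c(if (take1) sample(pool1, take1) else character(),
                if (n_overlap - take1 > 0)
                  sample(pool2, n_overlap - take1) else character())
    rows <- emg[match(chosen, emg$peak_id), , drop = FALSE]
    ov <- if (nrow(rows)) {
      s <- vapply(seq_len(nrow(rows)), function(i) {
        lo <- max(0L, rows$start[i] - cne_length + 1L)
        hi <- rows$end[i] - 1L
        runif_int(lo, hi)
      }, integer(1))
      data.frame(chrom = rows$chrom, start = s,
                 end = as.integer(s + cne_length),
                 name = sprintf("cne_ov_%04d", seq_len(nrow(rows))),
                 stringsAsFactors = FALSE)
    } else NULL
    n_bg <- n_total - n_overlap
    bg <- if (n_bg > 0) {
      all_peaks <- rbind(emg[c("chrom", "start", "end")],
                         data.frame(chrom = character(), start = integer(),
                                    end = integer()))
      starts <- integer(n_bg); chrs <- character(n_bg)
      for (i in seq_len(n_bg)) {
        for (try in seq_len(2000L)) {
          chr <- sample(names(genome$chrom_sizes), 1L)
          s <- sample.int(config$chromosome_length - cne_length, 1L)
          clash <- all_peaks$chrom == chr &
            all_peaks$start - 100L < s + cne_length &
            all_peaks$end + 100L > s
          if (!any(clash)) break
          if (try == 2000L) stop("could not place background CNE")
        }
        starts[i] <- s; chrs[i] <- chr
      }
      data.frame(chrom = chrs, start = starts,
                 end = as.integer(starts + cne_length),
                 name = sprintf("cne_bg_%04d", seq_len(n_bg)),
                 stringsAsFactors = FALSE)
    } else NULL
    list(cnes = rbind(ov, bg), chosen = chosen)
  })
  truth$cne_overlapping_rre_ids <- res$chosen
  cnes <- res$cnes
  if (is.null(cnes))
    cnes <- data.frame(chrom = character(), start = integer(),
                       end = integer(), name = character(),
                       stringsAsFactors = FALSE)
  rownames(cnes) <- NULL
  list(cnes = cnes, truth = truth)
}

#' @noRd
random_dna <- function(n_bases, gc) {
  sample(c("A", "C", "G", "T"), n_bases, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' @noRd
draw_motif_instance <- function(pwm) {
  bases <- rownames(pwm)
  paste0(vapply(seq_len(ncol(pwm)), function(j)
    sample(bases, 1L, prob = pwm[, j]), character(1)), collapse = "")
}

#' Generate 400 bp positive and control sequence elements
#'
#' One positive per emerging peak (the 400 bp element centered on it); ids
#' encode the synthetic chromosome (`<peak_id>|<chrom>`) so a
#' chromosome-based holdout is possible. With probability
#' `motif_plant_frequency` a positive receives the co-occurring Sox-like /
#' Six-like pair at start-to-start distance <= `cooccur_distance_bp`, and
#' (independently, same frequency) exactly one of the two decoy motifs —
#' never both, making the decoy pair structurally non-co-occurring. All
#' instances are planted inside the central 300 bp (offsets [50, 350) of the
#' element). Controls are pure order-0 background at the configured GC.
#'
#' @param truth manifest carrying `emerging_peaks`.
#' @param config a [synthetic_config()].
#' @param motif_library named list of PWMs; must contain the planted motifs.
#' @param pair planted co-occurring motif names (length 2).
#' @param decoys mutually exclusive decoy motif names (length 2).
#' @param n_controls number of control elements (default
#'   `round(control_factor * n_positives)`).
#' @return list with `positives`, `controls` (named character vectors of
#'   400 nt sequences) and updated `truth` (gains `planted_motif_instances`,
#'   `planted_cooccurring_pairs`, `planted_decoy_pair`).
#' @export
make_sequences <- function(truth, config,
                           motif_library = default_motif_library(),
                           pair = c("soxlike", "sixlike"),
                           decoys = c("foxlike", "gatalike"),
                           n_controls = NULL) {
  emg <- truth$emerging_peaks
  if (is.null(emg) || !nrow(emg)) stop("no emerging peaks in the manifest")
  needed <- c(pair, decoys)
  miss <- setdiff(needed, names(motif_library))
  if (length(miss))
    stop("motif_library is missing planted motif(s): ",
         paste(miss, collapse = ", "))
  n_pos <- nrow(emg)
  n_controls <- n_controls %||% round(config$control_factor * n_pos)
  elem_len <- 400L
  inner_lo <- 50L  # 0-based; plants allowed in [50, 350)
  gc <- config$gc_content

  out <- with_seed(derive_seed(config$seed, 6L), {
    pos_ids <- paste0(emg$peak_id, "|", emg$chrom)
    mat <- matrix(random_dna(elem_len * n_pos, gc), nrow = elem_len)
    instances <- vector("list", n_pos)
    for (i in seq_len(n_pos)) {
      planted <- list()  # (name, start, width, strand)
      occupied <- matrix(integer(0), ncol = 2L)
      plant_one <- function(name, start) {
        pwm <- motif_library[[name]]
        strand <- sample(c("+", "-"), 1L)
        inst <- draw_motif_instance(
          if (strand == "+") pwm else pwm_reverse_complement(pwm))
        mat[start + seq_len(nchar(inst)), i] <<-
          strsplit(inst, "")[[1L]]
        planted[[length(planted) + 1L]] <<-
          list(name = name, start = start, width = nchar(inst),
               strand = strand)
      }
      overlaps_any <- function(start, width) {
        if (!length(planted)) return(FALSE)
        any(vapply(planted, function(p)
          start < p$start + p$width && p$start < start + width,
          logical(1)))
      }
      if (stats::runif(1) < config$motif_plant_frequency) {
        wA <- ncol(motif_library[[pair[1L]]])
        wB <- ncol(motif_library[[pair[2L]]])
        delta <- runif_int(max(wA, wB), config$cooccur_distance_bp)
        left_first <- sample(c(TRUE, FALSE), 1L)
        s_left <- runif_int(inner_lo, 350L - delta - max(wA, wB))
        if (left_first) {
          plant_one(pair[1L], s_left); plant_one(pair[2L], s_left + delta)
        } else {
          plant_one(pair[2L], s_left); plant_one(pair[1L], s_left + delta)
        }
      }
      if (stats::runif(1) < config$motif_plant_frequency) {
        dk <- sample(decoys, 1L)
        wD <- ncol(motif_library[[dk]])
        placed <- FALSE
        for (try in seq_len(100L)) {
          s <- runif_int(inner_lo, 350L - wD)
          if (!overlaps_any(s, wD)) {
            plant_one(dk, s); placed <- TRUE; break
          }
        }
        if (!placed) stop("planting collision persisted after 100 retries")
      }
      instances[[i]] <- if (length(planted))
        data.frame(sequence_id = pos_ids[i],
                   motif_name = vapply(planted, `[[`, character(1), "name"),
                   start = vapply(planted, `[[`, integer(1), "start"),
                   strand = vapply(planted, `[[`, character(1), "strand"),
                   stringsAsFactors = FALSE)
      else NULL
    }
    positives <- stats::setNames(
      vapply(seq_len(n_pos), function(i)
        paste0(mat[, i], collapse = ""), character(1)), pos_ids)
    ctrl_chrom <- sample(paste0("chr", seq_len(config$n_chromosomes)),
                         n_controls, replace = TRUE)
    cmat <- matrix(random_dna(elem_len * n_controls, gc), nrow = elem_len)
    controls <- stats::setNames(
      vapply(seq_len(n_controls), function(i)
        paste0(cmat[, i], collapse = ""), character(1)),
      sprintf("ctrl_%05d|%s", seq_len(n_controls), ctrl_chrom))
    list(positives = positives, controls = controls,
         instances = do.call(rbind, instances))
  })
  truth$planted_motif_instances <- out$instances %||%
    data.frame(sequence_id = character(), motif_name = character(),
               start = integer(), strand = character(),
               stringsAsFactors = FALSE)
  truth$planted_cooccurring_pairs <-
    data.frame(motif_name_a = pair[1L], motif_name_b = pair[2L],
               stringsAsFactors = FALSE)
  truth$planted_decoy_pair <- decoys
  list(positives = out$positives, controls = out$controls, truth = truth)
}

#' Run the full synthetic-data generator
#'
#' Chains [make_genome()], [simulate_peaks_and_counts()], [make_de_genes()],
#' [make_cnes()] and [make_sequences()] under one config, optionally writing
#' every output file (see [write_simulation()]).
#'
#' @param config a [synthetic_config()].
#' @param outdir if non-NULL, write all outputs there.
#' @param motif_library PWMs for sequence planting.
#' @return list with genome, peaks/counts, de_genes, cnes, sequences and the
#'   completed `truth` manifest.
#' @export
simulate_all <- function(config = synthetic_config(), outdir = NULL,
                         motif_library = default_motif_library()) {
  genome <- make_genome(config)
  pk <- simulate_peaks_and_counts(config, genome)
  de <- make_de_genes(genome, pk$truth, config)
  cn <- make_cnes(genome, de$truth, config)
  sq <- make_sequences(cn$truth, config, motif_library)
  sim <- list(config = config, genome = genome,
              control_peaks = pk$control_peaks,
              treated_peaks = pk$treated_peaks,
              counts_control = pk$counts_control,
              counts_treated = pk$counts_treated,
              peak_stats = pk$peak_stats,
              de_genes = de$de_genes, cnes = cn$cnes,
              positives = sq$positives, controls = sq$controls,
              truth = sq$truth)
  if (!is.null(outdir)) write_simulation(sim, outdir)
  sim
}

#' Write a simulation to disk
#'
#' Emits genome.sizes, genes.gtf, peaks_control.bed / peaks_treated.bed,
#' peak_stats.tsv, counts_control.tsv / counts_treated.tsv (triplet),
#' cell_groups.tsv, de_genes.tsv, cnes.bed, positives.fa / controls.fa and
#' truth.json. Identical config and seed give byte-identical files.
#'
#' @param sim output of [simulate_all()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(outdir, x)
  write_chrom_sizes(sim$genome$chrom_sizes, fp("genome.sizes"))
  write_gtf_genes(sim$genome$genes, fp("genes.gtf"))
  write_bed(data.frame(chrom = sim$control_peaks$chrom,
                       start = sim$control_peaks$start,
                       end = sim$control_peaks$end,
                       name = sim$control_peaks$peak_id),
            fp("peaks_control.bed"))
  write_bed(data.frame(chrom = sim$treated_peaks$chrom,
                       start = sim$treated_peaks$start,
                       end = sim$treated_peaks$end,
                       name = sim$treated_peaks$peak_id),
            fp("peaks_treated.bed"))
  utils::write.table(sim$peak_stats, fp("peak_stats.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_counts_triplet(sim$counts_control, fp("counts_control.tsv"))
  write_counts_triplet(sim$counts_treated, fp("counts_treated.tsv"))
  groups <- data.frame(
    cell_id = c(colnames(sim$counts_control), colnames(sim$counts_treated)),
    group = rep(c("control", "treated"),
                c(ncol(sim$counts_control), ncol(sim$counts_treated))),
    stringsAsFactors = FALSE)
  utils::write.table(groups, fp("cell_groups.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$de_genes, fp("de_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_bed(sim$cnes, fp("cnes.bed"))
  write_fasta(sim$positives, fp("positives.fa"))
  write_fasta(sim$controls, fp("controls.fa"))
  jsonlite::write_json(sim$truth, fp("truth.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(outdir)
}
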