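# CNN module: encoding, fixed architecture, datasets, receptive fields,
# PWM matching, and a small training smoke test. Heavy recovery runs live
# in test-acceptance.R.

ns <- asNamespace("regenhancer")

revcomp_chr <- function(s) chartr("ACGT", "TGCA",
                                  vapply(strsplit(s, ""), function(x)
                                    paste(rev(x), collapse = ""), ""))

test_that("one_hot_encode crops, orders rows and zeroes N", {
  m <- one_hot_encode(strrep("A", 400))
  expect_equal(dim(m), c(4L, 300L))
  expect_true(all(m["A", ] == 1))
  expect_true(all(m[c("C", "G", "T"), ] == 0))
  s <- paste0(strrep("C", 50), strrep("G", 10), "N",
              strrep("T", 289), strrep("C", 50))
  m2 <- one_hot_encode(s)
  expect_equal(unname(colSums(m2)), c(rep(1, 10), 0, rep(1, 289)))
  expect_error(one_hot_encode(strrep("A", 399)), "400")
  # reverse complement = row swap + column reversal
  set.seed(701)
  for (rep in 1:5) {
    sq <- random_dna_str(400)
    a <- one_hot_encode(sq)
    # note: the RC of the full 400-mer crops to the RC of the cropped window
    b <- one_hot_encode(revcomp_chr(sq))
    expect_equal(unname(b), unname(a[c("T", "G", "C", "A"), 300:1]))
  }
})

test_that("build_model has exactly the printed parameter budget", {
  m <- build_model(seed = 1)
  expect_equal(count_parameters(m), 59785L)
  sz <- vapply(m$params, length, integer(1))
  # per-layer counts from k*C_in*C_out + C_out and in*out + out arithmetic
  expect_equal(unname(sz["W1"] + sz["b1"]), 9 * 4 * 64 + 64)       # 2,368
  expect_equal(unname(sz["W2"] + sz["b2"]), 5 * 64 * 64 + 64)      # 20,544
  expect_equal(unname(sz["W3"] + sz["b3"]), 5 * 64 * 64 + 64)      # 20,544
  expect_equal(unname(sz["W4"] + sz["b4"]), 5 * 64 * 8 + 8)        # 2,568
  expect_equal(unname(sz["W5"] + sz["b5"]), 8 * 1376 + 1376)       # 12,384
  expect_equal(unname(sz["W6"] + sz["b6"]), 1376 + 1)              # 1,377
  # spec deviation errors name the differing layer
  bad <- model_spec(); bad$conv1 <- c(filters = 32L, kernel = 9L, stride = 3L)
  expect_error(build_model(bad), "conv1")
  # zero weights: sigmoid(0) = 0.5 everywhere
  mz <- build_model(zero_weights = TRUE)
  expect_equal(predict(mz, c(strrep("A", 400), random_dna_str(400))),
               c(0.5, 0.5))
})

test_that("make_datasets builds 10:1 / 1:1 chromosome-holdout splits", {
  set.seed(702)
  pos <- stats::setNames(replicate(100, random_dna_str(400)),
                         sprintf("p%03d|chr%d", 1:100, rep(1:10, each = 10)))
  ctl <- stats::setNames(replicate(1200, random_dna_str(400)),
                         sprintf("c%04d|chr%d", 1:1200, rep(1:10, 120)))
  ds <- make_datasets(pos, ctl, seed = 1)
  expect_equal(ds$holdout_chroms, c("chr9", "chr10"))
  expect_equal(sum(ds$train$y), 80)          # non-holdout positives
  expect_equal(sum(ds$train$y == 0), 800)    # 10x controls
  expect_equal(sum(ds$test$y), 20)
  expect_equal(sum(ds$test$y == 0), 20)      # 1x controls
  expect_length(intersect(names(ds$train$x), names(ds$test$x)), 0)
  # no positives on holdout chromosomes -> error
  expect_error(make_datasets(pos[1:10], ctl, holdout_chroms = "chr5"),
               "holdout")
  # insufficient controls -> sample with replacement, with a message
  expect_message(make_datasets(pos, ctl[1:200], seed = 1), "replacement")
})

test_that("conv3 receptive fields are 90 bp with jump 12", {
  expect_equal(unname(conv3_receptive_field(0)), c(0L, 90L))
  expect_equal(unname(conv3_receptive_field(17)), c(204L, 294L))
  for (u in 1:17)
    expect_equal(conv3_receptive_field(u)["start"] -
                   conv3_receptive_field(u - 1)["start"],
                 c(start = 12L))
  expect_error(conv3_receptive_field(18), "0..17")
  expect_error(conv3_receptive_field(-1), "0..17")
})

test_that("analytic receptive field matches empirical gradient support", {
  # all-positive weights and a large input perturbation: a conv3 unit
  # changes iff its analytic field covers the perturbed position
  m <- build_model(seed = 3)
  params <- lapply(m$params, function(p) abs(p) + 0.01)
  params$b1 <- numeric(64); params$b2 <- numeric(64)
  params$b3 <- numeric(64); params$b4 <- numeric(8)
  base_codes <- matrix(1L, 300L, 1L)   # poly-A core
  X0 <- ns$codes_to_onehot(base_codes)
  z0 <- ns$cnn_forward(params, X0, m$idx, keep_cache = TRUE)$Z3
  analytic <- vapply(0:17, function(u) conv3_receptive_field(u),
                     integer(2))
  for (p0 in c(0L, 1L, 7L, 89L, 90L, 150L, 293L, 294L, 299L)) {
    X <- X0
    X[(p0 * 4L) + 2L, 1L] <- 100    # large bump on base C at position p0
    z <- ns$cnn_forward(params, X, m$idx, keep_cache = TRUE)$Z3
    changed <- which(apply(abs(matrix(z - z0, 64L, 18L)) > 1e-9, 2L, any)) - 1L
    expected <- which(analytic[1L, ] <= p0 & p0 < analytic[2L, ]) - 1L
    expect_equal(changed, expected, label = paste("position", p0))
  }
})

test_that("pwm_similarity and match_known_motifs behave at the limits", {
  lib <- default_motif_library()
  sox <- lib$soxlike
  expect_equal(pwm_similarity(sox, sox)$score, 1, tolerance = 1e-12)
  rc <- pwm_reverse_complement(sox)
  s <- pwm_similarity(sox, rc)
  expect_equal(s$score, 1, tolerance = 1e-12)
  expect_equal(s$strand, "-")
  # distinct library motifs are not near-identical
  for (a in names(lib)) for (b in names(lib))
    if (a != b)
      expect_lt(pwm_similarity(lib[[a]], lib[[b]])$score, 0.8)
  # uniform PWM: undefined correlations handled as score 0
  unif <- matrix(0.25, 4, 9, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(pwm_similarity(unif, sox)$score, 0)

  denovo <- list(list(filter_index = 1L, pwm = sox, n_sites = 50L))
  mm <- match_known_motifs(denovo, lib, n_null = 200, seed = 4)
  expect_true("soxlike" %in% mm$known_id)
  expect_true(all(mm$p_value < 1e-5))
  best <- mm[mm$best, ]
  expect_equal(best$known_id, "soxlike")
  expect_error(match_known_motifs(denovo, list()), "empty")
})

test_that("extract_denovo_motifs caps, normalizes and needs a live model", {
  cfg <- tiny_config(n_peaks_emerging_per_celltype = 30, cell_types = "SC")
  g <- make_genome(cfg)
  pk <- simulate_peaks_and_counts(cfg, g)
  sq <- make_sequences(pk$truth, cfg, n_controls = 10)
  m <- build_model(seed = 5)
  mot <- extract_denovo_motifs(m, sq$positives, min_sites = 1L)
  expect_lte(length(mot), 64)
  for (mo in mot) {
    expect_equal(unname(colSums(mo$pwm)), rep(1, 9), tolerance = 1e-9)
    expect_gte(mo$n_sites, 1)
  }
  # activation_fraction = 1: only argmax windows contribute
  mot1 <- extract_denovo_motifs(m, sq$positives, activation_fraction = 1,
                                min_sites = 1L)
  n1 <- vapply(mot1, `[[`, integer(1), "n_sites")
  n0 <- vapply(mot, `[[`, integer(1), "n_sites")
  expect_true(all(n1 >= 1))
  shared <- intersect(vapply(mot1, `[[`, integer(1), "filter_index"),
                      vapply(mot, `[[`, integer(1), "filter_index"))
  f1 <- vapply(mot1, `[[`, integer(1), "filter_index")
  f0 <- vapply(mot, `[[`, integer(1), "filter_index")
  expect_true(all(n1[match(shared, f1)] <= n0[match(shared, f0)]))
  # zero model: no positive activation anywhere
  mz <- build_model(zero_weights = TRUE)
  expect_error(extract_denovo_motifs(mz, sq$positives), "untrained")
})

test_that("detect_cooccurrence output is structural and validated", {
  m <- build_model(seed = 6)
  seqs <- stats::setNames(replicate(8, random_dna_str(400)), paste0("s", 1:8))
  mot <- extract_denovo_motifs(m, seqs, min_sites = 1L)[1:4]
  co <- detect_cooccurrence(m, mot, seqs, seqs)
  expect_true(all(co$motif_a < co$motif_b))
  expect_equal(nrow(co), choose(4, 2))
  expect_true(all(co$p_value >= 0 & co$p_value <= 1))
  # significance requires a higher positive rate, not just a small p
  expect_true(all(!co$significant |
                    co$count_pos / co$n_pos > co$count_bg / co$n_bg))
  expect_error(detect_cooccurrence(m, mot, seqs, character()), "empty")
})

test_that("training runs, is deterministic, and fails on a shuffled null", {
  cfg <- tiny_config(n_peaks_emerging_per_celltype = 40, cell_types = "SC",
                     n_chromosomes = 5, seed = 21)
  g <- make_genome(cfg)
  pk <- simulate_peaks_and_counts(cfg, g)
  sq <- make_sequences(pk$truth, cfg, n_controls = 440)
  ds <- make_datasets(sq$positives, sq$controls, seed = 21)
  hp <- default_hyperparams(epochs = 2, batch_size = 64, patience = 2)
  m <- build_model(seed = 21)
  t1 <- train_model(m, ds, hp, seed = 21)
  t2 <- train_model(build_model(seed = 21), ds, hp, seed = 21)
  expect_equal(t1$history$train_loss, t2$history$train_loss)  # determinism
  expect_equal(t1$history$val_loss, t2$history$val_loss)
  expect_true(all(is.finite(t1$history$train_loss)))
  expect_gte(nrow(t1$history), 1)
  # label-shuffled data: AUROC stays near chance
  ds_null <- ds
  set.seed(22)
  ds_null$train$y <- sample(ds_null$train$y)
  tn <- train_model(build_model(seed = 21), ds_null, hp, seed = 21)
  expect_gte(tn$test_auroc, 0.35)
  expect_lte(tn$test_auroc, 0.65)
})
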