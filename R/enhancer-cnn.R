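# Public API of the enhancer sequence classifier: the fixed 4-conv-layer
# architecture (59,785 trainable parameters), chromosome-holdout datasets
# with 10:1 controls, training, first-layer de novo motif extraction,
# PWM-vs-PWM matching against a known library, and third-layer
# receptive-field motif co-occurrence testing.

#' The fixed model architecture
#'
#' Input 4 x 300 one-hot (central 300 bp of a 400 bp element); conv1 64
#' filters kernel 9 stride 3; max pool k2 s2; conv2/conv3 64 filters kernel
#' 5; each followed by max pool k2 s2; conv4 8 filters kernel 5; global max
#' pool; dense 8 -> 1376; dense 1376 -> 1 with sigmoid; ReLU activations,
#' biases everywhere, no normalization layers. Total trainable parameters:
#' 59,785.
#'
#' @return list describing each layer; pass to [build_model()].
#' @export
model_spec <- function() {
  list(input = c(4L, 300L),
       conv1 = c(filters = 64L, kernel = 9L, stride = 3L),
       pool1 = c(k = 2L, s = 2L),
       conv2 = c(filters = 64L, kernel = 5L, stride = 1L),
       pool2 = c(k = 2L, s = 2L),
       conv3 = c(filters = 64L, kernel = 5L, stride = 1L),
       pool3 = c(k = 2L, s = 2L),
       conv4 = c(filters = 8L, kernel = 5L, stride = 1L),
       global_pool = "max",
       dense1 = 1376L,
       dense2 = 1L)
}

#' Build the (untrained) enhancer classifier
#'
#' @param spec architecture description; must equal [model_spec()] — any
#'   deviation raises an error naming the differing layer(s).
#' @param seed RNG seed for He-gaussian weight initialization.
#' @param zero_weights start from all-zero parameters (then the sigmoid
#'   output is exactly 0.5 for any input; useful for tests).
#' @return object of class `enhancer_cnn`.
#' @export
build_model <- function(spec = model_spec(), seed = 1L,
                        zero_weights = FALSE) {
  ref <- model_spec()
  diffs <- names(ref)[!vapply(names(ref), function(nm)
    identical(unname(spec[[nm]]), unname(ref[[nm]])) ||
      identical(spec[[nm]], ref[[nm]]), logical(1))]
  if (length(diffs))
    stop("model spec deviates from the fixed architecture in layer(s): ",
         paste(diffs, collapse = ", "))
  params <- with_seed(seed, cnn_init_params(zero = zero_weights))
  structure(list(spec = ref, params = params, idx = cnn_indices(),
                 trained = FALSE, seed = seed),
            class = "enhancer_cnn")
}

#' Count trainable parameters of the model
#' @param model an `enhancer_cnn`.
#' @return integer total of weights plus biases.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' @export
print.enhancer_cnn <- function(x, ...) {
  cat(sprintf("<enhancer_cnn> 4 conv layers, %d trainable parameters, %s\n",
              count_parameters(x),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' One-hot encode the central 300 bp of a 400 bp element
#'
#' Rows are ordered A, C, G, T; the 50 bp at each end are excluded
#' (positions 50..349, 0-based); N (or any non-ACGT) becomes an all-zero
#' column.
#'
#' @param sequence a single 400 nt string.
#' @return 4 x 300 numeric matrix with rownames A, C, G, T.
#' @export
one_hot_encode <- function(sequence) {
  codes <- encode_codes(sequence)
  m <- matrix(0, 4L, 300L, dimnames = list(c("A", "C", "G", "T"), NULL))
  keep <- codes[, 1L] > 0L
  m[cbind(codes[keep, 1L], which(keep))] <- 1
  m
}

#' Predict enhancer probability for 400 bp elements
#'
#' With `tta = TRUE` the probability is averaged over six views of each
#' element (crop shifts of -12/0/+12 bp x both strands) — the same
#' invariances used as training augmentation.
#'
#' @param object an `enhancer_cnn`.
#' @param sequences character vector of 400 nt sequences.
#' @param batch_size forward-pass batch size.
#' @param tta average over shifted/reverse-complemented views.
#' @param ... unused.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predict.enhancer_cnn <- function(object, sequences, batch_size = 256L,
                                 tta = FALSE, ...) {
  run <- function(codes) {
    n <- ncol(codes)
    out <- numeric(n)
    for (s in seq(1L, n, by = batch_size)) {
      e <- min(n, s + batch_size - 1L)
      X <- codes_to_onehot(codes[, s:e, drop = FALSE])
      out[s:e] <- cnn_forward(object$params, X, object$idx)$prob
    }
    out
  }
  if (!tta) return(run(encode_codes(sequences)))
  full <- encode_codes(sequences, crop = FALSE)
  acc <- 0
  for (off in c(-12L, 0L, 12L)) {
    view <- full[(51L + off):(350L + off), , drop = FALSE]
    acc <- acc + run(view) + run(rc_codes(view))
  }
  acc / 6
}

#' @noRd
element_chrom <- function(ids) {
  sub("^.*\\|", "", ids)
}

#' Split elements into chromosome-holdout train/test sets
#'
#' Training set: positives from all chromosomes except the holdout plus
#' `ratio_train`-fold (10x) controls; test set: holdout positives plus
#' `ratio_test`-fold (1x) controls. Sequence ids must encode their
#' chromosome as `...|chrN`. Test controls are reserved first; if the pool
#' cannot cover the 10x training demand, training controls are sampled with
#' replacement (with a message).
#'
#' @param positives,controls named character vectors of 400 nt sequences.
#' @param seed RNG seed for control sampling.
#' @param holdout_chroms chromosomes whose positives form the test set;
#'   default the two highest-numbered chromosomes present (mirroring a
#'   chr8/chr9-style holdout).
#' @param ratio_train,ratio_test controls per positive in each split.
#' @return list with `train` and `test`, each a list of `x` (named sequence
#'   vector) and `y` (1 = positive, 0 = control), plus `holdout_chroms`.
#' @export
make_datasets <- function(positives, controls, seed = 1L,
                          holdout_chroms = NULL, ratio_train = 10L,
                          ratio_test = 1L) {
  pchrom <- element_chrom(names(positives))
  if (is.null(holdout_chroms)) {
    chroms <- unique(pchrom)
    num <- suppressWarnings(as.integer(sub("\\D+", "", chroms)))
    holdout_chroms <- chroms[order(num)][seq(to = length(chroms),
                                             length.out = min(2L, length(chroms)))]
  }
  is_test <- pchrom %in% holdout_chroms
  if (!any(is_test)) stop("no positives on the holdout chromosomes (",
                          paste(holdout_chroms, collapse = ", "), ")")
  if (all(is_test)) stop("no training positives outside the holdout")
  train_pos <- positives[!is_test]
  test_pos <- positives[is_test]
  n_train_ctrl <- ratio_train * length(train_pos)
  n_test_ctrl <- ratio_test * length(test_pos)
  sel <- with_seed(seed, {
    pool <- names(controls)
    test_ids <- sample(pool, min(n_test_ctrl, length(pool)))
    rest <- setdiff(pool, test_ids)
    if (length(rest) >= n_train_ctrl) {
      train_ids <- sample(rest, n_train_ctrl)
    } else {
      message("control pool smaller than 10x training positives; ",
              "sampling training controls with replacement")
      train_ids <- sample(rest, n_train_ctrl, replace = TRUE)
    }
    list(train = train_ids, test = test_ids)
  })
  train_x <- c(train_pos, controls[sel$train])
  test_x <- c(test_pos, controls[sel$test])
  list(train = list(x = train_x,
                    y = rep(c(1, 0), c(length(train_pos),
                                       length(sel$train)))),
       test = list(x = test_x,
                   y = rep(c(1, 0), c(length(test_pos),
                                      length(sel$test)))),
       holdout_chroms = holdout_chroms)
}

#' Default training hyperparameters
#'
#' Binary cross-entropy, AdamW (lr 1e-3, decoupled weight decay 1e-4 on
#' weight matrices), batch 64, at most 30 epochs with early stopping
#' (patience 2) on a 10% validation split of the training set, and random
#' reverse-complement augmentation (DNA regulatory signal is
#' strand-symmetric, and augmentation suppresses sequence memorization in
#' favour of motif features). Class imbalance (10:1) is left unweighted,
#' mirroring the stated training composition.
#'
#' @param ... overrides.
#' @return list of hyperparameters.
#' @export
default_hyperparams <- function(...) {
  hp <- list(lr = 1e-3, batch_size = 64L, epochs = 30L, patience = 2L,
             val_fraction = 0.1, weight_decay = 1e-4, rc_augment = TRUE,
             shift_augment = 15L, kmer_seed_filters = 48L,
             head_warmstart = TRUE)
  utils::modifyList(hp, list(...))
}

#' Train the enhancer classifier
#'
#' @param model an untrained (or warm) `enhancer_cnn`.
#' @param datasets output of [make_datasets()].
#' @param hyperparams see [default_hyperparams()].
#' @param seed seed driving shuffling and the validation split; with a fixed
#'   seed the per-epoch loss sequence is reproducible on the same platform.
#' @param verbose print per-epoch losses.
#' @return list with `model` (trained), `history` (data.frame epoch,
#'   train_loss, val_loss), `test_auroc`, `test_scores`.
#' @export
train_model <- function(model, datasets, hyperparams = default_hyperparams(),
                        seed = 1L, verbose = FALSE) {
  stopifnot(inherits(model, "enhancer_cnn"))
  x <- datasets$train$x
  y <- datasets$train$y
  if (!length(x)) stop("empty training set")
  shift <- as.integer(hyperparams$shift_augment %||% 0L)
  shift <- max(0L, min(shift, 50L))
  # keep the full 400 bp when shift augmentation is on; the crop window is
  # re-drawn per sequence per batch (motifs are shift-invariant, memorized
  # positions are not)
  codes_full <- if (shift > 0L) encode_codes(x, crop = FALSE) else NULL
  codes <- encode_codes(x)
  params <- model$params
  idx <- model$idx
  n_seed <- as.integer(hyperparams$kmer_seed_filters %||% 0L)
  if (n_seed > 0L && !model$trained) {
    seeds <- enriched_kmer_seeds(x, y, n_seed = min(n_seed, 64L))
    if (length(seeds))
      params$W1[seq_along(seeds), ] <- kmer_filter_weights(seeds)
  }
  if (isTRUE(hyperparams$head_warmstart) && !model$trained) with_seed(
    derive_seed(seed, 97L), {
    # warm-start the dense head at the logistic fit on the global-max
    # embedding: the head can represent beta' g exactly (relu splits the
    # positive and negative parts), so backprop starts with a correctly
    # oriented readout instead of a random one
    sub <- seq_len(min(length(y), 8192L))
    G <- matrix(0, 8L, length(sub))
    for (s in seq(1L, length(sub), by = 512L)) {
      e <- min(length(sub), s + 511L)
      X <- codes_to_onehot(codes[, sub[s:e], drop = FALSE])
      G[, s:e] <- cnn_forward(params, X, idx, keep_cache = TRUE)$gmax
    }
    fit <- suppressWarnings(stats::glm.fit(cbind(1, t(G)), y[sub],
                                           family = stats::binomial()))
    beta <- fit$coefficients
    beta[!is.finite(beta)] <- 0
    W5 <- matrix(0, 1376L, 8L)
    W5[cbind(1:8, 1:8)] <- 1
    W5[cbind(9:16, 1:8)] <- -1
    W5[17:1376, ] <- matrix(stats::rnorm(1360L * 8L, sd = 0.05), 1360L, 8L)
    W6 <- matrix(stats::rnorm(1376L, sd = 1e-3), 1L, 1376L)
    W6[1, 1:8] <- beta[-1L]
    W6[1, 9:16] <- -beta[-1L]
    params$W5 <- W5
    params$b5 <- numeric(1376L)
    params$W6 <- W6
    params$b6 <- beta[1L]
  })
  hist <- with_seed(seed, {
    n <- length(y)
    n_val <- max(1L, floor(hyperparams$val_fraction * n))
    val_i <- sample.int(n, n_val)
    tr_i <- setdiff(seq_len(n), val_i)
    Xval <- codes_to_onehot(codes[, val_i, drop = FALSE])
    yval <- y[val_i]
    state <- adam_init(params)
    bce <- function(p, yy) {
      p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
      -mean(yy * log(p) + (1 - yy) * log(1 - p))
    }
    best <- list(loss = Inf, params = params)
    bad_epochs <- 0L
    rows <- list()
    for (epoch in seq_len(hyperparams$epochs)) {
      ord <- sample(tr_i)
      ep_loss <- 0; ep_n <- 0L
      for (s in seq(1L, length(ord), by = hyperparams$batch_size)) {
        bi <- ord[s:min(length(ord), s + hyperparams$batch_size - 1L)]
        if (shift > 0L) {
          off <- sample.int(2L * shift + 1L, length(bi), replace = TRUE) -
            shift - 1L                       # in [-shift, shift]
          row0 <- 50L + off                  # crop start, 0-based
          ridx <- rep(row0, each = 300L) + seq_len(300L)
          cb <- matrix(codes_full[cbind(ridx, rep(bi, each = 300L))],
                       300L, length(bi))
        } else {
          cb <- codes[, bi, drop = FALSE]
        }
        if (isTRUE(hyperparams$rc_augment)) {
          flip <- stats::runif(length(bi)) < 0.5
          if (any(flip)) cb[, flip] <- rc_codes(cb[, flip, drop = FALSE])
        }
        X <- codes_to_onehot(cb)
        cache <- cnn_forward(params, X, idx, keep_cache = TRUE)
        loss <- bce(cache$prob, y[bi])
        if (!is.finite(loss)) stop("training diverged (loss is not finite)")
        grads <- cnn_backward(params, cache, y[bi], idx)
        st <- adam_step(params, grads, state, lr = hyperparams$lr,
                        weight_decay = hyperparams$weight_decay %||% 0)
        params <- st$params; state <- st$state
        ep_loss <- ep_loss + loss * length(bi); ep_n <- ep_n + length(bi)
      }
      val_loss <- bce(cnn_forward(params, Xval, idx)$prob, yval)
      rows[[epoch]] <- data.frame(epoch = epoch,
                                  train_loss = ep_loss / ep_n,
                                  val_loss = val_loss)
      if (verbose)
        message(sprintf("epoch %d: train %.4f val %.4f", epoch,
                        ep_loss / ep_n, val_loss))
      if (val_loss < best$loss - 1e-5) {
        best <- list(loss = val_loss, params = params)
        bad_epochs <- 0L
      } else {
        bad_epochs <- bad_epochs + 1L
        if (bad_epochs >= hyperparams$patience) break
      }
    }
    list(history = do.call(rbind, rows), params = best$params)
  })
  model$params <- hist$params
  model$trained <- TRUE
  test_scores <- NULL
  test_auroc <- NA_real_
  if (!is.null(datasets$test) && length(datasets$test$x)) {
    test_scores <- predict(model, datasets$test$x)
    if (length(unique(datasets$test$y)) == 2L)
      test_auroc <- auroc(test_scores, datasets$test$y)
  }
  list(model = model, history = hist$history, test_auroc = test_auroc,
       test_scores = test_scores)
}

#' Extract de novo motifs from the first convolutional layer
#'
#' For each conv1 filter, every 9-mer window (stride 3, central 300 bp)
#' whose activation reaches `activation_fraction` of that filter's maximum
#' over the positive set contributes its one-hot counts; counts get a
#' pseudocount of 1 per base per column and are column-normalized into a
#' 4 x 9 PWM. Filters with fewer than `min_sites` contributing 9-mers are
#' dropped; at most 64 motifs (the filter count) can be returned.
#'
#' @param model a trained `enhancer_cnn`.
#' @param positives character vector of 400 nt positive elements.
#' @param activation_fraction site-collection threshold as a fraction of the
#'   per-filter maximum activation (default 0.7).
#' @param min_sites minimum contributing 9-mers (default 10).
#' @param batch_size forward batch size.
#' @return list of motifs: `filter_index` (1-based), `pwm` (4 x 9,
#'   column-stochastic), `n_sites`, `information_content` (bits),
#'   `threshold` and `max_activation` (reused by [detect_cooccurrence()]).
#' @export
extract_denovo_motifs <- function(model, positives, activation_fraction = 0.7,
                                  min_sites = 10L, batch_size = 512L) {
  stopifnot(inherits(model, "enhancer_cnn"))
  codes <- encode_codes(positives)
  n <- ncol(codes)
  maxact <- rep(-Inf, 64L)
  for (s in seq(1L, n, by = batch_size)) {
    e <- min(n, s + batch_size - 1L)
    A <- conv1_activations(model$params, codes[, s:e, drop = FALSE],
                           model$idx)
    maxact <- pmax(maxact, apply(A, 1L, max))
  }
  if (all(maxact <= 0))
    stop("no positive conv1 activation; model looks untrained")
  thr <- activation_fraction * maxact
  counts <- vector("list", 64L)
  n_sites <- integer(64L)
  for (s in seq(1L, n, by = batch_size)) {
    e <- min(n, s + batch_size - 1L)
    chunk <- codes[, s:e, drop = FALSE]
    X <- codes_to_onehot(chunk)
    Xc <- im2col(X, model$idx$idx1, 36L)               # 36 x 98B
    A <- pmax(model$params$W1 %*% Xc + model$params$b1, 0)
    for (f in which(maxact > 0)) {
      sel <- which(A[f, ] >= thr[f])
      if (!length(sel)) next
      cs <- rowSums(Xc[, sel, drop = FALSE])
      dim(cs) <- c(4L, 9L)
      counts[[f]] <- if (is.null(counts[[f]])) cs else counts[[f]] + cs
      n_sites[f] <- n_sites[f] + length(sel)
    }
  }
  out <- list()
  for (f in seq_len(64L)) {
    if (n_sites[f] < min_sites) next
    pwm <- counts[[f]] + 1
    pwm <- sweep(pwm, 2L, colSums(pwm), "/")
    rownames(pwm) <- c("A", "C", "G", "T")
    out[[length(out) + 1L]] <- list(
      filter_index = f, pwm = pwm, n_sites = n_sites[f],
      information_content = pwm_information_content(pwm),
      threshold = thr[f], max_activation = maxact[f])
  }
  out
}

# all column-pair Pearson correlations between two PWMs in one crossprod;
# zero-variance columns contribute correlation 0.
#' @noRd
pwm_col_cor_matrix <- function(P, Q) {
  zs <- function(M) {
    mu <- colMeans(M)
    ce <- sweep(M, 2L, mu)
    sd <- sqrt(colSums(ce^2) / 3)
    bad <- sd < 1e-12
    sd[bad] <- 1
    z <- sweep(ce, 2L, sd, "/")
    z[, bad] <- 0
    z
  }
  crossprod(zs(P), zs(Q)) / 3
}

# best mean-column-correlation alignment score given the wp x wq
# correlation matrix; offsets must overlap by >= min_overlap columns
#' @noRd
best_alignment_score <- function(R, min_overlap = 5L) {
  wp <- nrow(R); wq <- ncol(R)
  best <- -Inf
  for (o in (-(wq - min_overlap)):(wp - min_overlap)) {
    i <- seq(max(1L, 1L + o), min(wp, wq + o))
    j <- i - o
    if (length(i) < min_overlap) next
    best <- max(best, mean(R[cbind(i, j)]))
  }
  best
}

#' Score similarity of two PWMs
#'
#' Maximum over alignment offsets (>= 5 overlapping columns) and both
#' strands of the mean per-column Pearson correlation between probability
#' columns.
#'
#' @param pwm_a,pwm_b column-stochastic 4 x width matrices (rows A, C, G, T).
#' @param min_overlap minimum overlapping columns per alignment.
#' @return list with `score` and `strand` ("+" or "-").
#' @export
pwm_similarity <- function(pwm_a, pwm_b, min_overlap = 5L) {
  fwd <- best_alignment_score(pwm_col_cor_matrix(pwm_a, pwm_b), min_overlap)
  rev <- best_alignment_score(
    pwm_col_cor_matrix(pwm_a, pwm_reverse_complement(pwm_b)), min_overlap)
  if (fwd >= rev) list(score = fwd, strand = "+")
  else list(score = rev, strand = "-")
}

#' Match de novo motifs against a known motif library
#'
#' STAMP-style matching: each de novo PWM is scored against every known PFM
#' by [pwm_similarity()]; the null distribution is the score of shuffled
#' copies of the de novo PWM (column order permuted and base identities
#' permuted within each column) against the same known motif, a Gaussian is
#' fit to the null and the upper-tail p-value reported.
#' Matches with p < `alpha` (default 1e-5) are emitted; the best match per
#' de novo motif is flagged.
#'
#' @param denovo list from [extract_denovo_motifs()].
#' @param known_library named list of column-stochastic PFMs, width >= 5.
#' @param n_null number of shuffles for the null (default 1000).
#' @param alpha emission threshold on the p-value.
#' @param seed RNG seed for the shuffles.
#' @param min_overlap minimum aligned columns (default 7; shifts of up to
#'   two columns are still found, while the max-over-alignments null stays
#'   light enough for a perfect match to clear `alpha`).
#' @return data.frame (filter_index, known_id, score, strand, p_value, best).
#' @export
match_known_motifs <- function(denovo, known_library, n_null = 1000L,
                               alpha = 1e-5, seed = 1L, min_overlap = 7L) {
  if (!length(known_library)) stop("known motif library is empty")
  if (any(vapply(known_library, ncol, integer(1)) < 5L))
    stop("known motifs must have width >= 5")
  rows <- with_seed(seed, {
    out <- list()
    zs <- function(M) {
      ce <- sweep(M, 2L, colMeans(M))
      sd <- sqrt(colSums(ce^2) / 3)
      bad <- sd < 1e-12; sd[bad] <- 1
      z <- sweep(ce, 2L, sd, "/"); z[, bad] <- 0
      z
    }
    for (m in denovo) {
      P <- m$pwm
      wp <- ncol(P)
      # null copies: permute column order AND the base identities within
      # each column. A pure column shuffle leaves low-complexity (e.g.
      # AT-rich) motifs matching themselves near score 1 and the Gaussian
      # tail never reaches 1e-5; permuting bases within columns destroys
      # that composition signal while remaining a shuffled copy of P.
      shuffles <- replicate(n_null, {
        P[c(replicate(wp, sample.int(4L))) +
            rep(4L * (sample.int(wp) - 1L), each = 4L)]
      }, simplify = FALSE)
      zshuf <- lapply(shuffles, function(v) zs(matrix(v, 4L, wp)))
      for (k in names(known_library)) {
        Q <- known_library[[k]]
        zQf <- zs(Q)
        zQr <- zs(pwm_reverse_complement(Q))
        sf <- best_alignment_score(crossprod(zs(P), zQf) / 3, min_overlap)
        sr <- best_alignment_score(crossprod(zs(P), zQr) / 3, min_overlap)
        obs <- max(sf, sr)
        strand <- if (sf >= sr) "+" else "-"
        null <- vapply(zshuf, function(zP)
          max(best_alignment_score(crossprod(zP, zQf) / 3, min_overlap),
              best_alignment_score(crossprod(zP, zQr) / 3, min_overlap)),
          numeric(1))
        mu <- mean(null); sdv <- stats::sd(null)
        p <- stats::pnorm(obs, mean = mu, sd = max(sdv, 1e-12),
                          lower.tail = FALSE)
        out[[length(out) + 1L]] <- data.frame(
          filter_index = m$filter_index, known_id = k, score = obs,
          strand = strand, p_value = p, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
  if (is.null(rows)) return(data.frame(filter_index = integer(),
                                       known_id = character(),
                                       score = numeric(),
                                       strand = character(),
                                       p_value = numeric(),
                                       best = logical()))
  rows$best <- FALSE
  for (f in unique(rows$filter_index)) {
    i <- which(rows$filter_index == f)
    rows$best[i[which.max(rows$score[i])]] <- TRUE
  }
  rows <- rows[rows$p_value < alpha, , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' Receptive field of a third-convolutional-layer unit
#'
#' Each conv3 unit sees 90 bp of the (cropped, 300 bp) input, and
#' consecutive units shift by 12 bp: field = [12 u, 12 u + 90) for unit
#' u in 0..17 (the recurrence 9 + (2-1)*3 + (5-1)*6 + (2-1)*6 + (5-1)*12 =
#' 90 with jump 3*2*2 = 12).
#'
#' @param unit_index 0-based conv3 spatial index, 0..17.
#' @return integer vector c(start, end), 0-based half-open in cropped input
#'   coordinates.
#' @export
conv3_receptive_field <- function(unit_index) {
  if (length(unit_index) != 1L || is.na(unit_index) ||
      unit_index < 0L || unit_index > 17L)
    stop("unit_index must be a single value in 0..17")
  start <- 12L * as.integer(unit_index)
  c(start = start, end = start + 90L)
}

# per-sequence (filters x 18) incidence of activating conv1 hits inside each
# conv3 receptive-field window
#' @noRd
window_unit_incidence <- function() {
  W <- matrix(FALSE, 98L, 18L)
  for (w in seq_len(98L)) {
    s <- 3L * (w - 1L)
    for (u in 0:17) {
      if (12L * u <= s && s + 9L <= 12L * u + 90L) W[w, u + 1L] <- TRUE
    }
  }
  W
}

#' Test motif co-occurrence inside conv3 receptive fields
#'
#' A pair of de novo motifs co-occurs in a sequence iff some conv3
#' receptive-field window (90 bp, step 12) fully contains an activating
#' conv1 hit of both filters (activation thresholds reused from motif
#' extraction). Per pair, the fraction of positive sequences with a
#' co-occurrence is compared with the background (control) fraction by a
#' one-sided Fisher's exact test; a pair is significant iff p < `alpha`
#' (default 0.001, no multiple-testing correction) and the positive rate
#' exceeds the background rate.
#'
#' @param model a trained `enhancer_cnn`.
#' @param motifs list from [extract_denovo_motifs()].
#' @param positives,controls character vectors of 400 nt sequences.
#' @param alpha significance threshold.
#' @param batch_size forward batch size.
#' @return data.frame (motif_a, motif_b, count_pos, n_pos, count_bg, n_bg,
#'   p_value, significant), motif_a < motif_b (filter indices).
#' @export
detect_cooccurrence <- function(model, motifs, positives, controls,
                                alpha = 0.001, batch_size = 512L) {
  if (!length(controls)) stop("background (control) sequence set is empty")
  if (!length(positives)) stop("positive sequence set is empty")
  if (length(motifs) < 2L)
    return(data.frame(motif_a = integer(), motif_b = integer(),
                      count_pos = integer(), n_pos = integer(),
                      count_bg = integer(), n_bg = integer(),
                      p_value = numeric(), significant = logical()))
  filt <- vapply(motifs, `[[`, integer(1), "filter_index")
  thr <- vapply(motifs, `[[`, numeric(1), "threshold")
  WU <- window_unit_incidence() * 1
  nf <- length(filt)
  count_set <- function(seqs) {
    codes <- encode_codes(seqs)
    n <- ncol(codes)
    co <- matrix(0L, nf, nf)
    for (s in seq(1L, n, by = batch_size)) {
      e <- min(n, s + batch_size - 1L)
      A <- conv1_activations(model$params, codes[, s:e, drop = FALSE],
                             model$idx)
      for (b in seq_len(e - s + 1L)) {
        hits <- (A[filt, , b, drop = FALSE] >= thr) * 1   # nf x 98
        dim(hits) <- c(nf, 98L)
        M <- hits %*% WU                                   # nf x 18
        co <- co + ((M > 0) %*% t(M > 0) > 0)
      }
    }
    co
  }
  co_pos <- count_set(positives)
  co_bg <- count_set(controls)
  n_pos <- length(positives); n_bg <- length(controls)
  rows <- list()
  for (i in seq_len(nf - 1L)) {
    for (j in (i + 1L):nf) {
      cp <- co_pos[i, j]; cb <- co_bg[i, j]
      p <- stats::fisher.test(
        matrix(c(cp, n_pos - cp, cb, n_bg - cb), nrow = 2L),
        alternative = "greater")$p.value
      rows[[length(rows) + 1L]] <- data.frame(
        motif_a = min(filt[i], filt[j]), motif_b = max(filt[i], filt[j]),
        count_pos = cp, n_pos = n_pos, count_bg = cb, n_bg = n_bg,
        p_value = p,
        significant = p < alpha && (cp / n_pos) > (cb / n_bg),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
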