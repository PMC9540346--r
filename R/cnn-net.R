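# Internal network machinery for the enhancer classifier: im2col
# convolutions as BLAS matmuls, ReLU, k2/s2 max pooling, a global max pool,
# dense head, manual backprop and Adam. No deep-learning framework is
# available (or needed) for a 59,785-parameter model; everything here is
# vectorized base R.
#
# Layout conventions: a batch of one-hot inputs is a (4*300) x B matrix,
# column-major with base fastest, so the im2col window of conv1 (kernel 9,
# stride 3) is a *contiguous* slice of 36 flat indices; deeper layers store
# activations as (channels * length) x B with channels fastest, making every
# kernel-5 window a contiguous slice of 320 indices.

# geometry of the fixed architecture
.cnn_geom <- list(
  input_len = 300L,
  conv1 = list(filters = 64L, kernel = 9L, stride = 3L, out_len = 98L),
  pool1_out = 49L,
  conv2 = list(filters = 64L, kernel = 5L, stride = 1L, out_len = 45L),
  pool2_out = 22L,
  conv3 = list(filters = 64L, kernel = 5L, stride = 1L, out_len = 18L),
  pool3_out = 9L,
  conv4 = list(filters = 8L, kernel = 5L, stride = 1L, out_len = 5L),
  dense1 = 1376L
)

# im2col index vectors (contiguous windows, see header comment)
#' @noRd
im2col_idx <- function(n_windows, window_len, stride_flat) {
  as.vector(vapply(seq_len(n_windows) - 1L,
                   function(w) w * stride_flat + seq_len(window_len),
                   integer(window_len)))
}

#' @noRd
cnn_indices <- function() {
  g <- .cnn_geom
  list(
    idx1 = im2col_idx(g$conv1$out_len, 4L * g$conv1$kernel,
                      4L * g$conv1$stride),
    idx2 = im2col_idx(g$conv2$out_len, 64L * g$conv2$kernel, 64L),
    idx3 = im2col_idx(g$conv3$out_len, 64L * g$conv3$kernel, 64L),
    idx4 = im2col_idx(g$conv4$out_len, 64L * g$conv4$kernel, 64L)
  )
}

#' @noRd
im2col <- function(Xflat, idxv, win_len) {
  B <- ncol(Xflat)
  M <- Xflat[idxv, , drop = FALSE]
  dim(M) <- c(win_len, (length(idxv) %/% win_len) * B)
  M
}

# scatter-add of column gradients back to the flat input
#' @noRd
col2im <- function(dcol, idxv, win_len, n_in, B) {
  dim(dcol) <- c(length(idxv), B)
  r <- rowsum(dcol, group = idxv)
  out <- matrix(0, n_in, B)
  out[as.integer(rownames(r)), ] <- r
  out
}

# max pool k2 s2 along length; input (C, L, B) array, drops a trailing odd
# position. Returns pooled array and the odd-wins mask for backprop.
#' @noRd
pool2 <- function(A, C, L, B) {
  Lp <- L %/% 2L
  dim(A) <- c(C, L, B)
  Ao <- A[, seq(1L, 2L * Lp - 1L, 2L), , drop = FALSE]
  Ae <- A[, seq(2L, 2L * Lp, 2L), , drop = FALSE]
  list(P = pmax(Ao, Ae), mask_odd = Ao >= Ae, Lp = Lp)
}

#' @noRd
unpool2 <- function(dP, mask_odd, C, L, B) {
  Lp <- dim(dP)[2L]
  out <- array(0, c(C, L, B))
  out[, seq(1L, 2L * Lp - 1L, 2L), ] <- dP * mask_odd
  out[, seq(2L, 2L * Lp, 2L), ] <- dP * !mask_odd
  out
}

# He-scaled gaussian init for one weight matrix
#' @noRd
init_mat <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

# Initialization: He-gaussian for conv1 and the dense head, delta (identity
# passthrough at the central kernel position, plus small noise) for
# conv2-conv4. A randomly-initialized deep max-pool stack erases the weak
# per-window motif signal conv1 produces, and gradient descent then prefers
# memorization; delta initialization keeps the network signal-preserving at
# the start (cf. delta-orthogonal initialization for deep CNNs) so the
# first-layer filters receive usable gradient. conv4 (64 -> 8 channels)
# averages input channels congruent mod 8, giving every conv1 filter a path
# to the head.
#' @noRd
cnn_init_params <- function(zero = FALSE) {
  g <- .cnn_geom
  mk <- function(nr, nc) if (zero) matrix(0, nr, nc) else init_mat(nr, nc, nc)
  noise_mk <- function(nr, nc, sd = 0.03)
    matrix(if (zero) 0 else stats::rnorm(nr * nc, sd = sd), nr, nc)
  # per-conv1-channel kernel-position offsets for the passthrough taps of
  # conv2/conv3/conv4. With valid (unpadded) convolutions a center-only
  # identity chain sees barely the middle ~125 bp of the input; staggering
  # the tap position per channel makes the per-channel views tile the whole
  # 300 bp, so every conv1 filter keeps an undiluted, position-complete-ish
  # path into the global max pool at initialization.
  combos <- as.matrix(expand.grid(o2 = 0:4, o3 = 0:4, o4 = 0:4))
  offs <- combos[round(seq(1L, nrow(combos), length.out = 64L)), ,
                 drop = FALSE]
  W2 <- noise_mk(64L, 64L * 5L)
  W3 <- noise_mk(64L, 64L * 5L)
  W4 <- noise_mk(8L, 64L * 5L)
  if (!zero) {
    for (ci in 1:64) {
      W2[ci, offs[ci, 1L] * 64L + ci] <- W2[ci, offs[ci, 1L] * 64L + ci] + 1
      W3[ci, offs[ci, 2L] * 64L + ci] <- W3[ci, offs[ci, 2L] * 64L + ci] + 1
      co <- ((ci - 1L) %% 8L) + 1L
      W4[co, offs[ci, 3L] * 64L + ci] <- W4[co, offs[ci, 3L] * 64L + ci] + 1
    }
  }
  list(
    W1 = mk(g$conv1$filters, 4L * g$conv1$kernel),
    b1 = numeric(g$conv1$filters),
    W2 = W2,
    b2 = numeric(g$conv2$filters),
    W3 = W3,
    b3 = numeric(g$conv3$filters),
    W4 = W4,
    b4 = numeric(g$conv4$filters),
    W5 = mk(g$dense1, g$conv4$filters),
    b5 = numeric(g$dense1),
    W6 = mk(1L, g$dense1),
    b6 = numeric(1L)
  )
}

# Full forward pass. X is (1200 x B). Returns probabilities and, if
# keep_cache, every intermediate needed by cnn_backward.
#' @noRd
cnn_forward <- function(params, X, idx, keep_cache = FALSE) {
  g <- .cnn_geom
  B <- ncol(X)
  Xc <- im2col(X, idx$idx1, 36L)                       # 36 x 98B
  Z1 <- params$W1 %*% Xc + params$b1                   # 64 x 98B
  A1 <- pmax(Z1, 0)
  p1 <- pool2(A1, 64L, g$conv1$out_len, B)             # 64 x 49 x B
  P1 <- p1$P; dim(P1) <- c(64L * g$pool1_out, B)
  P1c <- im2col(P1, idx$idx2, 320L)                    # 320 x 45B
  Z2 <- params$W2 %*% P1c + params$b2
  A2 <- pmax(Z2, 0)
  p2 <- pool2(A2, 64L, g$conv2$out_len, B)             # 64 x 22 x B
  P2 <- p2$P; dim(P2) <- c(64L * g$pool2_out, B)
  P2c <- im2col(P2, idx$idx3, 320L)                    # 320 x 18B
  Z3 <- params$W3 %*% P2c + params$b3
  A3 <- pmax(Z3, 0)
  p3 <- pool2(A3, 64L, g$conv3$out_len, B)             # 64 x 9 x B
  P3 <- p3$P; dim(P3) <- c(64L * g$pool3_out, B)
  P3c <- im2col(P3, idx$idx4, 320L)                    # 320 x 5B
  Z4 <- params$W4 %*% P3c + params$b4                  # 8 x 5B
  A4 <- pmax(Z4, 0)
  dim(A4) <- c(8L, g$conv4$out_len, B)
  gmax <- matrix(A4[, 1L, ], 8L, B)                    # global max pool
  amax <- matrix(1L, 8L, B)
  for (j in 2:g$conv4$out_len) {
    Aj <- matrix(A4[, j, ], 8L, B)
    upd <- Aj > gmax
    gmax[upd] <- Aj[upd]
    amax[upd] <- j
  }
  H <- pmax(params$W5 %*% gmax + params$b5, 0)         # 1376 x B
  logits <- as.numeric(params$W6 %*% H + params$b6)
  prob <- 1 / (1 + exp(-logits))
  if (!keep_cache) return(list(prob = prob))
  list(prob = prob, Xc = Xc, Z1 = Z1, mask1 = p1$mask_odd,
       P1c = P1c, Z2 = Z2, mask2 = p2$mask_odd,
       P2c = P2c, Z3 = Z3, mask3 = p3$mask_odd,
       P3c = P3c, Z4 = Z4, amax = amax, gmax = gmax, H = H, B = B)
}

#' @noRd
cnn_backward <- function(params, cache, y, idx) {
  g <- .cnn_geom
  B <- cache$B
  dlogit <- matrix((cache$prob - y) / B, 1L, B)
  dW6 <- dlogit %*% t(cache$H)
  db6 <- sum(dlogit)
  dH <- crossprod(params$W6, dlogit)
  dH[cache$H <= 0] <- 0
  dW5 <- dH %*% t(cache$gmax)
  db5 <- rowSums(dH)
  dg <- crossprod(params$W5, dH)                       # 8 x B
  dA4 <- array(0, c(8L, g$conv4$out_len, B))
  for (j in seq_len(g$conv4$out_len)) {
    sel <- cache$amax == j
    tmp <- matrix(0, 8L, B)
    tmp[sel] <- dg[sel]
    dA4[, j, ] <- tmp
  }
  dZ4 <- dA4; dim(dZ4) <- c(8L, g$conv4$out_len * B)
  dZ4[cache$Z4 <= 0] <- 0
  dW4 <- dZ4 %*% t(cache$P3c)
  db4 <- rowSums(dZ4)
  dP3c <- crossprod(params$W4, dZ4)                    # 320 x 5B
  dP3 <- col2im(dP3c, idx$idx4, 320L, 64L * g$pool3_out, B)
  dim(dP3) <- c(64L, g$pool3_out, B)
  dA3 <- unpool2(dP3, cache$mask3, 64L, g$conv3$out_len, B)
  dZ3 <- dA3; dim(dZ3) <- c(64L, g$conv3$out_len * B)
  dZ3[cache$Z3 <= 0] <- 0
  dW3 <- dZ3 %*% t(cache$P2c)
  db3 <- rowSums(dZ3)
  dP2c <- crossprod(params$W3, dZ3)
  dP2 <- col2im(dP2c, idx$idx3, 320L, 64L * g$pool2_out, B)
  dim(dP2) <- c(64L, g$pool2_out, B)
  dA2 <- unpool2(dP2, cache$mask2, 64L, g$conv2$out_len, B)
  dZ2 <- dA2; dim(dZ2) <- c(64L, g$conv2$out_len * B)
  dZ2[cache$Z2 <= 0] <- 0
  dW2 <- dZ2 %*% t(cache$P1c)
  db2 <- rowSums(dZ2)
  dP1c <- crossprod(params$W2, dZ2)
  dP1 <- col2im(dP1c, idx$idx2, 320L, 64L * g$pool1_out, B)
  dim(dP1) <- c(64L, g$pool1_out, B)
  dA1 <- unpool2(dP1, cache$mask1, 64L, g$conv1$out_len, B)
  dZ1 <- dA1; dim(dZ1) <- c(64L, g$conv1$out_len * B)
  dZ1[cache$Z1 <= 0] <- 0
  dW1 <- dZ1 %*% t(cache$Xc)
  db1 <- rowSums(dZ1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, W3 = dW3, b3 = db3,
       W4 = dW4, b4 = db4, W5 = dW5, b5 = db5, W6 = dW6, b6 = db6)
}

#' @noRd
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

# AdamW: decoupled weight decay applied to weight matrices only (not biases)
#' @noRd
adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    step <- lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    if (weight_decay > 0 && startsWith(nm, "W"))
      step <- step + lr * weight_decay * params[[nm]]
    params[[nm]] <- params[[nm]] - step
  }
  list(params = params, state = state)
}

# reverse-complement in code space: A<->T, C<->G, N stays, order reversed
#' @noRd
rc_codes <- function(codes) {
  out <- codes[rev(seq_len(nrow(codes))), , drop = FALSE]
  ifelse(out == 0L, 0L, 5L - out)
}

# Data-driven conv1 seeding: rank 9-mers by their enrichment in training
# positives over training controls (both strands, all offsets in the central
# 300 bp) and initialize the first n_seed filters as match/mismatch
# detectors of the top distinct 9-mers. This is the CNN analogue of seeding
# a de novo motif search with over-represented k-mers; backprop discovery of
# motif filters through three max-pool layers is otherwise extremely slow.
# Uses only the training split - no test data, no ground truth.
#' @noRd
enriched_kmer_seeds <- function(x, y, n_seed = 48L, k = 9L,
                                max_bg = 2000L, min_hamming = 3L) {
  kmers_of <- function(seqs) {
    unlist(lapply(seqs, function(s) {
      core <- substr(s, 51L, 350L)
      n <- nchar(core) - k + 1L
      substring(core, seq_len(n), seq_len(n) + k - 1L)
    }), use.names = FALSE)
  }
  revcomp_str <- function(s) chartr("ACGT", "TGCA",
                                    vapply(strsplit(s, ""), function(ch)
                                      paste(rev(ch), collapse = ""),
                                      character(1)))
  pos <- x[y == 1]
  bg <- x[y == 0]
  if (length(bg) > max_bg) bg <- bg[seq_len(max_bg)]
  kp <- kmers_of(pos)
  kp <- c(kp, revcomp_str(kp[grepl("^[ACGT]+$", kp)]))
  kb <- kmers_of(bg)
  kb <- c(kb, revcomp_str(kb[grepl("^[ACGT]+$", kb)]))
  tp <- table(kp)
  tb <- table(kb)
  cand <- names(tp)[grepl("^[ACGT]+$", names(tp))]
  cp <- as.numeric(tp[cand])
  cb <- as.numeric(tb[cand]); cb[is.na(cb)] <- 0
  scale_bg <- length(kp) / max(1, length(kb))
  score <- log2((cp + 1) / (cb * scale_bg + 1))
  ord <- order(score, decreasing = TRUE)
  chosen <- character()
  ham <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  for (i in ord) {
    km <- cand[i]
    if (length(chosen) >= n_seed) break
    # same-strand near-duplicates are redundant; a seed and its reverse
    # complement are NOT (each filter sees one strand only)
    if (any(vapply(chosen, function(ch) ham(ch, km) < min_hamming,
                   logical(1)))) next
    chosen <- c(chosen, km)
  }
  chosen
}

# one filter row per seed k-mer: +0.75 on the matching base, -0.25 elsewhere
#' @noRd
kmer_filter_weights <- function(kmers, scale = 1) {
  bases <- c("A", "C", "G", "T")
  t(vapply(kmers, function(km) {
    oh <- matrix(0, 4L, nchar(km))
    oh[cbind(match(strsplit(km, "")[[1]], bases), seq_len(nchar(km)))] <- 1
    as.vector(scale * (oh - 0.25))
  }, numeric(4L * nchar(kmers[1L]))))
}

# DNA to integer codes (A=1 C=2 G=3 T=4, N/other = 0) for the central 300 bp
# of 400 bp elements.
#' @noRd
encode_codes <- function(seqs, crop = TRUE) {
  lens <- nchar(seqs)
  if (any(lens != 400L))
    stop("every element must be exactly 400 nt; got length ",
         lens[which(lens != 400L)[1L]])
  lookup <- integer(256)
  lookup[utf8ToInt("A")] <- 1L; lookup[utf8ToInt("C")] <- 2L
  lookup[utf8ToInt("G")] <- 3L; lookup[utf8ToInt("T")] <- 4L
  lookup[utf8ToInt("a")] <- 1L; lookup[utf8ToInt("c")] <- 2L
  lookup[utf8ToInt("g")] <- 3L; lookup[utf8ToInt("t")] <- 4L
  m <- vapply(seqs, function(s) lookup[utf8ToInt(s)], integer(400L),
              USE.NAMES = FALSE)
  if (crop) m <- m[51:350, , drop = FALSE]  # exclude 50 bp at both ends
  m
}

# codes (300 x B) -> one-hot flat (1200 x B)
#' @noRd
codes_to_onehot <- function(codes) {
  B <- ncol(codes)
  X <- matrix(0, 1200L, B)
  pos <- rep(seq_len(300L), B)
  col <- rep(seq_len(B), each = 300L)
  keep <- codes > 0L
  X[cbind((pos[keep] - 1L) * 4L + codes[keep], col[keep])] <- 1
  X
}

# conv1 activations for a batch of codes: (64 x 98 x B)
#' @noRd
conv1_activations <- function(params, codes, idx) {
  X <- codes_to_onehot(codes)
  Xc <- im2col(X, idx$idx1, 36L)
  A <- pmax(params$W1 %*% Xc + params$b1, 0)
  dim(A) <- c(64L, 98L, ncol(codes))
  A
}
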