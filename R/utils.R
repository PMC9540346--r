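# Internal numeric helpers shared across modules.

#' @noRd
logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Area under the ROC curve by the rank (Mann-Whitney) identity.
#' @param scores numeric predictions, larger = more positive.
#' @param labels 0/1 (or logical) truth.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("auroc needs both classes present")
  r <- rank(scores)  # midranks handle ties
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Deterministic child seed: keeps derived seeds in 32-bit integer range.
#' @noRd
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483587)
}

# Run expr with a temporarily-seeded RNG, restoring global RNG state after,
# so generator stages are individually deterministic and composable.
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Uniform integer in [lo, hi] immune to sample()'s scalar surprise.
#' @noRd
runif_int <- function(lo, hi) {
  if (hi < lo) stop("empty integer range [", lo, ", ", hi, "]")
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}
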