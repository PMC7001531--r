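# Internal helpers shared across modules.

.assert <- function(cond, ...) {
  if (!isTRUE(cond)) stop(..., call. = FALSE)
}

# Coerce a two-class label vector to 0/1 integers, preserving level order.
# Factors use their level order; logicals map FALSE/TRUE -> 0/1; numeric
# vectors must already be two-valued and are mapped by sorted value.
.as_binary <- function(y) {
  if (is.factor(y)) {
    .assert(nlevels(droplevels(y)) == 2L, "labels must contain exactly two classes")
    lev <- levels(droplevels(y))
    list(y01 = as.integer(droplevels(y)) - 1L, levels = lev)
  } else if (is.logical(y)) {
    .assert(length(unique(y)) == 2L, "labels must contain exactly two classes")
    list(y01 = as.integer(y), levels = c("FALSE", "TRUE"))
  } else {
    u <- sort(unique(y))
    .assert(length(u) == 2L, "labels must contain exactly two classes")
    list(y01 = as.integer(y == u[2L]), levels = as.character(u))
  }
}

# Stratified fold assignment: shuffles within each class and deals
# round-robin, so fold class counts differ by at most one. Consumes the
# current RNG stream; callers that need reproducibility set the seed.
.stratified_folds <- function(y01, k) {
  .assert(k >= 2L, "need at least 2 folds")
  folds <- integer(length(y01))
  for (cls in unique(y01)) {
    idx <- which(y01 == cls)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

.set_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

# Truncated normal sampling by inverse-CDF; exact, no rejection loop.
.rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# Deterministic per-stage seeds derived from one master seed.
.stage_seeds <- function(master, stages) {
  .set_seed(master)
  s <- sample.int(.Machine$integer.max - 1L, length(stages))
  names(s) <- stages
  s
}
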