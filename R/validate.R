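# Model quality beyond the training fit: cross-validated Q2Y, label
# permutation validation, and the exploratory PCA companion.

# Cross-validated PRESS per component count on raw (unscaled) x, for a
# given fold assignment. Each fold's centering/scaling and PLS fit use its
# training split only.
.q2_press <- function(x, y01, ncomp, fold_id) {
  press <- numeric(ncomp)
  for (f in unique(fold_id)) {
    te <- fold_id == f
    if (!any(te)) next
    tr <- !te
    ytr <- y01[tr]
    ctr <- colMeans(x[tr, , drop = FALSE])
    scl <- apply(x[tr, , drop = FALSE], 2L, stats::sd)
    scl[scl < 1e-12] <- 1  # constant-in-fold column: center only
    xs_tr <- scale(x[tr, , drop = FALSE], ctr, scl)
    xs_te <- scale(x[te, , drop = FALSE], ctr, scl)
    ym <- mean(ytr)
    a_max <- min(ncomp, sum(tr) - 1L, ncol(x))
    fit <- .pls1(xs_tr, ytr - ym, a_max)
    for (a in seq_len(ncomp)) {
      b <- .pls1_coef(fit, min(a, a_max))
      pred <- ym + drop(xs_te %*% b)
      press[a] <- press[a] + sum((y01[te] - pred)^2)
    }
  }
  press
}

#' Cross-validated Q2Y of a two-class PLS-DA
#'
#' Predictive fraction of label variance, `Q2 = 1 - PRESS/SS`, where PRESS
#' accumulates squared prediction error of held-out samples over stratified
#' cross-validation folds (each fold's model, centering and scaling fitted
#' on its training split only) and SS is the total sum of squares of the
#' 0/1-coded labels about their global mean. Reported cumulatively per
#' component count; values can be negative when the model predicts worse
#' than the label mean.
#'
#' @param x numeric matrix, samples x variables (raw or normalized scale;
#'   standardization happens within each training fold).
#' @param y two-class labels.
#' @param ncomp number of components, default 2.
#' @param folds number of stratified folds, default 7 (the usual
#'   chemometrics convention); alternatively an explicit per-sample fold
#'   assignment vector of length `nrow(x)` (e.g. `1:n` for leave-one-out).
#' @param seed optional integer; when supplied, the fold draw is
#'   reproducible (ignored for explicit fold vectors).
#' @return Numeric vector of cumulative Q2Y values, length `ncomp`.
#' @export
q2y <- function(x, y, ncomp = 2, folds = 7, seed = NULL) {
  .assert(is.matrix(x) && !anyNA(x), "x must be a complete numeric matrix")
  bin <- .as_binary(y)
  .assert(length(bin$y01) == nrow(x), "length(y) must equal nrow(x)")
  if (length(folds) == 1L) {
    .assert(folds >= 2L, "need at least 2 folds")
    .set_seed(seed)
    fold_id <- .stratified_folds(bin$y01, folds)
  } else {
    .assert(length(folds) == nrow(x),
            "explicit fold assignment must have one entry per sample")
    fold_id <- as.integer(folds)
  }
  for (f in unique(fold_id))
    if (length(unique(bin$y01[fold_id != f])) < 2L)
      stop("fold ", f, " leaves single-class training data", call. = FALSE)
  ss <- sum((bin$y01 - mean(bin$y01))^2)
  if (ss == 0) stop("labels have zero variance", call. = FALSE)
  1 - .q2_press(x, bin$y01, ncomp, fold_id) / ss
}

#' Permutation validation of a PLS-DA model
#'
#' Refits the model on randomly permuted class labels and records, for
#' each permutation, the absolute correlation of the permuted labels with
#' the originals together with the refit's R2Y and cross-validated Q2Y.
#' Least-squares lines of R2 and Q2 against the label correlation
#' (including the unpermuted point at correlation 1) are extrapolated to
#' correlation 0; a negative Q2 intercept is the usual evidence that the
#' model is not overfit.
#'
#' @param x numeric matrix, samples x variables.
#' @param y two-class labels.
#' @param n_permutations number of label permutations, default 200.
#'   Below 20 the intercepts are unstable and a warning is raised.
#' @param ncomp number of PLS components, default 2.
#' @param folds stratified folds for each Q2 evaluation, default 7.
#' @param seed optional integer seed for the permutations and fold draws.
#' @return Object of class `"plsda_permutation"`: `summary` data frame
#'   (`correlation`, `r2`, `q2`, `permuted`; the first row is the
#'   unpermuted model), `r2_intercept`, `q2_intercept`, and `valid`
#'   (`TRUE` when the Q2 intercept is negative).
#' @export
permutation_validate <- function(x, y, n_permutations = 200, ncomp = 2,
                                 folds = 7, seed = NULL) {
  .assert(is.matrix(x) && !anyNA(x), "x must be a complete numeric matrix")
  .assert(nrow(x) >= 6L, "need at least 6 samples")
  bin <- .as_binary(y)
  .assert(length(bin$y01) == nrow(x), "length(y) must equal nrow(x)")
  if (n_permutations < 20)
    warning("fewer than 20 permutations: intercept estimates are unstable",
            call. = FALSE)
  .set_seed(seed)
  y01 <- bin$y01
  ss <- sum((y01 - mean(y01))^2)

  # Standardize once for the R2 refits; Q2 rescales within folds from raw x.
  scl <- apply(x, 2L, stats::sd)
  if (any(scl == 0))
    stop("zero-variance column(s): ",
         paste(colnames(x)[scl == 0], collapse = ", "), call. = FALSE)
  xs <- scale(x)

  eval_labels <- function(yp) {
    ypc <- yp - mean(yp)
    fit <- .pls1(xs, ypc, ncomp)
    fold_id <- .stratified_folds(yp, folds)
    c(r2 = sum(fit$ssy) / sum(ypc^2),
      q2 = 1 - .q2_press(x, yp, ncomp, fold_id)[ncomp] / ss)
  }

  res <- matrix(NA_real_, n_permutations + 1L, 3L,
                dimnames = list(NULL, c("correlation", "r2", "q2")))
  orig <- eval_labels(y01)
  res[1L, ] <- c(1, orig)
  for (i in seq_len(n_permutations)) {
    yp <- sample(y01)
    res[i + 1L, ] <- c(abs(stats::cor(yp, y01)), eval_labels(yp))
  }
  df <- as.data.frame(res)
  df$permuted <- c(FALSE, rep(TRUE, n_permutations))
  r2_int <- unname(stats::coef(stats::lm(r2 ~ correlation, df))[1])
  q2_int <- unname(stats::coef(stats::lm(q2 ~ correlation, df))[1])
  structure(list(summary = df, n_permutations = n_permutations,
                 ncomp = ncomp, r2_intercept = r2_int,
                 q2_intercept = q2_int, valid = q2_int < 0),
            class = "plsda_permutation")
}

#' @export
print.plsda_permutation <- function(x, digits = 3, ...) {
  cat("PLS-DA permutation validation (", x$n_permutations,
      " permutations, ", x$ncomp, " component(s))\n", sep = "")
  cat(sprintf("  model: R2Y = %.*f, Q2Y = %.*f\n", digits,
              x$summary$r2[1], digits, x$summary$q2[1]))
  cat(sprintf("  intercepts at zero label correlation: R2 = %.*f, Q2 = %.*f\n",
              digits, x$r2_intercept, digits, x$q2_intercept))
  cat("  verdict:", if (x$valid) "Q2 intercept < 0 (not overfit)"
      else "Q2 intercept >= 0 (possible overfit)", "\n")
  invisible(x)
}

#' @export
plot.plsda_permutation <- function(x, ...) {
  df <- x$summary
  graphics::plot(df$correlation, df$r2, col = "forestgreen", pch = 16,
                 ylim = range(df$r2, df$q2),
                 xlab = "|correlation with original labels|",
                 ylab = expression(R^2 ~ "/" ~ Q^2), ...)
  graphics::points(df$correlation, df$q2, col = "royalblue", pch = 17)
  graphics::abline(stats::lm(r2 ~ correlation, df), col = "forestgreen",
                   lty = 2)
  graphics::abline(stats::lm(q2 ~ correlation, df), col = "royalblue",
                   lty = 2)
  graphics::abline(h = 0, col = "grey60", lty = 3)
  graphics::legend("topleft", c("R2", "Q2"), col = c("forestgreen",
                                                     "royalblue"),
                   pch = c(16, 17), bty = "n")
  invisible(x)
}

#' Principal component scores (exploratory companion)
#'
#' Scores and explained-variance fractions of the leading principal
#' components, for unsupervised inspection alongside the supervised model.
#'
#' @param x numeric matrix (typically already UV-scaled).
#' @param ncomp number of leading components to return.
#' @param center,scale forwarded to [stats::prcomp()]; defaults assume `x`
#'   is already standardized.
#' @return List with `scores` (n x ncomp) and `explained_variance`
#'   (fractions of total variance, summing to at most 1).
#' @export
pca_scores <- function(x, ncomp = 2, center = FALSE, scale = FALSE) {
  .assert(is.matrix(x) && !anyNA(x), "x must be a complete numeric matrix")
  max_rank <- min(nrow(x) - 1L, ncol(x))
  .assert(ncomp >= 1L && ncomp <= max_rank,
          "ncomp must be between 1 and min(n - 1, p) = ", max_rank)
  pc <- stats::prcomp(x, center = center, scale. = scale)
  list(scores = pc$x[, seq_len(ncomp), drop = FALSE],
       explained_variance = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(ncomp)])
}
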