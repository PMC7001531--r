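# Exhaustive biomarker-panel evaluation: rank-sum AUC, ROC staircases,
# repeated stratified k-fold cross-validation, and panel ranking.

#' Area under the ROC curve (rank-sum form)
#'
#' Probability that a randomly chosen positive sample outscores a randomly
#' chosen negative one, with ties counted one half — the Mann-Whitney
#' formulation. Invariant under any strictly increasing transform of the
#' scores.
#'
#' @param scores numeric classifier scores, higher = more positive-like.
#' @param labels two-class labels; the second level is the positive class.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  y01 <- .as_binary(labels)$y01
  .assert(length(scores) == length(y01),
          "scores and labels must have equal length")
  .auc01(scores, y01)
}

# rank-sum AUC on pre-coded 0/1 labels (hot path of the CV loops)
.auc01 <- function(scores, y01) {
  n1 <- sum(y01 == 1L); n0 <- length(y01) - n1
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[y01 == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve coordinates
#'
#' Monotone staircase of (false-positive rate, true-positive rate) points
#' from (0, 0) to (1, 1), with tied scores collapsed into single steps so
#' the trapezoidal area equals the rank-sum [auc()].
#'
#' @inheritParams auc
#' @return Data frame with columns `fpr` and `tpr`.
#' @export
roc_points <- function(scores, labels) {
  y01 <- .as_binary(labels)$y01
  .assert(length(scores) == length(y01),
          "scores and labels must have equal length")
  n1 <- sum(y01 == 1L); n0 <- sum(y01 == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("ROC undefined: both classes must be present", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- y01[ord]
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last_of_tie]
  fp <- cumsum(1L - y)[last_of_tie]
  data.frame(fpr = c(0, fp / n0), tpr = c(0, tp / n1))
}

#' Enumerate all nonempty panels over a candidate list
#'
#' All `2^k - 1` nonempty subsets of the candidates, in deterministic
#' order: by panel size, then lexicographically with respect to the
#' candidate order (the [utils::combn()] sequence).
#'
#' @param candidates character vector of 1 to 20 candidate names.
#' @return List of character vectors, one per panel.
#' @export
enumerate_panels <- function(candidates) {
  k <- length(candidates)
  if (k < 1L) stop("candidate list is empty", call. = FALSE)
  .assert(k <= 20L, "exhaustive enumeration capped at 20 candidates")
  .assert(!anyDuplicated(candidates), "candidate names must be unique")
  unlist(lapply(seq_len(k), function(size)
    utils::combn(candidates, size, simplify = FALSE)), recursive = FALSE)
}

#' Confidence interval for a mean AUC over CV replicates
#'
#' Student-t interval over replicate-level mean AUCs:
#' `mean +/- t(1 - (1-conf)/2, df = r - 1) * SD / sqrt(r)`.
#'
#' @param replicate_means numeric vector of per-replicate mean AUCs
#'   (length >= 2).
#' @param conf confidence level, default 0.95.
#' @return Numeric vector `c(lower, upper)`.
#' @export
ci_mean_auc <- function(replicate_means, conf = 0.95) {
  r <- length(replicate_means)
  if (r < 2L) stop("need at least 2 replicate means", call. = FALSE)
  ci_from_summary(mean(replicate_means), stats::sd(replicate_means), r,
                  conf)
}

#' Replicate-t confidence interval from summary statistics
#'
#' Same convention as [ci_mean_auc()] but starting from a reported mean
#' and SD of `r` replicate means, e.g. when recomputing published
#' intervals from a results table.
#'
#' @param mean,sd reported mean and SD over the replicate means.
#' @param r number of replicates.
#' @param conf confidence level, default 0.95.
#' @return Numeric vector `c(lower, upper)`.
#' @export
ci_from_summary <- function(mean, sd, r, conf = 0.95) {
  .assert(r >= 2, "need at least 2 replicates")
  half <- stats::qt(1 - (1 - conf) / 2, df = r - 1) * sd / sqrt(r)
  c(lower = mean - half, upper = mean + half)
}

# Shared family object: constructing binomial() per fit is measurably
# expensive inside the repeated-CV loops.
.binomial <- stats::binomial()

# Train-standardize, fit unpenalized logistic regression, and return
# linear-predictor scores for train and test rows. Perfect separation is
# harmless here (only the score ranking matters), so the glm.fit
# convergence chatter is muffled.
.score_logistic <- function(xtr, ytr, xte) {
  n_tr <- nrow(xtr); n_te <- nrow(xte)
  ctr <- colMeans(xtr)
  xc <- xtr - rep(ctr, each = n_tr)
  scl <- sqrt(colSums(xc * xc) / (n_tr - 1))
  scl[scl < 1e-12] <- 1
  xs_tr <- cbind(1, xc / rep(scl, each = n_tr))
  xs_te <- cbind(1, (xte - rep(ctr, each = n_te)) / rep(scl, each = n_te))
  fit <- suppressWarnings(
    stats::glm.fit(xs_tr, ytr, family = .binomial))
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  list(train = drop(xs_tr %*% beta), test = drop(xs_te %*% beta))
}

.score_plsda <- function(xtr, ytr, xte) {
  a <- min(2L, ncol(xtr), nrow(xtr) - 1L)
  fit <- plsda(xtr, ytr, ncomp = a)
  list(train = predict(fit),
       test = predict(fit, newdata = xte))
}

#' Repeated stratified cross-validated AUC of one panel
#'
#' Evaluates a feature panel by `n_replicates` independent rounds of
#' stratified `n_folds`-fold cross-validation. Per fold, the classifier
#' (and its standardization) is fitted on the training split only and the
#' held-out samples are scored; fold-level test AUCs are averaged into
#' replicate means. The summary follows the usual reporting convention:
#' the overall mean test AUC over all folds of all replicates, the SD of
#' the replicate-level means, and a Student-t 95% CI over the replicate
#' means.
#'
#' @param x numeric matrix restricted to the panel's columns.
#' @param y two-class labels (second level = positive).
#' @param n_replicates CV repetitions, default 10.
#' @param n_folds folds per repetition, default 10. Reduced (with a
#'   warning) to the smaller class size when stratified folds could not
#'   otherwise hold both classes in every test fold.
#' @param seed optional integer seed: the same seed gives a bit-identical
#'   result.
#' @param classifier `"logistic"` (default) for unpenalized logistic
#'   regression, or `"plsda"` to score by a two-component PLS-DA fitted
#'   within each training split.
#' @return Object of class `"panel_cv"`: `panel` (column names),
#'   `mean_auc_train`, `mean_auc_test`, `sd_auc_test` (over replicate
#'   means), `ci95_test`, `replicate_means`, the per-fold AUC matrices,
#'   and the run parameters.
#' @export
cv_auc_panel <- function(x, y, n_replicates = 10, n_folds = 10,
                         seed = NULL, classifier = c("logistic", "plsda")) {
  classifier <- match.arg(classifier)
  .assert(is.matrix(x) && !anyNA(x), "x must be a complete numeric matrix")
  bin <- .as_binary(y)
  y01 <- bin$y01
  .assert(length(y01) == nrow(x), "length(y) must equal nrow(x)")
  n1 <- sum(y01 == 1L); n0 <- sum(y01 == 0L)
  .assert(n1 > 0L && n0 > 0L, "both classes must be present")
  k <- min(n_folds, n1, n0)
  if (k < 2L)
    stop("too few samples per class for cross-validation", call. = FALSE)
  if (k < n_folds)
    warning("fold count reduced from ", n_folds, " to ", k,
            " so every stratified test fold holds both classes",
            call. = FALSE)
  score_fun <- switch(classifier, logistic = .score_logistic,
                      plsda = function(xtr, ytr, xte)
                        .score_plsda(xtr, ytr, xte))
  .set_seed(seed)
  auc_test <- auc_train <- matrix(NA_real_, n_replicates, k)
  for (rep_i in seq_len(n_replicates)) {
    fold_id <- .stratified_folds(y01, k)
    for (f in seq_len(k)) {
      te <- fold_id == f
      tr <- !te
      sc <- score_fun(x[tr, , drop = FALSE], y01[tr], x[te, , drop = FALSE])
      auc_train[rep_i, f] <- .auc01(sc$train, y01[tr])
      auc_test[rep_i, f] <- .auc01(sc$test, y01[te])
    }
  }
  replicate_means <- rowMeans(auc_test)
  structure(list(panel = colnames(x),
                 mean_auc_train = mean(auc_train),
                 mean_auc_test = mean(auc_test),
                 sd_auc_test = stats::sd(replicate_means),
                 ci95_test = ci_mean_auc(replicate_means),
                 replicate_means = replicate_means,
                 fold_auc_test = auc_test,
                 fold_auc_train = auc_train,
                 n_replicates = n_replicates, n_folds = k,
                 classifier = classifier, seed = seed),
            class = "panel_cv")
}

#' @export
print.panel_cv <- function(x, digits = 3, ...) {
  cat("Panel:", paste(x$panel, collapse = " + "), "\n")
  cat(sprintf("  %d x %d-fold CV (%s): train AUC %.*f, test AUC %.*f (SD %.*f, 95%% CI %.*f-%.*f)\n",
              x$n_replicates, x$n_folds, x$classifier,
              digits, x$mean_auc_train, digits, x$mean_auc_test,
              digits, x$sd_auc_test, digits, x$ci95_test[1],
              digits, x$ci95_test[2]))
  invisible(x)
}

#' Rank evaluated panels by mean test AUC
#'
#' Descending mean test AUC; ties broken by descending mean training AUC,
#' then by panel name, so the ranking is deterministic and invariant to
#' input order.
#'
#' @param results list of [cv_auc_panel()] objects.
#' @param candidates candidate names for the membership indicator columns
#'   (default: union of all panel members).
#' @return Data frame of class `"panel_ranking"`: one row per panel with
#'   0/1 membership columns, `panel`, `size`, `mean_auc_train`,
#'   `mean_auc_test`, `sd_auc_test`, `ci95_lower`, `ci95_upper`, `rank`.
#' @export
rank_panels <- function(results, candidates = NULL) {
  .assert(length(results) >= 1L, "no panel results to rank")
  .assert(all(vapply(results, inherits, logical(1), "panel_cv")),
          "results must be cv_auc_panel() objects")
  if (is.null(candidates))
    candidates <- unique(unlist(lapply(results, `[[`, "panel")))
  member <- t(vapply(results, function(r)
    as.integer(candidates %in% r$panel), integer(length(candidates))))
  colnames(member) <- candidates
  df <- data.frame(member, check.names = FALSE)
  df$panel <- vapply(results, function(r) paste(r$panel, collapse = "+"),
                     character(1))
  df$size <- vapply(results, function(r) length(r$panel), integer(1))
  df$mean_auc_train <- vapply(results, `[[`, numeric(1), "mean_auc_train")
  df$mean_auc_test <- vapply(results, `[[`, numeric(1), "mean_auc_test")
  df$sd_auc_test <- vapply(results, `[[`, numeric(1), "sd_auc_test")
  df$ci95_lower <- vapply(results, function(r) r$ci95_test[[1]], numeric(1))
  df$ci95_upper <- vapply(results, function(r) r$ci95_test[[2]], numeric(1))
  ord <- order(-df$mean_auc_test, -df$mean_auc_train, df$panel)
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  class(df) <- c("panel_ranking", "data.frame")
  df
}

#' @export
print.panel_ranking <- function(x, n = 10, digits = 3, ...) {
  cat("Panel ranking by mean test AUC (", nrow(x), " panels)\n", sep = "")
  cols <- intersect(c("rank", "panel", "mean_auc_train", "mean_auc_test",
                      "sd_auc_test", "ci95_lower", "ci95_upper"), names(x))
  print.data.frame(utils::head(x[, cols, drop = FALSE], n),
                   digits = digits, row.names = FALSE)
  if (nrow(x) > n) cat("  ... and", nrow(x) - n, "more\n")
  invisible(x)
}

#' Exhaustively evaluate and rank all panels over a candidate set
#'
#' Enumerates every nonempty subset of the candidates, evaluates each with
#' [cv_auc_panel()] (all panels share the same seed, hence the same fold
#' assignments, making panel comparisons paired), and ranks the results.
#'
#' @param x numeric matrix whose columns include all candidates.
#' @param y two-class labels.
#' @param candidates candidate column names, default all columns of `x`.
#' @inheritParams cv_auc_panel
#' @return A [rank_panels()] table covering all `2^k - 1` panels.
#' @export
panel_search <- function(x, y, candidates = colnames(x),
                         n_replicates = 10, n_folds = 10, seed = NULL,
                         classifier = c("logistic", "plsda")) {
  classifier <- match.arg(classifier)
  .assert(all(candidates %in% colnames(x)),
          "candidates must be columns of x")
  panels <- enumerate_panels(candidates)
  results <- lapply(panels, function(p)
    cv_auc_panel(x[, p, drop = FALSE], y, n_replicates = n_replicates,
                 n_folds = n_folds, seed = seed, classifier = classifier))
  rank_panels(results, candidates = candidates)
}

#' Append a standardized clinical covariate to a feature matrix
#'
#' Adds one mean-centered, unit-variance column (e.g. age) so that
#' downstream cross-validation treats it like any metabolite.
#'
#' @param x numeric feature matrix.
#' @param covariate numeric vector, one value per sample.
#' @param name column name for the new covariate.
#' @return `x` with one extra column.
#' @export
augment_with_covariate <- function(x, covariate, name = "age") {
  .assert(is.matrix(x), "x must be a matrix")
  if (length(covariate) != nrow(x))
    stop("covariate length (", length(covariate),
         ") does not match sample count (", nrow(x), ")", call. = FALSE)
  s <- stats::sd(covariate)
  if (is.na(s) || s == 0)
    stop("covariate '", name, "' has zero variance", call. = FALSE)
  .assert(!name %in% colnames(x), "column '", name, "' already present")
  out <- cbind(x, (covariate - mean(covariate)) / s)
  colnames(out)[ncol(out)] <- name
  out
}
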