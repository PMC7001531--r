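# Two-class PLS-DA via the PLS1 NIPALS sequence with y deflation.
# The class label is coded 0/1 (first level = 0) and mean-centered; for a
# single centered response each NIPALS component is closed-form: the weight
# is the normalized covariance of the X residual with the y residual.

# Core extractor. xs: centered/scaled matrix; yc: centered response.
# Returns weights W (unit norm), loadings P, scores T, y-loadings q, and
# ssy (y sum of squares explained per component).
.pls1 <- function(xs, yc, ncomp) {
  n <- nrow(xs); p <- ncol(xs)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  q <- numeric(ncomp); ssy <- numeric(ncomp)
  Xr <- xs; yr <- yc
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xr, yr)
    nw <- sqrt(sum(w * w))
    if (nw < 1e-12)
      stop("component ", a, " exceeds the rank of the data: no residual ",
           "covariance left", call. = FALSE)
    w <- w / nw
    t_a <- Xr %*% w
    tt <- sum(t_a * t_a)
    if (tt < 1e-12)
      stop("component ", a, " has a degenerate score vector", call. = FALSE)
    p_a <- crossprod(Xr, t_a) / tt
    q_a <- sum(yr * t_a) / tt
    Xr <- Xr - tcrossprod(t_a, p_a)
    yr <- yr - q_a * t_a
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a
    q[a] <- q_a; ssy[a] <- q_a^2 * tt
  }
  list(weights = W, loadings = P, scores = Tm, y_loadings = q,
       ssy = ssy, x_residual = Xr, y_residual = yr)
}

# Regression coefficients for the first `a` components:
# B = W_a (P_a' W_a)^{-1} q_a, mapping standardized X to centered y.
.pls1_coef <- function(fit, a) {
  Wa <- fit$weights[, seq_len(a), drop = FALSE]
  Pa <- fit$loadings[, seq_len(a), drop = FALSE]
  qa <- fit$y_loadings[seq_len(a)]
  drop(Wa %*% solve(crossprod(Pa, Wa), qa))
}

#' Fit a two-class PLS-DA model
#'
#' Partial least-squares discriminant analysis for two groups. The class
#' label is coded 0/1 (first factor level = 0) and mean-centered; the
#' predictor matrix is mean-centered and unit-variance scaled by default.
#' Components are extracted by the NIPALS sequence: each weight vector is
#' the normalized covariance of the X residual with the y residual, scores
#' are the projection of the X residual on the weight, and both X and y
#' are deflated by the fitted component.
#'
#' @param x numeric matrix, samples x variables (metabolites).
#' @param y two-class labels: factor, logical, or two-valued vector. The
#'   second level is coded 1 (e.g. poor recovery).
#' @param ncomp number of components, default 2.
#' @param center,scale apply mean-centering / unit-variance scaling to `x`
#'   before fitting (defaults `TRUE`; set `scale = FALSE` if `x` is already
#'   standardized).
#' @return An object of class `"plsda"`: list with `weights` (p x A, unit
#'   norm columns), `loadings`, `scores` (n x A, mutually orthogonal),
#'   `y_loadings`, `r2y` (cumulative fraction of label variance explained
#'   per component count), `ssy`, `coefficients`, centering/scaling
#'   metadata, `y01`, and the class `levels`.
#' @seealso [vip()], [r2y()], [q2y()], [permutation_validate()],
#'   [predict.plsda()]
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(40 * 5), 40, 5,
#'             dimnames = list(NULL, paste0("m", 1:5)))
#' y <- rep(c("GR", "PR"), each = 20)
#' x[y == "PR", 1] <- x[y == "PR", 1] + 2
#' fit <- plsda(x, y)
#' fit
#' vip(fit)
#' @export
plsda <- function(x, y, ncomp = 2, center = TRUE, scale = TRUE) {
  .assert(is.matrix(x) && is.numeric(x) && !anyNA(x),
          "x must be a complete numeric matrix")
  bin <- .as_binary(y)
  .assert(length(bin$y01) == nrow(x), "length(y) must equal nrow(x)")
  max_rank <- min(nrow(x) - 1L, ncol(x))
  .assert(ncomp >= 1L && ncomp <= max_rank,
          "ncomp must be between 1 and min(n - 1, p) = ", max_rank)
  ctr <- if (center) colMeans(x) else rep(0, ncol(x))
  scl <- if (scale) apply(x, 2L, stats::sd) else rep(1, ncol(x))
  if (any(scl == 0))
    stop("zero-variance column(s): ",
         paste(colnames(x)[scl == 0], collapse = ", "), call. = FALSE)
  xs <- scale(x, ctr, scl)
  y_mean <- mean(bin$y01)
  yc <- bin$y01 - y_mean
  ss_y <- sum(yc * yc)
  if (ss_y == 0) stop("labels have zero variance", call. = FALSE)

  fit <- .pls1(xs, yc, ncomp)
  vars <- colnames(x)
  dimnames(fit$weights) <- dimnames(fit$loadings) <-
    list(vars, paste0("comp", seq_len(ncomp)))
  dimnames(fit$scores) <- list(rownames(x), paste0("comp", seq_len(ncomp)))

  structure(list(
    ncomp = ncomp,
    weights = fit$weights,
    loadings = fit$loadings,
    scores = fit$scores,
    y_loadings = fit$y_loadings,
    ssy = fit$ssy,
    r2y = cumsum(fit$ssy) / ss_y,
    coefficients = stats::setNames(.pls1_coef(fit, ncomp), vars),
    x_center = ctr, x_scale = scl,
    y_mean = y_mean, y01 = bin$y01, levels = bin$levels,
    n = nrow(x), p = ncol(x),
    call = match.call()
  ), class = "plsda")
}

#' Cumulative R2Y of a fitted PLS-DA model
#'
#' Fraction of the centered class-label variance explained, cumulatively
#' by component count: `1 - RSS(a)/TSS`. Non-decreasing in the number of
#' components.
#'
#' @param model a [plsda()] fit.
#' @return Numeric vector of length `ncomp`.
#' @export
r2y <- function(model) {
  .assert(inherits(model, "plsda"), "model must be a plsda fit")
  model$r2y
}

#' Variable Importance in Projection (VIP) scores
#'
#' Wold's VIP: for variable j,
#' `VIP_j = sqrt( p * sum_a SSY_a w_aj^2 / sum_a SSY_a )`
#' with unit-norm weight vectors `w_a` and `SSY_a` the label variance
#' explained by component a. The squared scores average to 1, so VIP > 1
#' marks variables contributing more than average to the discrimination.
#'
#' @param model a [plsda()] fit with at least one component.
#' @return Named nonnegative numeric vector, one score per variable;
#'   `sum(vip^2) == p`.
#' @export
vip <- function(model) {
  .assert(inherits(model, "plsda"), "model must be a plsda fit")
  if (sum(model$ssy) <= 0)
    stop("no label variance explained: VIP undefined", call. = FALSE)
  w2 <- model$weights^2
  v <- sqrt(model$p * drop(w2 %*% model$ssy) / sum(model$ssy))
  stats::setNames(v, rownames(model$weights))
}

#' Select biomarkers by VIP threshold
#'
#' Keeps variables whose VIP is strictly greater than the threshold,
#' ordered by descending VIP with ties broken by name.
#'
#' @param scores named VIP vector from [vip()].
#' @param threshold selection cutoff, default 1.
#' @return Character vector of selected variable names (possibly empty).
#' @export
select_biomarkers <- function(scores, threshold = 1) {
  sel <- scores[scores > threshold]
  names(sel)[order(-sel, names(sel))]
}

#' @export
print.plsda <- function(x, digits = 3, ...) {
  cat("Two-class PLS-DA (NIPALS)\n")
  cat(sprintf("  %d samples (%s = 0, %s = 1), %d variables, %d component(s)\n",
              x$n, x$levels[1], x$levels[2], x$p, x$ncomp))
  cat("  cumulative R2Y:", paste(format(x$r2y, digits = digits),
                                 collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.plsda <- function(object, vip_threshold = 1, ...) {
  v <- vip(object)
  structure(list(fit = object, vip = v[order(-v, names(v))],
                 selected = select_biomarkers(v, vip_threshold),
                 vip_threshold = vip_threshold),
            class = "summary.plsda")
}

#' @export
print.summary.plsda <- function(x, digits = 3, ...) {
  print(x$fit, digits = digits)
  cat("\nVIP scores (descending):\n")
  print(round(x$vip, digits))
  cat("\nVIP >", x$vip_threshold, "selection:",
      if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' Regression coefficients of a PLS-DA fit
#'
#' Coefficients mapping the standardized predictors to the centered 0/1
#' class code, using the first `ncomp` components.
#'
#' @param object a [plsda()] fit.
#' @param ncomp number of components to use (default: all fitted).
#' @param ... unused.
#' @return Named numeric vector of length p.
#' @export
coef.plsda <- function(object, ncomp = object$ncomp, ...) {
  .assert(ncomp >= 1L && ncomp <= object$ncomp,
          "ncomp must be between 1 and the fitted number of components")
  if (ncomp == object$ncomp) return(object$coefficients)
  stats::setNames(.pls1_coef(object, ncomp), names(object$coefficients))
}

#' Predict from a PLS-DA fit
#'
#' @param object a [plsda()] fit.
#' @param newdata numeric matrix with the training variables as columns;
#'   defaults to the training data reconstruction.
#' @param ncomp components to use.
#' @param type `"response"` for the continuous predicted class code
#'   (near 0 = first level, near 1 = second level), `"class"` for hard
#'   labels at the 0.5 midpoint, `"scores"` for latent component scores.
#' @param ... unused.
#' @return Numeric vector, factor, or score matrix according to `type`.
#' @export
predict.plsda <- function(object, newdata = NULL, ncomp = object$ncomp,
                          type = c("response", "class", "scores"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    # On the training data the latent scores are stored and yhat = T q.
    if (type == "scores")
      return(object$scores[, seq_len(ncomp), drop = FALSE])
    Ta <- object$scores[, seq_len(ncomp), drop = FALSE]
    yhat <- drop(object$y_mean + Ta %*% object$y_loadings[seq_len(ncomp)])
  } else {
    .assert(is.matrix(newdata) && ncol(newdata) == object$p,
            "newdata must be a matrix with ", object$p, " columns")
    if (!is.null(colnames(newdata)) &&
        !is.null(names(object$coefficients)) &&
        !identical(colnames(newdata), names(object$coefficients)))
      newdata <- newdata[, names(object$coefficients), drop = FALSE]
    xs <- scale(newdata, object$x_center, object$x_scale)
    if (type == "scores") {
      Wa <- object$weights[, seq_len(ncomp), drop = FALSE]
      Pa <- object$loadings[, seq_len(ncomp), drop = FALSE]
      return(xs %*% Wa %*% solve(crossprod(Pa, Wa)))
    }
    b <- coef(object, ncomp = ncomp)
    yhat <- drop(object$y_mean + xs %*% b)
  }
  if (type == "response") return(yhat)
  factor(object$levels[(yhat > 0.5) + 1L], levels = object$levels)
}

#' @export
fitted.plsda <- function(object, ...) {
  drop(object$y_mean + object$scores %*% object$y_loadings)
}

#' @export
residuals.plsda <- function(object, ...) {
  object$y01 - fitted(object)
}

#' Score plot of a PLS-DA fit
#'
#' Scatter plot of two latent components colored by class, the standard
#' separation display for two-group discriminant models.
#'
#' @param x a [plsda()] fit.
#' @param comps which two components to display.
#' @param ... passed to [graphics::plot()].
#' @export
plot.plsda <- function(x, comps = c(1, 2), ...) {
  .assert(length(comps) == 2L && max(comps) <= x$ncomp,
          "comps must name two fitted components")
  s <- x$scores[, comps, drop = FALSE]
  cls <- x$y01 + 1L
  graphics::plot(s[, 1], s[, 2], col = c("forestgreen", "royalblue")[cls],
                 pch = c(16, 17)[cls],
                 xlab = colnames(s)[1], ylab = colnames(s)[2], ...)
  graphics::abline(h = 0, v = 0, lty = 3, col = "grey60")
  graphics::legend("topright", legend = x$levels, bty = "n",
                   col = c("forestgreen", "royalblue"), pch = c(16, 17))
  invisible(x)
}
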