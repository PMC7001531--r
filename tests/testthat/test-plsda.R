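# PLS-DA core: NIPALS extraction, R2Y/Q2Y, VIP, permutation validation,
# and the PCA companion. mixOmics (when available) serves as an
# independent reference implementation for the dual-route checks.

test_that("first weight vector is proportional to the class-mean difference", {
  d <- make_signal_matrix(shift = 1.5, shifted_cols = c(1, 3))
  fit <- plsda(d$x, d$y)
  xs <- scale(d$x)
  diff <- colMeans(xs[d$y == "B", ]) - colMeans(xs[d$y == "A", ])
  expected <- diff / sqrt(sum(diff^2))
  got <- fit$weights[, 1] * sign(sum(fit$weights[, 1] * expected))
  expect_equal(unname(got), unname(expected), tolerance = 1e-8)
})

test_that("NIPALS components have the structural invariants", {
  d <- make_signal_matrix(n_per_class = 10, p = 5, shift = 1)
  fit <- plsda(d$x, d$y, ncomp = 3)
  # unit-norm weights
  expect_equal(unname(colSums(fit$weights^2)), rep(1, 3))
  # mutually orthogonal scores
  g <- crossprod(fit$scores)
  off <- g[upper.tri(g)] / sqrt(diag(g)[c(1, 1, 2)] * diag(g)[c(2, 3, 3)])
  expect_true(all(abs(off) < 1e-8))
  # rank-complete extraction reconstructs the standardized matrix
  full <- plsda(d$x, d$y, ncomp = 5)
  xs <- scale(d$x)
  recon <- full$scores %*% t(full$loadings)
  expect_lt(max(abs(xs - recon)), 1e-8)
})

test_that("fits are invariant to sample order", {
  d <- make_signal_matrix(seed = 7)
  fit <- plsda(d$x, d$y)
  set.seed(3)
  perm <- sample(nrow(d$x))
  fit_p <- plsda(d$x[perm, ], d$y[perm])
  # weights/loadings fixed up to numerical noise, scores permuted along
  align <- sign(diag(crossprod(fit$weights, fit_p$weights)))
  expect_equal(fit_p$weights %*% diag(align), fit$weights,
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(fit_p$scores %*% diag(align), fit$scores[perm, ],
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("R2Y is cumulative, non-decreasing, and exact for a perfect predictor", {
  y <- rep(c(0, 1), each = 8)
  x1 <- cbind(a = as.numeric(y))
  fit1 <- plsda(x1, y, ncomp = 1)
  expect_equal(r2y(fit1)[1], 1)

  d <- make_signal_matrix(shift = 1)
  fit <- plsda(d$x, d$y, ncomp = 4)
  expect_true(all(diff(r2y(fit)) >= -1e-12))
  expect_true(all(r2y(fit) >= 0 & r2y(fit) <= 1 + 1e-12))

  # strongly separable synthetic data: R2Y > 0.9 at two components
  big <- make_signal_matrix(n_per_class = 20, p = 8, shift = 6,
                            shifted_cols = 1:4, seed = 5)
  expect_gt(r2y(plsda(big$x, big$y, ncomp = 2))[2], 0.9)

  expect_error(plsda(d$x, rep("A", nrow(d$x))), "two classes")
  expect_error(plsda(d$x, d$y, ncomp = 40), "ncomp")
})

test_that("Q2Y matches a leave-one-out PRESS oracle on a small problem", {
  # 6 samples, 2 variables; LOO folds. The oracle recomputes each held-out
  # prediction with an independent PLS implementation (mixOmics).
  skip_if_not_installed("mixOmics")
  x <- cbind(m1 = c(0.2, 1.1, -0.4, 2.3, 3.0, 2.2),
             m2 = c(1.0, 0.1, 0.5, -0.8, -1.2, -0.3))
  rownames(x) <- paste0("s", 1:6)
  y01 <- c(0, 0, 0, 1, 1, 1)
  press <- 0
  for (i in 1:6) {
    tr_x <- x[-i, , drop = FALSE]; tr_y <- y01[-i]
    mo <- mixOmics::pls(tr_x, tr_y, ncomp = 1, mode = "regression",
                        scale = TRUE)
    pred <- predict(mo, x[i, , drop = FALSE])$predict[1, 1, 1]
    press <- press + (y01[i] - pred)^2
  }
  q2_oracle <- 1 - press / sum((y01 - mean(y01))^2)
  q2_mine <- q2y(x, y01, ncomp = 1, folds = 1:6)  # explicit LOO folds
  expect_equal(q2_mine[1], q2_oracle, tolerance = 1e-10)
})

test_that("full fits agree with the mixOmics reference implementation", {
  skip_if_not_installed("mixOmics")
  d <- make_signal_matrix(shift = 1.5, shifted_cols = c(1, 3), seed = 42)
  y01 <- as.integer(d$y) - 1L
  fit <- plsda(d$x, d$y, ncomp = 2)
  mo <- mixOmics::pls(d$x, y01, ncomp = 2, mode = "regression",
                      scale = TRUE)
  for (a in 1:2) {
    w <- fit$weights[, a]; mw <- mo$loadings$X[, a]
    expect_equal(unname(w), unname(sign(sum(w * mw)) * mw),
                 tolerance = 1e-10)
  }
  xnew <- matrix(rnorm(30), 5, 6, dimnames = list(NULL, colnames(d$x)))
  expect_equal(unname(predict(fit, xnew)),
               unname(predict(mo, xnew)$predict[, , 2]), tolerance = 1e-10)
  expect_equal(unname(vip(fit)), unname(mixOmics::vip(mo)[, 2]),
               tolerance = 1e-10)
})

test_that("Q2Y of pure noise is near zero and bounded by R2Y", {
  # null behavior: with y independent of x, Q2 rarely exceeds 0.1
  set.seed(88)
  hits <- vapply(seq_len(200), function(i) {
    x <- matrix(rnorm(40 * 20), 40, 20)
    y <- rep(c(0, 1), each = 20)
    q2y(x, y, ncomp = 2, folds = 7)[2] <= 0.1
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  # Q2 <= R2Y for matched component count on simulated datasets
  set.seed(99)
  ok <- vapply(seq_len(50), function(i) {
    d <- make_signal_matrix(n_per_class = 12, p = 8,
                            shift = runif(1, 0, 2), seed = 200 + i)
    fit <- plsda(d$x, d$y, ncomp = 2)
    all(q2y(d$x, d$y, ncomp = 2, folds = 7) <= r2y(fit) + 1e-9)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("VIP follows Wold's formula and its normalization identity", {
  # hand-computable single-component case: weights (0.8, 0.6)
  toy <- structure(list(
    weights = matrix(c(0.8, 0.6), 2, 1, dimnames = list(c("a", "b"), NULL)),
    ssy = 1, p = 2), class = "plsda")
  expect_equal(unname(vip(toy)), c(sqrt(2 * 0.64), sqrt(2 * 0.36)))
  expect_equal(round(unname(vip(toy)), 4), c(1.1314, 0.8485))

  # equal-magnitude weights give VIP = 1 everywhere
  unif <- structure(list(
    weights = matrix(rep(1 / sqrt(4), 4), 4, 1,
                     dimnames = list(letters[1:4], NULL)),
    ssy = 0.7, p = 4), class = "plsda")
  expect_equal(unname(vip(unif)), rep(1, 4))

  # sum of squared VIPs equals p for every fitted model
  for (i in 1:5) {
    d <- make_signal_matrix(n_per_class = 10, p = 7,
                            shift = runif(1, 0, 3), seed = 300 + i)
    fit <- plsda(d$x, d$y, ncomp = sample(1:3, 1))
    expect_equal(sum(vip(fit)^2), 7, tolerance = 1e-8)
  }
})

test_that("VIP selection uses a strict threshold and deterministic order", {
  v <- c(thr = 1.04, arg = 1.47, glu = 1.89, pro = 1.97, leu = 2.46,
         ala = 0.9, ser = 0.8, gly = 1.0)
  sel <- select_biomarkers(v)
  expect_equal(sel, c("leu", "pro", "glu", "arg", "thr"))
  expect_length(sel, 5L)  # VIP exactly 1.0 is excluded
  expect_equal(select_biomarkers(c(a = 0.4, b = 0.99)), character(0))
  # ties broken by name
  expect_equal(select_biomarkers(c(z = 1.5, a = 1.5)), c("a", "z"))
})

test_that("spiked metabolites are selected by VIP on default cohorts", {
  # Oracle-measured recovery property at the generator's conditions: the
  # five spiked analytes are all within the VIP>1 set in ~86% of seeds
  # (development run, 100 seeds); exact-set recovery is much rarer because
  # ~half of all seeds push one of the 15 null analytes over 1.
  hits <- vapply(seq_len(60), function(i) {
    co <- make_cohort(seed = 10000 + i)
    fit <- plsda(preprocess_cohort(co), co$true_labels)
    all(co$true_discriminative_set %in% select_biomarkers(vip(fit)))
  }, logical(1))
  expect_gte(mean(hits), 0.75)
})

test_that("permutation validation flags honest models and reproduces the original", {
  co <- make_cohort()
  x <- preprocess_cohort(co)
  pv <- permutation_validate(x, co$true_labels, n_permutations = 60,
                             seed = 42)
  expect_equal(nrow(pv$summary), 61L)
  expect_equal(pv$summary$correlation[1], 1)
  expect_false(pv$summary$permuted[1])
  # the unpermuted row reproduces the plain fit's R2Y
  fit <- plsda(x, co$true_labels, ncomp = 2)
  expect_equal(pv$summary$r2[1], r2y(fit)[2], tolerance = 1e-10)
  # strong signal: original Q2 beats at least 95% of permuted Q2 values
  expect_gte(mean(pv$summary$q2[1] > pv$summary$q2[-1]), 0.95)
  expect_true(pv$valid)
  expect_lt(pv$q2_intercept, 0)

  expect_warning(permutation_validate(x, co$true_labels,
                                      n_permutations = 10, seed = 1),
                 "unstable")
})

test_that("PCA scores decompose variance correctly", {
  # collinear data: one component carries all variance
  t <- rnorm(20)
  line <- cbind(t, 2 * t, -t)
  pc <- pca_scores(line, ncomp = 1)
  expect_equal(pc$explained_variance[1], 1)

  set.seed(21)
  x <- scale(matrix(rnorm(30 * 5), 30, 5))
  pc5 <- pca_scores(x, ncomp = 4)
  g <- crossprod(pc5$scores)
  expect_true(all(abs(g[upper.tri(g)]) < 1e-8))
  # total variance conserved across the full decomposition
  full <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  expect_equal(sum(full$sdev^2), sum(apply(x, 2, var)), tolerance = 1e-10)
})

test_that("predict/coef/fitted methods are mutually consistent", {
  d <- make_signal_matrix(shift = 2.5, shifted_cols = 1:2)
  fit <- plsda(d$x, d$y)
  # in-sample predictions equal the coefficient path applied to new data
  expect_equal(unname(predict(fit)), unname(predict(fit, d$x)),
               tolerance = 1e-10)
  expect_equal(unname(predict(fit)), unname(fitted(fit)),
               tolerance = 1e-10)
  expect_equal(unname(residuals(fit)),
               unname((as.integer(d$y) - 1) - fitted(fit)))
  # hard labels recover the groups on a strong signal
  cls <- predict(fit, d$x, type = "class")
  expect_gte(mean(cls == d$y), 0.9)
  expect_length(coef(fit), ncol(d$x))
})
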