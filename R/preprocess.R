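# Preprocessing of targeted peak-area matrices: sparse-metabolite removal,
# per-sample median normalization, half-minimum imputation, UV scaling, and
# group summaries (fold changes, heat-map matrix).

.check_peak_matrix <- function(x) {
  .assert(is.matrix(x) && is.numeric(x),
          "peak table must be a numeric matrix (samples x metabolites)")
  .assert(!is.null(rownames(x)) && !anyDuplicated(rownames(x)),
          "peak table needs unique sample ids as row names")
  .assert(!is.null(colnames(x)) && !anyDuplicated(colnames(x)),
          "peak table needs unique metabolite names as column names")
  .assert(all(x >= 0, na.rm = TRUE), "peak areas must be nonnegative")
  invisible(x)
}

#' Drop metabolites with excessive missingness
#'
#' Removes metabolites (columns) whose fraction of missing samples exceeds
#' `max_missing_fraction`, e.g. an analyte undetected in most samples.
#' Retained values are untouched and column order is preserved.
#'
#' @param x numeric matrix, samples x metabolites, `NA` = not detected.
#' @param max_missing_fraction drop a metabolite when its missing fraction
#'   is strictly greater than this; default 0.5 ("missing in most samples").
#' @return List with `table` (the reduced matrix) and `dropped`
#'   (character vector of removed metabolite names).
#' @export
drop_sparse_metabolites <- function(x, max_missing_fraction = 0.5) {
  .check_peak_matrix(x)
  .assert(max_missing_fraction >= 0 && max_missing_fraction <= 1,
          "max_missing_fraction must lie in [0, 1]")
  frac <- colMeans(is.na(x))
  drop <- frac > max_missing_fraction
  if (all(drop))
    stop("all metabolites exceed the missingness threshold", call. = FALSE)
  list(table = x[, !drop, drop = FALSE], dropped = colnames(x)[drop])
}

#' Median-normalize a peak-area matrix
#'
#' Divides every value by its own sample's median over the non-missing
#' retained metabolites, removing per-sample technical scale. Missing
#' entries stay missing. After normalization every sample's median is 1.
#'
#' @param x numeric matrix, samples x metabolites (sparse metabolites
#'   should already be dropped, so mostly-missing columns do not perturb
#'   the divisors).
#' @return The normalized matrix with attribute `"sample_medians"` holding
#'   the per-sample divisors.
#' @export
median_normalize <- function(x) {
  .check_peak_matrix(x)
  med <- apply(x, 1L, stats::median, na.rm = TRUE)
  bad <- is.na(med) | med <= 0
  if (any(bad))
    stop("sample(s) with no positive median: ",
         paste(rownames(x)[bad], collapse = ", "), call. = FALSE)
  out <- x / med
  attr(out, "sample_medians") <- med
  out
}

#' Impute scattered non-detects by half the minimum
#'
#' Replaces each remaining missing cell by half the minimum observed value
#' of that metabolite — the standard targeted-metabolomics convention for
#' values below the detection limit. Metabolites missing everywhere should
#' have been removed by [drop_sparse_metabolites()] first and raise an
#' error here.
#'
#' @param x numeric matrix, samples x metabolites.
#' @return The completed matrix.
#' @export
impute_half_min <- function(x) {
  .check_peak_matrix(x)
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (!any(miss)) next
    if (all(miss))
      stop("metabolite '", colnames(x)[j], "' is entirely missing; ",
           "drop sparse metabolites before imputing", call. = FALSE)
    x[miss, j] <- min(x[!miss, j]) / 2
  }
  x
}

#' Mean-center and unit-variance scale a complete matrix
#'
#' Column-standardizes using the sample (n-1) standard deviation, the
#' common chemometrics convention. The centers and scales are attached so
#' they can be applied to held-out samples.
#'
#' @param x complete numeric matrix, samples x metabolites.
#' @return Standardized matrix with attributes `"scaled:center"` and
#'   `"scaled:scale"`.
#' @export
uv_scale <- function(x) {
  .assert(is.matrix(x) && is.numeric(x) && !anyNA(x),
          "uv_scale needs a complete numeric matrix")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance metabolite(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  scale(x)
}

#' Per-metabolite group fold changes
#'
#' Ratio of poor-recovery to good-recovery group means of the normalized
#' quantities; a value above 1 means the metabolite is elevated in the
#' poor-recovery group.
#'
#' @param x normalized matrix, samples x metabolites, with sample ids as
#'   row names.
#' @param cohort a [stratify_extremes()] result (or any list with
#'   `good_ids` and `poor_ids`).
#' @return Named numeric vector of PR/GR mean ratios.
#' @export
compute_fold_changes <- function(x, cohort) {
  .assert(all(cohort$good_ids %in% rownames(x)) &&
            all(cohort$poor_ids %in% rownames(x)),
          "cohort ids not all present in the table")
  gr_mean <- colMeans(x[cohort$good_ids, , drop = FALSE], na.rm = TRUE)
  pr_mean <- colMeans(x[cohort$poor_ids, , drop = FALSE], na.rm = TRUE)
  if (any(gr_mean == 0))
    stop("zero good-recovery mean for: ",
         paste(colnames(x)[gr_mean == 0], collapse = ", "), call. = FALSE)
  pr_mean / gr_mean
}

#' Heat-map matrix relative to the good-recovery mean
#'
#' Expresses each sample's normalized value as a ratio to the
#' good-recovery group mean of that metabolite, the scale used for
#' group-contrast heat maps (1 = at the GR average).
#'
#' @param x normalized matrix, samples x metabolites.
#' @param cohort a [stratify_extremes()] result.
#' @param metabolites metabolite names to include (default: all columns).
#' @return Matrix of ratios with rows ordered good group then poor group.
#' @export
heatmap_matrix <- function(x, cohort, metabolites = colnames(x)) {
  missing_names <- setdiff(metabolites, colnames(x))
  if (length(missing_names))
    stop("unknown metabolite(s): ", paste(missing_names, collapse = ", "),
         call. = FALSE)
  sel <- x[c(cohort$good_ids, cohort$poor_ids), metabolites, drop = FALSE]
  gr_mean <- colMeans(x[cohort$good_ids, metabolites, drop = FALSE],
                      na.rm = TRUE)
  sweep(sel, 2L, gr_mean, "/")
}
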