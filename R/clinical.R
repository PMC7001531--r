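#' Screening criteria for rehabilitation cohort inclusion
#'
#' Bundles the inclusion/exclusion rules applied before recovery
#' stratification: age window, admission Functional Independence Measure
#' (FIM) window (both inclusive), a strict minimum length of stay, and the
#' names of binary exclusion flags (a record is dropped when any flag is 1).
#'
#' @param age_range inclusive age window in years, default `c(50, 85)`.
#' @param admission_fim_range inclusive admission total-FIM window,
#'   default `c(36, 71)`.
#' @param min_length_of_stay strict lower bound on length of stay in days;
#'   records are kept only when `length_of_stay > min_length_of_stay`.
#' @param exclusion_flags character vector of column names holding 0/1
#'   exclusion indicators (e.g. tube feeding, active cancer).
#' @return A list of class `"screening_criteria"`.
#' @export
screening_criteria <- function(age_range = c(50, 85),
                               admission_fim_range = c(36, 71),
                               min_length_of_stay = 6,
                               exclusion_flags = character()) {
  .assert(length(age_range) == 2L && age_range[1] <= age_range[2],
          "age_range must be an increasing pair")
  .assert(length(admission_fim_range) == 2L &&
            admission_fim_range[1] <= admission_fim_range[2],
          "admission_fim_range must be an increasing pair")
  structure(list(age_range = as.numeric(age_range),
                 admission_fim_range = as.numeric(admission_fim_range),
                 min_length_of_stay = as.numeric(min_length_of_stay),
                 exclusion_flags = as.character(exclusion_flags)),
            class = "screening_criteria")
}

#' Screen a clinical table against inclusion/exclusion criteria
#'
#' Keeps exactly the records with age inside the inclusive age window,
#' admission FIM inside the inclusive FIM window, length of stay strictly
#' greater than the minimum, and no exclusion flag set. Input row order is
#' preserved, so screening is idempotent.
#'
#' @param records data frame with one row per patient; must contain
#'   `age`, `admission_fim` and `length_of_stay` columns, plus any columns
#'   named in `criteria$exclusion_flags`.
#' @param criteria a [screening_criteria()] object.
#' @return The subset of `records` passing all criteria, original order.
#' @export
screen_cohort <- function(records, criteria = screening_criteria()) {
  .assert(is.data.frame(records), "records must be a data frame")
  required <- c("age", "admission_fim", "length_of_stay",
                criteria$exclusion_flags)
  for (f in required) {
    if (!f %in% names(records))
      stop("records are missing required field '", f, "'", call. = FALSE)
    if (anyNA(records[[f]]))
      stop("required field '", f, "' has missing values (records ",
           paste(which(is.na(records[[f]])), collapse = ", "), ")",
           call. = FALSE)
  }
  keep <- records$age >= criteria$age_range[1] &
    records$age <= criteria$age_range[2] &
    records$admission_fim >= criteria$admission_fim_range[1] &
    records$admission_fim <= criteria$admission_fim_range[2] &
    records$length_of_stay > criteria$min_length_of_stay
  for (f in criteria$exclusion_flags) keep <- keep & records[[f]] == 0
  records[keep, , drop = FALSE]
}

#' Montebello Rehabilitation Factor Score (MRFS)
#'
#' Relative functional gain: the achieved FIM gain divided by the patient's
#' potential for improvement,
#' `(discharge_fim - admission_fim) / (max_fim - admission_fim)`.
#' Always at most 1; negative when the patient deteriorates.
#'
#' @param admission_fim,discharge_fim total FIM scores (18--126). Vectors
#'   are recycled to a common length.
#' @param max_fim maximum attainable total FIM, 126 for the standard
#'   18-item scale; overridable for other scales.
#' @return Numeric vector of MRFS values.
#' @export
compute_mrfs <- function(admission_fim, discharge_fim, max_fim = 126) {
  .assert(all(admission_fim >= 18 & admission_fim <= max_fim),
          "admission_fim outside the 18..", max_fim, " scale")
  .assert(all(discharge_fim >= 18 & discharge_fim <= max_fim),
          "discharge_fim outside the 18..", max_fim, " scale")
  if (any(admission_fim == max_fim))
    stop("admission_fim equals max_fim (", max_fim,
         "): MRFS denominator is zero", call. = FALSE)
  (discharge_fim - admission_fim) / (max_fim - admission_fim)
}

#' MRFS efficiency (per-day relative gain)
#'
#' @param mrfs MRFS values from [compute_mrfs()].
#' @param length_of_stay rehabilitation stay in days, strictly positive.
#' @return `mrfs / length_of_stay`.
#' @export
compute_mrfs_efficiency <- function(mrfs, length_of_stay) {
  if (any(length_of_stay <= 0))
    stop("length_of_stay must be strictly positive", call. = FALSE)
  mrfs / length_of_stay
}

#' Attach MRFS and MRFS efficiency to a clinical table
#'
#' @param records data frame with `admission_fim`, `discharge_fim`,
#'   `length_of_stay`.
#' @param max_fim maximum total FIM (see [compute_mrfs()]).
#' @return `records` with `mrfs` and `mrfs_efficiency` columns appended.
#' @export
score_recovery <- function(records, max_fim = 126) {
  records$mrfs <- compute_mrfs(records$admission_fim,
                               records$discharge_fim, max_fim)
  records$mrfs_efficiency <- compute_mrfs_efficiency(records$mrfs,
                                                     records$length_of_stay)
  records
}

#' Stratify extreme recovery groups by MRFS efficiency
#'
#' Selects the `n_per_group` eligible patients with the highest MRFS
#' efficiency (good recovery, GR) and the `n_per_group` with the lowest
#' (poor recovery, PR). Selection equals the head and tail of a full stable
#' sort by (efficiency, patient_id), so ties are broken deterministically
#' by ascending patient id.
#'
#' @param records data frame with `patient_id` and `mrfs_efficiency`
#'   columns (see [score_recovery()]).
#' @param n_per_group patients per extreme group (20 in the motivating
#'   design, the top/bottom 19% of 106 eligible).
#' @return An object of class `"stratified_cohort"`: list with
#'   `good_ids` (descending efficiency), `poor_ids` (ascending efficiency)
#'   and `n_per_group`.
#' @export
stratify_extremes <- function(records, n_per_group = 20) {
  .assert(is.data.frame(records) && all(c("patient_id", "mrfs_efficiency")
                                        %in% names(records)),
          "records must carry patient_id and mrfs_efficiency")
  .assert(!anyNA(records$mrfs_efficiency),
          "mrfs_efficiency has missing values")
  n <- nrow(records)
  if (n < 2L * n_per_group)
    stop("stratification needs at least ", 2L * n_per_group,
         " eligible records but only ", n, " are available", call. = FALSE)
  ord <- order(records$mrfs_efficiency, records$patient_id)
  ids <- records$patient_id[ord]
  structure(list(good_ids = rev(utils::tail(ids, n_per_group)),
                 poor_ids = utils::head(ids, n_per_group),
                 n_per_group = as.integer(n_per_group),
                 n_eligible = n),
            class = "stratified_cohort")
}

#' @export
print.stratified_cohort <- function(x, ...) {
  cat("Stratified recovery cohort\n")
  cat("  eligible:", x$n_eligible, " per extreme group:", x$n_per_group,
      sprintf("(%.0f%% each)", 100 * x$n_per_group / x$n_eligible), "\n")
  cat("  good recovery:", paste(utils::head(x$good_ids, 5), collapse = ", "),
      if (x$n_per_group > 5) "..." else "", "\n")
  cat("  poor recovery:", paste(utils::head(x$poor_ids, 5), collapse = ", "),
      if (x$n_per_group > 5) "..." else "", "\n")
  invisible(x)
}

#' Two-sample comparison of a continuous clinical variable
#'
#' Pooled-variance two-sided t-test (primary) with Welch statistics
#' reported alongside, plus group descriptives. When both groups are
#' constant and equal the statistic is 0 with p = 1.
#'
#' @param values_a,values_b numeric vectors, each of length >= 2.
#' @return A one-row data frame: `mean_a`, `sd_a`, `mean_b`, `sd_b`,
#'   `statistic`, `df`, `p_value` (pooled) and `welch_statistic`,
#'   `welch_df`, `welch_p_value`.
#' @export
compare_groups_continuous <- function(values_a, values_b) {
  .assert(length(values_a) >= 2L && length(values_b) >= 2L,
          "each group needs at least 2 values")
  desc <- data.frame(mean_a = mean(values_a), sd_a = stats::sd(values_a),
                     mean_b = mean(values_b), sd_b = stats::sd(values_b))
  if (desc$sd_a == 0 && desc$sd_b == 0) {
    if (desc$mean_a == desc$mean_b) {
      df <- length(values_a) + length(values_b) - 2L
      return(cbind(desc, data.frame(statistic = 0, df = df, p_value = 1,
                                    welch_statistic = 0, welch_df = df,
                                    welch_p_value = 1)))
    }
    stop("both groups have zero variance with different means: ",
         "t-statistic is undefined", call. = FALSE)
  }
  pooled <- stats::t.test(values_a, values_b, var.equal = TRUE)
  welch <- stats::t.test(values_a, values_b, var.equal = FALSE)
  cbind(desc, data.frame(statistic = unname(pooled$statistic),
                         df = unname(pooled$parameter),
                         p_value = pooled$p.value,
                         welch_statistic = unname(welch$statistic),
                         welch_df = unname(welch$parameter),
                         welch_p_value = welch$p.value))
}

#' Chi-square comparison of a categorical clinical variable
#'
#' Pearson chi-square without continuity correction on a 2 x k
#' contingency table. A warning is emitted when any expected count is
#' below 5 (the usual small-cell caveat).
#'
#' @param counts 2 x k matrix of nonnegative integer counts with positive
#'   row and column margins.
#' @return A one-row data frame: `statistic`, `df`, `p_value`.
#' @export
compare_groups_categorical <- function(counts) {
  counts <- as.matrix(counts)
  .assert(nrow(counts) == 2L && ncol(counts) >= 2L,
          "counts must be a 2 x k table with k >= 2")
  .assert(all(counts >= 0) && all(counts == round(counts)),
          "counts must be nonnegative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("contingency table has a zero row or column margin", call. = FALSE)
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected < 5))
    warning("expected count below 5 in ", sum(expected < 5),
            " cell(s); chi-square approximation may be poor", call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  data.frame(statistic = unname(ht$statistic),
             df = unname(ht$parameter),
             p_value = ht$p.value)
}

#' Pearson correlation between two clinical/metabolic variables
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return The product-moment correlation coefficient in `[-1, 1]`.
#' @export
correlate <- function(x, y) {
  .assert(length(x) == length(y), "x and y must have equal length")
  .assert(length(x) >= 3L, "need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance input", call. = FALSE)
  stats::cor(x, y)
}

#' Group-comparison table for a stratified cohort
#'
#' Builds a characteristics table in the usual Table-1 layout: one row per
#' variable with good-recovery summary, poor-recovery summary, and the
#' p-value from the pooled t-test (numeric variables) or Pearson
#' chi-square (categorical variables).
#'
#' @param records scored clinical data frame containing `patient_id`.
#' @param cohort a [stratify_extremes()] result.
#' @param continuous,categorical character vectors naming the columns to
#'   summarize with each test.
#' @return Data frame with columns `characteristic`, `good_recovery`,
#'   `poor_recovery`, `p_value`.
#' @export
group_comparison_table <- function(records, cohort,
                                   continuous, categorical = character()) {
  gr <- records[match(cohort$good_ids, records$patient_id), , drop = FALSE]
  pr <- records[match(cohort$poor_ids, records$patient_id), , drop = FALSE]
  rows <- lapply(continuous, function(v) {
    ct <- compare_groups_continuous(gr[[v]], pr[[v]])
    data.frame(characteristic = v,
               good_recovery = sprintf("%.2f ± %.2f", ct$mean_a, ct$sd_a),
               poor_recovery = sprintf("%.2f ± %.2f", ct$mean_b, ct$sd_b),
               p_value = ct$p_value)
  })
  rows_cat <- lapply(categorical, function(v) {
    lev <- sort(unique(records[[v]]))
    tab <- rbind(table(factor(gr[[v]], levels = lev)),
                 table(factor(pr[[v]], levels = lev)))
    ct <- tryCatch(suppressWarnings(compare_groups_categorical(tab)),
                   error = function(e) data.frame(statistic = NA_real_,
                                                  df = NA_real_,
                                                  p_value = NA_real_))
    n1 <- length(cohort$good_ids); n2 <- length(cohort$poor_ids)
    pos <- if (length(lev) == 2L) 2L else which.max(colSums(tab))
    data.frame(characteristic = v,
               good_recovery = sprintf("%d (%.0f%%)", tab[1, pos],
                                       100 * tab[1, pos] / n1),
               poor_recovery = sprintf("%d (%.0f%%)", tab[2, pos],
                                       100 * tab[2, pos] / n2),
               p_value = ct$p_value)
  })
  do.call(rbind, c(rows, rows_cat))
}
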