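# End-to-end driver: screen -> score -> stratify -> normalize ->
# PLS-DA/VIP -> exhaustive panel search -> report files.

#' Configuration for a full pipeline run
#'
#' @param clinical_path,peaks_path input files (see [read_clinical()],
#'   [read_peak_table()]); alternatively supply `cohort`.
#' @param cohort optional in-memory [generate_cohort()] object used instead
#'   of file inputs.
#' @param out_dir directory for all result files (created if absent).
#' @param column_map optional clinical column renaming (see
#'   [read_clinical()]).
#' @param criteria screening rules, a [screening_criteria()] object.
#' @param n_per_group extreme-group size for stratification, default 20.
#' @param max_fim maximum total FIM, default 126.
#' @param sparse_threshold missingness fraction above which a metabolite is
#'   dropped, default 0.5.
#' @param ncomp PLS-DA components, default 2.
#' @param n_permutations label permutations for model validation,
#'   default 200.
#' @param vip_threshold biomarker selection cutoff, default 1.
#' @param n_replicates,n_folds repeated-CV scheme for the panel search,
#'   defaults 10 and 10.
#' @param q2_folds stratified folds for Q2Y, default 7.
#' @param classifier panel classifier, `"logistic"` or `"plsda"`.
#' @param include_age also evaluate the best metabolite panel augmented
#'   with age, default `TRUE`.
#' @param seed master seed; per-stage seeds are derived from it
#'   deterministically, so a rerun with the same config is byte-identical.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(clinical_path = NULL, peaks_path = NULL,
                       cohort = NULL, out_dir = tempfile("strokemet_run_"),
                       column_map = NULL,
                       criteria = screening_criteria(),
                       n_per_group = 20, max_fim = 126,
                       sparse_threshold = 0.5, ncomp = 2,
                       n_permutations = 200, vip_threshold = 1,
                       n_replicates = 10, n_folds = 10, q2_folds = 7,
                       classifier = c("logistic", "plsda"),
                       include_age = TRUE, seed = 20200124) {
  classifier <- match.arg(classifier)
  if (is.null(cohort) && (is.null(clinical_path) || is.null(peaks_path)))
    stop("supply either a cohort object or both clinical_path and ",
         "peaks_path", call. = FALSE)
  structure(list(clinical_path = clinical_path, peaks_path = peaks_path,
                 cohort = cohort, out_dir = out_dir,
                 column_map = column_map, criteria = criteria,
                 n_per_group = n_per_group, max_fim = max_fim,
                 sparse_threshold = sparse_threshold, ncomp = ncomp,
                 n_permutations = n_permutations,
                 vip_threshold = vip_threshold,
                 n_replicates = n_replicates, n_folds = n_folds,
                 q2_folds = q2_folds, classifier = classifier,
                 include_age = include_age, seed = seed),
            class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE))
}

#' Run the full recovery-metabolomics workflow
#'
#' Executes screen, recovery scoring, extreme-group stratification, median
#' normalization (after sparse-metabolite removal), half-minimum
#' imputation, UV scaling, PLS-DA with R2Y/Q2Y and permutation validation,
#' VIP biomarker selection, exhaustive panel search by repeated
#' cross-validated AUC, and (optionally) the age-augmented best panel.
#' Every intermediate is persisted as TSV in `config$out_dir` along with a
#' JSON manifest sufficient to reproduce the run; identical config + seed
#' gives byte-identical outputs.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list of class `"recovery_run"` with all in-memory
#'   results (`eligible`, `cohort_groups`, `normalized`, `fit`, `q2y`,
#'   `permutation`, `vip`, `selected`, `fold_changes`, `ranking`,
#'   `age_panel`, `manifest`, `files`).
#' @export
run_pipeline <- function(config) {
  .assert(inherits(config, "run_config"), "config must come from run_config()")
  seeds <- .stage_seeds(config$seed, c("q2", "permutation", "panels", "age"))
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  warnings_log <- character()
  note <- function(...) warnings_log <<- c(warnings_log, paste0(...))

  # --- input ---------------------------------------------------------
  inputs <- .stage("input", {
    if (!is.null(config$cohort)) {
      .assert(inherits(config$cohort, "synthetic_cohort"),
              "cohort must come from generate_cohort()")
      list(clinical = config$cohort$records, peaks = config$cohort$peaks)
    } else {
      list(clinical = read_clinical(config$clinical_path, config$column_map),
           peaks = read_peak_table(config$peaks_path))
    }
  })

  # --- screen / score / stratify ------------------------------------
  eligible <- .stage("screen", screen_cohort(inputs$clinical,
                                             config$criteria))
  eligible <- .stage("score", score_recovery(eligible, config$max_fim))
  groups <- .stage("stratify", stratify_extremes(eligible,
                                                 config$n_per_group))
  sel_ids <- c(groups$good_ids, groups$poor_ids)
  labels <- factor(rep(c("GR", "PR"), each = config$n_per_group),
                   levels = c("GR", "PR"))
  names(labels) <- sel_ids

  # --- preprocessing -------------------------------------------------
  norm <- .stage("normalize", {
    .assert(all(sel_ids %in% rownames(inputs$peaks)),
            "peak table is missing stratified sample(s): ",
            paste(setdiff(sel_ids, rownames(inputs$peaks)), collapse = ", "))
    peaks <- inputs$peaks[sel_ids, , drop = FALSE]
    dropped <- drop_sparse_metabolites(peaks, config$sparse_threshold)
    if (length(dropped$dropped))
      note("dropped sparse metabolite(s): ",
           paste(dropped$dropped, collapse = ", "))
    normalized <- impute_half_min(median_normalize(dropped$table))
    list(normalized = normalized, dropped = dropped$dropped)
  })
  fold_changes <- .stage("fold_changes",
                         compute_fold_changes(norm$normalized, groups))

  # --- PLS-DA / validation / VIP ------------------------------------
  fit <- .stage("plsda", plsda(norm$normalized, labels,
                               ncomp = config$ncomp))
  q2 <- .stage("q2y", q2y(norm$normalized, labels, ncomp = config$ncomp,
                          folds = config$q2_folds, seed = seeds[["q2"]]))
  perm <- .stage("permutation",
                 permutation_validate(norm$normalized, labels,
                                      n_permutations = config$n_permutations,
                                      ncomp = config$ncomp,
                                      folds = config$q2_folds,
                                      seed = seeds[["permutation"]]))
  vip_scores <- .stage("vip", vip(fit))
  selected <- .stage("vip", select_biomarkers(vip_scores,
                                              config$vip_threshold))
  if (length(selected) == 0L)
    stop("[stage vip] no metabolite exceeds the VIP threshold ",
         config$vip_threshold, call. = FALSE)
  heat <- .stage("heatmap", heatmap_matrix(norm$normalized, groups,
                                           selected))

  # --- panel search --------------------------------------------------
  ranking <- .stage("panels",
                    panel_search(norm$normalized, labels,
                                 candidates = selected,
                                 n_replicates = config$n_replicates,
                                 n_folds = config$n_folds,
                                 seed = seeds[["panels"]],
                                 classifier = config$classifier))
  best_panel <- strsplit(ranking$panel[1], "+", fixed = TRUE)[[1]]

  age_panel <- NULL
  if (config$include_age) {
    age_panel <- .stage("age_panel", {
      age <- eligible$age[match(sel_ids, eligible$patient_id)]
      feats <- augment_with_covariate(
        norm$normalized[, best_panel, drop = FALSE], age, "age")
      cv_auc_panel(feats, labels, n_replicates = config$n_replicates,
                   n_folds = config$n_folds, seed = seeds[["age"]],
                   classifier = config$classifier)
    })
  }

  # --- report --------------------------------------------------------
  files <- .stage("report", {
    f <- list()
    table1 <- group_comparison_table(
      eligible, groups,
      continuous = intersect(c("age", "admission_fim", "discharge_fim",
                               "length_of_stay", "mrfs", "mrfs_efficiency"),
                             names(eligible)),
      categorical = intersect(c("sex", "smoking", "hypertension",
                                "diabetes"), names(eligible)))
    f$group_comparison <- write_tsv(table1,
                                    file.path(config$out_dir,
                                              "group_comparison.tsv"))
    f$normalized <- write_tsv(norm$normalized,
                              file.path(config$out_dir, "normalized.tsv"))
    f$fold_changes <- write_tsv(
      data.frame(metabolite = names(fold_changes),
                 fold_change = unname(fold_changes)),
      file.path(config$out_dir, "fold_changes.tsv"))
    f$vip <- write_tsv(
      data.frame(metabolite = names(sort(-vip_scores)),
                 vip = unname(sort(vip_scores, decreasing = TRUE)),
                 fold_change = unname(
                   fold_changes[names(sort(-vip_scores))]),
                 selected = as.integer(names(sort(-vip_scores))
                                       %in% selected)),
      file.path(config$out_dir, "vip_table.tsv"))
    f$scores <- write_tsv(fit$scores,
                          file.path(config$out_dir, "plsda_scores.tsv"))
    model_tab <- data.frame(metabolite = rownames(fit$weights),
                            fit$weights, fit$loadings,
                            vip = unname(vip_scores[rownames(fit$weights)]),
                            check.names = FALSE)
    names(model_tab) <- c("metabolite",
                          paste0("weight_", colnames(fit$weights)),
                          paste0("loading_", colnames(fit$loadings)), "vip")
    f$model <- write_tsv(model_tab,
                         file.path(config$out_dir, "plsda_model.tsv"))
    f$permutation <- write_tsv(perm$summary,
                               file.path(config$out_dir, "permutation.tsv"))
    f$heatmap <- write_tsv(heat, file.path(config$out_dir, "heatmap.tsv"))
    f$panels <- write_tsv(as.data.frame(ranking),
                          file.path(config$out_dir, "panel_ranking.tsv"))
    roc_best <- roc_points(
      .score_logistic(norm$normalized[, best_panel, drop = FALSE],
                      as.integer(labels) - 1L,
                      norm$normalized[, best_panel, drop = FALSE])$test,
      labels)
    f$roc <- write_tsv(roc_best,
                       file.path(config$out_dir, "roc_best_panel.tsv"))
    f
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("strokemet")),
    seed = config$seed, stage_seeds = as.list(seeds),
    parameters = config[c("n_per_group", "max_fim", "sparse_threshold",
                          "ncomp", "n_permutations", "vip_threshold",
                          "n_replicates", "n_folds", "q2_folds",
                          "classifier", "include_age")],
    counts = list(records_in = nrow(inputs$clinical),
                  eligible = nrow(eligible),
                  stratified = length(sel_ids),
                  metabolites_in = ncol(inputs$peaks),
                  metabolites_retained = ncol(norm$normalized),
                  panels = nrow(ranking)),
    dropped_metabolites = norm$dropped,
    selected_biomarkers = selected,
    best_panel = best_panel,
    model = list(r2y = fit$r2y, q2y = q2,
                 r2_intercept = perm$r2_intercept,
                 q2_intercept = perm$q2_intercept,
                 permutation_valid = perm$valid),
    warnings = warnings_log)
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files$manifest <- manifest_path

  invisible(structure(list(eligible = eligible, cohort_groups = groups,
                           normalized = norm$normalized,
                           fold_changes = fold_changes, fit = fit,
                           q2y = q2, permutation = perm, vip = vip_scores,
                           selected = selected, ranking = ranking,
                           age_panel = age_panel, manifest = manifest,
                           files = files),
                      class = "recovery_run"))
}

#' @export
print.recovery_run <- function(x, ...) {
  cat("Recovery-metabolomics run\n")
  cat("  eligible:", nrow(x$eligible), "; stratified:",
      2 * x$cohort_groups$n_per_group, "\n")
  cat("  retained metabolites:", ncol(x$normalized), "\n")
  cat(sprintf("  PLS-DA: R2Y %.3f, Q2Y %.3f, permutation Q2 intercept %.3f\n",
              x$fit$r2y[x$fit$ncomp], x$q2y[length(x$q2y)],
              x$permutation$q2_intercept))
  cat("  VIP-selected:", paste(x$selected, collapse = ", "), "\n")
  cat("  best panel:", x$ranking$panel[1],
      sprintf("(test AUC %.3f)", x$ranking$mean_auc_test[1]), "\n")
  if (!is.null(x$age_panel))
    cat(sprintf("  with age: test AUC %.3f\n", x$age_panel$mean_auc_test))
  cat("  outputs:", dirname(x$files$manifest), "\n")
  invisible(x)
}
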