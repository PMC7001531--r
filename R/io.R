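# Delimited-text I/O. Delimiter (comma or tab) is auto-detected from the
# header line; empty cells and "NA" both mean missing; numbers are written
# with 17 significant digits so write -> read round-trips are exact.

.detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L)
    stop("file '", path, "' is empty", call. = FALSE)
  if (grepl("\t", header)) "\t" else ","
}

.read_delim <- function(path) {
  if (!file.exists(path))
    stop("input file not found: '", path, "'", call. = FALSE)
  sep <- .detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = c("", "NA"), check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", fill = FALSE)
  df
}

#' Read a targeted peak-area table
#'
#' Delimited text (comma or tab, auto-detected), header row required,
#' samples as rows with the sample id in the first column, metabolites as
#' the remaining columns. Empty cells and `NA` both parse as missing.
#'
#' @param path file path.
#' @return Numeric matrix, samples x metabolites, sample ids as row names.
#' @export
read_peak_table <- function(path) {
  df <- .read_delim(path)
  .assert(ncol(df) >= 2L, "peak table needs a sample-id column plus data")
  ids <- as.character(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppress <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(suppress))
      if (length(bad))
        stop("malformed value in '", path, "', column '",
             names(vals)[j], "', line ", bad[1] + 1L, ": '", v[bad[1]], "'",
             call. = FALSE)
      vals[[j]] <- suppress
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  .check_peak_matrix(m)
  m
}

#' Read a clinical table
#'
#' Delimited text with one row per patient. Column names can be remapped
#' through `column_map`, a named character vector whose names are the
#' canonical names the pipeline expects (`patient_id`, `age`,
#' `admission_fim`, ...) and whose values are the column names in the file.
#'
#' @param path file path.
#' @param column_map optional named character vector for renaming.
#' @return Data frame of clinical records.
#' @export
read_clinical <- function(path, column_map = NULL) {
  df <- .read_delim(path)
  if (!is.null(column_map)) {
    missing_cols <- setdiff(unname(column_map), names(df))
    if (length(missing_cols))
      stop("column_map refers to absent column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    idx <- match(unname(column_map), names(df))
    names(df)[idx] <- names(column_map)
  }
  df
}

#' Write a table as TSV with full numeric precision
#'
#' Numeric cells are serialized with 17 significant digits so that reading
#' the file back reproduces the doubles bit-for-bit; missing values are
#' written as `NA`. Matrices get their row names as a leading `sample_id`
#' column.
#'
#' @param x data frame or matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  if (is.matrix(x)) {
    df <- data.frame(sample_id = rownames(x), as.data.frame(x),
                     check.names = FALSE)
    x <- df
  }
  .assert(is.data.frame(x), "x must be a data frame or matrix")
  out <- x
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- NA_character_
      out[[j]] <- v
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write a synthetic cohort to disk
#'
#' Emits the clinical table (`clinical.csv`) and peak-area matrix
#' (`peaks.csv`) in exactly the formats [read_clinical()] and
#' [read_peak_table()] parse, plus a `ground_truth.json` sidecar with the
#' labels, the discriminative set, and the generating parameters.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if absent).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  .assert(inherits(cohort, "synthetic_cohort"),
          "cohort must come from generate_cohort()")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  clinical_path <- file.path(dir, "clinical.csv")
  peaks_path <- file.path(dir, "peaks.csv")
  truth_path <- file.path(dir, "ground_truth.json")
  utils::write.csv(cohort$records, clinical_path, row.names = FALSE,
                   quote = FALSE)
  pk <- data.frame(sample_id = rownames(cohort$peaks),
                   as.data.frame(cohort$peaks), check.names = FALSE)
  for (j in seq_along(pk)) {
    if (is.double(pk[[j]])) {
      v <- sprintf("%.17g", pk[[j]])
      v[is.na(pk[[j]])] <- NA_character_
      pk[[j]] <- v
    }
  }
  utils::write.table(pk, peaks_path, sep = ",", quote = FALSE,
                     row.names = FALSE, na = "")
  truth <- list(labels = as.list(stats::setNames(
    as.character(cohort$true_labels), names(cohort$true_labels))),
    discriminative_set = cohort$true_discriminative_set,
    config = cohort$config[c("n_good", "n_poor", "biological_cv",
                             "sample_scale_sd", "seed")],
    fold_changes = as.list(cohort$config$fold_changes))
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(clinical = clinical_path, peaks = peaks_path,
              ground_truth = truth_path))
}
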