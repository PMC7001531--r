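# Shared fixtures, all built in code.

# Default-condition synthetic cohort with a chosen seed.
make_cohort <- function(seed = 20200124, ...) {
  generate_cohort(simulation_config(seed = seed, ...))
}

make_null_cohort <- function(seed = 1) {
  generate_null_cohort(simulation_config(seed = seed))
}

# Sparse-drop + median-normalize + half-min impute, as the pipeline does.
preprocess_cohort <- function(cohort, threshold = 0.5) {
  kept <- drop_sparse_metabolites(cohort$peaks, threshold)$table
  impute_half_min(median_normalize(kept))
}

# Minimal well-formed clinical table for screening tests.
make_records <- function(n = 10,
                         age = rep(60, n),
                         admission_fim = rep(50, n),
                         discharge_fim = pmin(126, admission_fim + 30),
                         length_of_stay = rep(14, n)) {
  data.frame(patient_id = sprintf("P%03d", seq_len(n)), age = age,
             admission_fim = admission_fim, discharge_fim = discharge_fim,
             length_of_stay = length_of_stay, stringsAsFactors = FALSE)
}

# Small labelled feature matrix with a known group shift on some columns.
make_signal_matrix <- function(n_per_class = 15, p = 6, shift = 2,
                               shifted_cols = 1, seed = 42) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n_per_class * p), 2 * n_per_class, p,
              dimnames = list(sprintf("s%02d", seq_len(2 * n_per_class)),
                              paste0("m", seq_len(p))))
  y <- factor(rep(c("A", "B"), each = n_per_class))
  x[y == "B", shifted_cols] <- x[y == "B", shifted_cols] + shift
  list(x = x, y = y)
}
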