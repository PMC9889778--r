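# Shared fixture builders. Cohorts used by several test files are cached in
# this environment so each is generated once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A tiny cell_matrix with explicit counts for arithmetic oracles.
toy_cell_matrix <- function(counts, n_samples = 1) {
  n <- ncol(counts)
  meta <- data.frame(
    patient_id = rep(sprintf("P%d", seq_len(n_samples)), length.out = n),
    sample_id = rep(sprintf("P%d", seq_len(n_samples)), length.out = n))
  cell_matrix(counts, meta)
}

# Three planted subpopulations at a given effect size, 12 samples.
three_pop_cohort <- function(lfc = 1.5, n_patients = 12, cells = 150,
                             n_genes = 800, batch_sd = 0, seed = 21) {
  generate_cohort(cohort_config(
    n_patients = n_patients, cells_per_patient = cells, n_genes = n_genes,
    batch_sd = batch_sd,
    cell_type_spec = list(
      list(type_name = "adventitial", proportion = 1 / 3,
           signature_genes = 30, signature_log2fc = lfc),
      list(type_name = "alveolar", proportion = 1 / 3,
           signature_genes = 30, signature_log2fc = lfc),
      list(type_name = "myofibroblast", proportion = 1 / 3,
           signature_genes = 30, signature_log2fc = lfc)),
    seed = seed))
}

# Six-type reference emulating a lung dissociation (fibroblast subpopulations
# as minority populations), for deconvolution tests.
lung_reference_spec <- function(lfc = 1.5) {
  list(
    list(type_name = "epithelial", proportion = 0.30,
         signature_genes = 40, signature_log2fc = lfc),
    list(type_name = "immune", proportion = 0.30,
         signature_genes = 40, signature_log2fc = lfc),
    list(type_name = "endothelial", proportion = 0.20,
         signature_genes = 40, signature_log2fc = lfc),
    list(type_name = "adventitial", proportion = 0.07,
         signature_genes = 30, signature_log2fc = lfc),
    list(type_name = "alveolar", proportion = 0.07,
         signature_genes = 30, signature_log2fc = lfc),
    list(type_name = "myofibroblast", proportion = 0.06,
         signature_genes = 30, signature_log2fc = lfc))
}

fib_types <- c("adventitial", "alveolar", "myofibroblast")

# Cached cohorts reused across test files.
three_pop_lfc2 <- function() {
  cached("cohort_3pop_lfc2", function() {
    three_pop_cohort(lfc = 2, cells = 120, n_genes = 800, seed = 37)
  })
}

fibmur_cohort <- function() {
  cached("cohort_fibmur", function() {
    generate_cohort(cohort_config(
      n_patients = 6, cells_per_patient = 200, n_genes = 800, batch_sd = 0,
      cell_type_spec = list(
        list(type_name = "fibroblast", proportion = 0.5,
             signature_genes = 30, signature_log2fc = 2),
        list(type_name = "mural", proportion = 0.5,
             signature_genes = 30, signature_log2fc = 2)),
      seed = 23))
  })
}

deconv_ref <- function() {
  cached("deconv_ref", function() {
    generate_cohort(cohort_config(
      n_patients = 6, cells_per_patient = 400, n_genes = 1000, batch_sd = 0,
      cell_type_spec = lung_reference_spec(1.5), seed = 31))
  })
}

demarcation_cohort <- function() {
  cached("cohort_demarc", function() {
    generate_cohort(cohort_config(seed = 42))  # defaults: 12 x 500, lfc 1.5
  })
}

# Majority-mapped accuracy between predicted and true partitions.
mapped_accuracy <- function(pred, truth) {
  tab <- table(pred, truth)
  sum(apply(tab, 1, max)) / length(truth)
}
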