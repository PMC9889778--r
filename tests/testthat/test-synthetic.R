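# Synthetic-data generators: determinism, planted structure, and the
# statistical invariants downstream stages rely on.

test_that("cohort generation is deterministic and validates its config", {
  cfg <- cohort_config(n_patients = 2, cells_per_patient = 50, n_genes = 200,
                       seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$cell_meta, b$cell_meta)

  expect_error(cohort_config(cell_type_spec = list(
    list(type_name = "a", proportion = 0.6, signature_genes = 5,
         signature_log2fc = 1),
    list(type_name = "b", proportion = 0.6, signature_genes = 5,
         signature_log2fc = 1))), "sum to 1")
  expect_error(cohort_config(dispersion = -1), "dispersion")
})

test_that("realized cell-type counts follow the configured proportions", {
  cfg <- cohort_config(n_patients = 12, cells_per_patient = 500,
                       n_genes = 100,
                       cell_type_spec = list(
                         list(type_name = "a", proportion = 0.5,
                              signature_genes = 0, signature_log2fc = 0),
                         list(type_name = "b", proportion = 0.3,
                              signature_genes = 0, signature_log2fc = 0),
                         list(type_name = "c", proportion = 0.2,
                              signature_genes = 0, signature_log2fc = 0)),
                       seed = 3)
  cm <- generate_cohort(cfg)
  counts <- table(cm$cell_meta$true_type)
  n <- 6000
  for (i in seq_along(c(a = 0.5, b = 0.3, c = 0.2))) {
    p <- c(0.5, 0.3, 0.2)[i]
    ci <- qbinom(c(0.005, 0.995), n, p)  # binomial 99% CI
    expect_gte(counts[i], ci[1])
    expect_lte(counts[i], ci[2])
  }
})

test_that("zero signature effect leaves 'signature' genes unplanted", {
  cfg <- cohort_config(n_patients = 4, cells_per_patient = 250, n_genes = 300,
                       batch_sd = 0,
                       cell_type_spec = list(
                         list(type_name = "a", proportion = 0.5,
                              signature_genes = 20, signature_log2fc = 0),
                         list(type_name = "b", proportion = 0.5,
                              signature_genes = 20, signature_log2fc = 0)),
                       seed = 11)
  cm <- generate_cohort(cfg)
  sig <- attr(cm, "signature_genes")
  a_cells <- cm$cell_meta$true_type == "a"
  mean_a <- colMeans(t(cm$lognorm[sig$a, a_cells]))
  # per-gene means of a's "signature" in a-cells vs b-cells: no difference
  ma <- rowMeans(cm$lognorm[sig$a, a_cells])
  mb <- rowMeans(cm$lognorm[sig$a, !a_cells])
  expect_gt(t.test(ma, mb, paired = TRUE)$p.value, 0.01)
})

test_that("generated marginal means match configured NB means", {
  cfg <- cohort_config(n_patients = 10, cells_per_patient = 500,
                       n_genes = 150, batch_sd = 0,
                       cell_type_spec = list(
                         list(type_name = "a", proportion = 1,
                              signature_genes = 0, signature_log2fc = 0)),
                       seed = 13)
  cm <- generate_cohort(cfg)
  # marginal mean over >= 5000 cells: counts mean ~ base_mean * E[sf];
  # compare the realized library-size-adjusted totals at 2% tolerance
  realized <- mean(colSums(cm$counts))
  expected <- cfg$lib_size_mean * exp(0.3^2 / 2)  # lognormal(0, 0.3) mean
  expect_lt(abs(realized / expected - 1), 0.02)
})

test_that("trajectory datasets carry planted modules, branches and windows", {
  cfg <- trajectory_config(n_cells = 300, n_genes = 600, n_datasets = 2,
                           seed = 5)
  ds <- generate_trajectory_dataset(cfg)
  expect_length(ds, 2)
  mg <- attr(ds, "module_genes")
  expect_length(unique(unlist(mg)), length(unlist(mg)))  # disjoint
  cm <- ds[[1]]
  tt <- cm$cell_meta$true_pseudotime
  # early-activation genes: mean at t in [0.2, 0.3] exceeds t in [0.8, 1]
  early <- mg[["early-activation"]]
  m_in <- mean(cm$lognorm[early, tt >= 0.2 & tt <= 0.3])
  m_out <- mean(cm$lognorm[early, tt >= 0.8])
  expect_gt(m_in, m_out)
  # identical seeds reproduce
  ds2 <- generate_trajectory_dataset(cfg)
  expect_identical(ds[[2]]$counts, ds2[[2]]$counts)
  # invalid window rejected
  expect_error(trajectory_config(module_spec = list(
    list(module_name = "bad", genes = 5, activation_window = c(0.5, 0.4),
         amplitude_log2fc = 1))), "activation_window")
})

test_that("zero-amplitude modules produce no pseudotime signal", {
  cfg <- trajectory_config(
    n_cells = 200, n_genes = 300, n_datasets = 1,
    module_spec = list(list(module_name = "flat", genes = 30,
                            activation_window = c(0.2, 0.8),
                            amplitude_log2fc = 0)),
    branch_spec = list(branchA = list(genes = 10, log2fc = 0)),
    batch_sd = 0, seed = 8)
  cm <- generate_trajectory_dataset(cfg)[[1]]
  fit <- pseudotime_de(cm, cm$cell_meta$true_pseudotime,
                       genes = attr(generate_trajectory_dataset(cfg),
                                    "module_genes")$flat)
  expect_true(all(p.adjust(fit$table$p, "BH") > 0.05))
})

test_that("survival cohorts respect censoring and planted hazards", {
  # censor_time -> 0: everyone censored
  rec0 <- generate_survival_cohort(survival_config(n_subjects = 50,
                                                   censor_time = 1e-9,
                                                   seed = 2))
  expect_true(all(rec0$event == 0))
  # deterministic given seed
  r1 <- generate_survival_cohort(survival_config(n_subjects = 100, seed = 9))
  r2 <- generate_survival_cohort(survival_config(n_subjects = 100, seed = 9))
  expect_identical(r1, r2)
  expect_true(all(r1$time_months > 0))
  expect_true(all(r1$score >= 0 & r1$score <= 100))
})

test_that("cell_matrix IO round-trips through MTX and CSV", {
  cfg <- cohort_config(n_patients = 2, cells_per_patient = 20, n_genes = 50,
                       cell_type_spec = list(
                         list(type_name = "a", proportion = 1,
                              signature_genes = 5, signature_log2fc = 1)),
                       seed = 1)
  cm <- generate_cohort(cfg)
  for (fmt in c("mtx", "csv")) {
    dir <- withr::local_tempdir()
    write_cell_matrix(cm, dir, format = fmt)
    back <- read_cell_matrix(dir)
    expect_equal(back$counts, cm$counts)
    expect_equal(back$cell_meta$patient_id, cm$cell_meta$patient_id)
  }
})
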