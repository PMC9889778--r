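# Synthetic-data generators. These define the study conditions the rest of
# the package is validated under: negative-binomial counts with gene-level
# dispersion, multiplicative per-patient batch effects on a subset of genes,
# planted cell-type signatures, a bifurcating differentiation trajectory with
# temporally ordered gene modules, and survival cohorts with a planted
# hazard on a continuous score.

#' Configuration for a synthetic single-cell cohort
#'
#' Counts are negative binomial with variance mu + mu^2/theta. Per-cell
#' expected totals are set by \code{lib_size_mean} with lognormal(0, 0.3)
#' library-size factors. Each patient receives a multiplicative batch effect
#' (normal on the log2 scale, sd \code{batch_sd}) on a random
#' \code{batch_gene_frac} share of genes. Cell types are planted by
#' multiplying the means of disjoint signature-gene blocks by
#' \code{2^signature_log2fc}.
#'
#' @param n_patients number of patients (one sample per patient).
#' @param cells_per_patient cells per patient.
#' @param n_genes number of genes.
#' @param cell_type_spec list of specs; each a list with \code{type_name},
#'   \code{proportion}, \code{signature_genes} (count) and
#'   \code{signature_log2fc}. Proportions must sum to 1.
#' @param batch_sd sd (log2 scale) of per-patient multiplicative effects.
#' @param batch_gene_frac fraction of genes affected per patient.
#' @param dispersion NB inverse-dispersion theta (> 0).
#' @param lib_size_mean expected counts per cell.
#' @param tissue_assignment character vector (length \code{n_patients}) of
#'   values in control/LUAD/LUSC; defaults to alternating control/LUAD.
#' @param seed integer seed; the whole cohort is deterministic given it.
#' @return A \code{cohort_config} list.
#' @export
cohort_config <- function(n_patients = 12, cells_per_patient = 500,
                          n_genes = 2000,
                          cell_type_spec = list(
                            list(type_name = "fibroblast", proportion = 0.5,
                                 signature_genes = 30, signature_log2fc = 1.5),
                            list(type_name = "mural", proportion = 0.3,
                                 signature_genes = 30, signature_log2fc = 1.5),
                            list(type_name = "other", proportion = 0.2,
                                 signature_genes = 30, signature_log2fc = 1.5)),
                          batch_sd = 0.5, batch_gene_frac = 0.3,
                          dispersion = 10, lib_size_mean = 10000,
                          tissue_assignment = NULL, seed = 1) {
  stopifnot(is_count(n_patients), is_count(cells_per_patient), is_count(n_genes))
  if (!is.numeric(dispersion) || dispersion <= 0) stopf("dispersion must be > 0")
  if (batch_sd < 0) stopf("batch_sd must be >= 0")
  props <- vapply(cell_type_spec, function(s) s$proportion, numeric(1))
  if (abs(sum(props) - 1) > 1e-9) {
    stopf("cell type proportions must sum to 1 (got %.6f)", sum(props))
  }
  if (any(props < 0)) stopf("cell type proportions must be non-negative")
  total_sig <- sum(vapply(cell_type_spec, function(s) s$signature_genes, numeric(1)))
  if (total_sig > n_genes) stopf("signature genes exceed n_genes")
  if (is.null(tissue_assignment)) {
    tissue_assignment <- rep(c("control", "LUAD"), length.out = n_patients)
  }
  if (length(tissue_assignment) != n_patients) {
    stopf("tissue_assignment must have length n_patients")
  }
  structure(list(n_patients = n_patients, cells_per_patient = cells_per_patient,
                 n_genes = n_genes, cell_type_spec = cell_type_spec,
                 batch_sd = batch_sd, batch_gene_frac = batch_gene_frac,
                 dispersion = dispersion, lib_size_mean = lib_size_mean,
                 tissue_assignment = tissue_assignment, seed = seed),
            class = "cohort_config")
}

# Gene base means: lognormal, rescaled so a cell's expected total equals
# lib_size_mean. Mirrors the skewed mean-expression profile of droplet data.
draw_base_means <- function(n_genes, lib_size_mean) {
  bm <- exp(stats::rnorm(n_genes, mean = 0, sd = 1.2))
  bm / sum(bm) * lib_size_mean
}

#' Generate a synthetic single-cell cohort
#'
#' @param config a \code{\link{cohort_config}}.
#' @return A \code{\link{cell_matrix}} whose \code{cell_meta} carries
#'   \code{true_type}; attribute \code{signature_genes} holds the planted
#'   per-type signature gene lists, \code{batch_genes} the per-patient
#'   affected gene sets.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    ng <- config$n_genes
    np <- config$n_patients
    nc <- np * config$cells_per_patient
    genes <- sprintf("gene%05d", seq_len(ng))
    base_mean <- draw_base_means(ng, config$lib_size_mean)

    type_names <- vapply(config$cell_type_spec, `[[`, character(1), "type_name")
    props <- vapply(config$cell_type_spec, `[[`, numeric(1), "proportion")
    # disjoint signature blocks
    pool <- seq_len(ng)
    sig_genes <- list()
    sig_lfc <- numeric(length(type_names))
    for (i in seq_along(config$cell_type_spec)) {
      s <- config$cell_type_spec[[i]]
      picked <- sample(pool, s$signature_genes)
      pool <- setdiff(pool, picked)
      sig_genes[[s$type_name]] <- genes[sort(picked)]
      sig_lfc[i] <- s$signature_log2fc
    }

    patient_id <- rep(sprintf("P%02d", seq_len(np)), each = config$cells_per_patient)
    tissue <- rep(config$tissue_assignment, each = config$cells_per_patient)
    true_type <- sample(type_names, nc, replace = TRUE, prob = props)

    # per-patient batch effects, log2 scale, on a random gene subset
    batch_log2 <- matrix(0, ng, np)
    batch_genes <- list()
    n_affected <- round(config$batch_gene_frac * ng)
    for (p in seq_len(np)) {
      aff <- sample(ng, n_affected)
      batch_log2[aff, p] <- stats::rnorm(n_affected, 0, config$batch_sd)
      batch_genes[[p]] <- genes[sort(aff)]
    }
    names(batch_genes) <- sprintf("P%02d", seq_len(np))

    sf <- exp(stats::rnorm(nc, 0, 0.3))  # library-size factors

    mu <- matrix(base_mean, ng, nc)
    # signature effects by cell type
    for (i in seq_along(type_names)) {
      idx <- match(sig_genes[[type_names[i]]], genes)
      cells_i <- which(true_type == type_names[i])
      if (length(cells_i) && length(idx) && sig_lfc[i] != 0) {
        mu[idx, cells_i] <- mu[idx, cells_i] * 2^sig_lfc[i]
      }
    }
    p_idx <- match(patient_id, sprintf("P%02d", seq_len(np)))
    mu <- mu * 2^batch_log2[, p_idx, drop = FALSE]
    mu <- sweep(mu, 2, sf, "*")

    counts <- matrix(stats::rnbinom(ng * nc, mu = mu, size = config$dispersion),
                     ng, nc, dimnames = list(genes, sprintf("cell%06d", seq_len(nc))))
    meta <- data.frame(patient_id = patient_id, sample_id = patient_id,
                       tissue_type = tissue, dataset_id = "synthetic",
                       true_type = true_type, stringsAsFactors = FALSE)
    out <- cell_matrix(counts, meta)
    attr(out, "signature_genes") <- sig_genes
    attr(out, "batch_genes") <- batch_genes
    out
  })
}

#' Configuration for synthetic differentiation trajectories
#'
#' Emulates two progenitor branches converging on one terminal state, with
#' gene modules activated in ordered pseudotime windows. A module gene's NB
#' mean is multiplied by \code{2^(amplitude * bump(t))}, where \code{bump} is
#' a smooth unimodal function (squared sine) supported on the activation
#' window. Branch-identity genes decay as \code{2^(log2fc * (1 - t))} on
#' their branch only, so the two progenitor states are distinguishable and
#' fade into the shared terminal state.
#'
#' @param n_cells cells per dataset.
#' @param n_genes genes per dataset.
#' @param module_spec list of lists with \code{module_name}, \code{genes}
#'   (count), \code{activation_window} (c(lo, hi) within [0,1]) and
#'   \code{amplitude_log2fc}. Gene sets are disjoint by construction.
#' @param branch_spec list with entries \code{branchA}, \code{branchB}, each
#'   a list with \code{genes} (count) and \code{log2fc}.
#' @param n_datasets number of independent replicate datasets.
#' @param n_patients_per_dataset patients (batch units) per dataset.
#' @param batch_sd,batch_gene_frac,dispersion,lib_size_mean as in
#'   \code{\link{cohort_config}}.
#' @param seed integer seed.
#' @return A \code{trajectory_config} list.
#' @export
trajectory_config <- function(n_cells = 500, n_genes = 1500,
                              module_spec = list(
                                list(module_name = "progenitor", genes = 50,
                                     activation_window = c(0, 0.3),
                                     amplitude_log2fc = 1.5),
                                list(module_name = "early-activation", genes = 50,
                                     activation_window = c(0.15, 0.5),
                                     amplitude_log2fc = 1.5),
                                list(module_name = "proto-differentiation", genes = 50,
                                     activation_window = c(0.45, 0.85),
                                     amplitude_log2fc = 1.5),
                                list(module_name = "differentiation", genes = 50,
                                     activation_window = c(0.7, 1),
                                     amplitude_log2fc = 1.5)),
                              branch_spec = list(
                                branchA = list(genes = 40, log2fc = 2),
                                branchB = list(genes = 40, log2fc = 2)),
                              n_datasets = 3, n_patients_per_dataset = 4,
                              batch_sd = 0.3, batch_gene_frac = 0.3,
                              dispersion = 10, lib_size_mean = 10000,
                              seed = 1) {
  stopifnot(is_count(n_cells), is_count(n_genes), is_count(n_datasets))
  for (m in module_spec) {
    w <- m$activation_window
    if (!(length(w) == 2 && w[1] >= 0 && w[2] <= 1 && w[1] < w[2])) {
      stopf("activation_window of module '%s' must satisfy 0 <= lo < hi <= 1",
            m$module_name)
    }
  }
  total <- sum(vapply(module_spec, `[[`, numeric(1), "genes")) +
    sum(vapply(branch_spec, `[[`, numeric(1), "genes"))
  if (total > n_genes) stopf("module + branch genes exceed n_genes")
  structure(list(n_cells = n_cells, n_genes = n_genes,
                 module_spec = module_spec, branch_spec = branch_spec,
                 n_datasets = n_datasets,
                 n_patients_per_dataset = n_patients_per_dataset,
                 batch_sd = batch_sd, batch_gene_frac = batch_gene_frac,
                 dispersion = dispersion, lib_size_mean = lib_size_mean,
                 seed = seed),
            class = "trajectory_config")
}

# Smooth unimodal bump supported on [lo, hi]: sin^2 rescaled to peak at 1.
bump_window <- function(t, lo, hi) {
  b <- numeric(length(t))
  inside <- t >= lo & t <= hi
  b[inside] <- sin(pi * (t[inside] - lo) / (hi - lo))^2
  b
}

#' Generate replicate trajectory datasets
#'
#' @param config a \code{\link{trajectory_config}}.
#' @return A list of \code{\link{cell_matrix}} objects (one per dataset),
#'   each with \code{true_pseudotime} and \code{true_branch} in
#'   \code{cell_meta}. The list carries attributes \code{module_genes}
#'   (named list of gene vectors, shared across datasets) and
#'   \code{branch_genes}.
#' @export
generate_trajectory_dataset <- function(config) {
  stopifnot(inherits(config, "trajectory_config"))
  with_seed(config$seed, {
    ng <- config$n_genes
    genes <- sprintf("gene%05d", seq_len(ng))
    base_mean <- draw_base_means(ng, config$lib_size_mean)

    pool <- seq_len(ng)
    module_genes <- list()
    for (m in config$module_spec) {
      picked <- sample(pool, m$genes)
      pool <- setdiff(pool, picked)
      module_genes[[m$module_name]] <- genes[sort(picked)]
    }
    branch_genes <- list()
    for (bn in names(config$branch_spec)) {
      picked <- sample(pool, config$branch_spec[[bn]]$genes)
      pool <- setdiff(pool, picked)
      branch_genes[[bn]] <- genes[sort(picked)]
    }

    datasets <- vector("list", config$n_datasets)
    for (d in seq_len(config$n_datasets)) {
      nc <- config$n_cells
      t_cell <- stats::runif(nc)
      branch_names <- names(config$branch_spec)
      branch <- sample(branch_names, nc, replace = TRUE)
      np <- config$n_patients_per_dataset
      patient <- sample(sprintf("D%dP%02d", d, seq_len(np)), nc, replace = TRUE)

      mu <- matrix(base_mean, ng, nc)
      for (m in config$module_spec) {
        idx <- match(module_genes[[m$module_name]], genes)
        w <- m$activation_window
        boost <- 2^(m$amplitude_log2fc * bump_window(t_cell, w[1], w[2]))
        mu[idx, ] <- mu[idx, ] * rep(boost, each = length(idx))
      }
      for (bn in names(config$branch_spec)) {
        idx <- match(branch_genes[[bn]], genes)
        on_branch <- branch == bn
        boost <- ifelse(on_branch,
                        2^(config$branch_spec[[bn]]$log2fc * (1 - t_cell)), 1)
        mu[idx, ] <- mu[idx, ] * rep(boost, each = length(idx))
      }
      # per-patient batch effects
      n_aff <- round(config$batch_gene_frac * ng)
      pat_levels <- sort(unique(patient))
      batch_log2 <- matrix(0, ng, length(pat_levels))
      for (p in seq_along(pat_levels)) {
        aff <- sample(ng, n_aff)
        batch_log2[aff, p] <- stats::rnorm(n_aff, 0, config$batch_sd)
      }
      mu <- mu * 2^batch_log2[, match(patient, pat_levels), drop = FALSE]
      sf <- exp(stats::rnorm(nc, 0, 0.3))
      mu <- sweep(mu, 2, sf, "*")

      counts <- matrix(stats::rnbinom(ng * nc, mu = mu, size = config$dispersion),
                       ng, nc,
                       dimnames = list(genes, sprintf("D%dcell%05d", d, seq_len(nc))))
      meta <- data.frame(patient_id = patient, sample_id = patient,
                         tissue_type = "control",
                         dataset_id = sprintf("dataset%d", d),
                         true_pseudotime = t_cell, true_branch = branch,
                         stringsAsFactors = FALSE)
      datasets[[d]] <- cell_matrix(counts, meta)
    }
    attr(datasets, "module_genes") <- module_genes
    attr(datasets, "branch_genes") <- branch_genes
    datasets
  })
}

#' Configuration for a synthetic survival cohort
#'
#' Event times are Weibull with the subject hazard multiplied by
#' \code{exp(log_hazard_per_unit * score)}; the continuous score is normal,
#' truncated to [0, 100] (mimicking a percentage abundance). Subjects are
#' censored at \code{min(censor_time, U(0, 2 * censor_time))}.
#'
#' @param n_subjects cohort size.
#' @param score_mean,score_sd distribution of the continuous score.
#' @param log_hazard_per_unit planted log hazard ratio per score unit.
#' @param weibull_shape,weibull_scale baseline Weibull parameters (months).
#' @param censor_time administrative censoring horizon (months).
#' @param seed integer seed.
#' @return A \code{survival_config} list.
#' @export
survival_config <- function(n_subjects = 500, score_mean = 50, score_sd = 20,
                            log_hazard_per_unit = 0.02,
                            weibull_shape = 1.2, weibull_scale = 80,
                            censor_time = 120, seed = 1) {
  stopifnot(is_count(n_subjects))
  if (weibull_shape <= 0 || weibull_scale <= 0) stopf("Weibull parameters must be > 0")
  if (censor_time < 0) stopf("censor_time must be >= 0")
  structure(list(n_subjects = n_subjects, score_mean = score_mean,
                 score_sd = score_sd,
                 log_hazard_per_unit = log_hazard_per_unit,
                 weibull_shape = weibull_shape, weibull_scale = weibull_scale,
                 censor_time = censor_time, seed = seed),
            class = "survival_config")
}

#' Generate a synthetic survival cohort
#'
#' @param config a \code{\link{survival_config}}.
#' @return data.frame with columns \code{subject_id}, \code{time_months},
#'   \code{event}, \code{score}, \code{age}, \code{stage}.
#' @export
generate_survival_cohort <- function(config) {
  stopifnot(inherits(config, "survival_config"))
  with_seed(config$seed, {
    n <- config$n_subjects
    score <- pmin(100, pmax(0, stats::rnorm(n, config$score_mean, config$score_sd)))
    lp <- config$log_hazard_per_unit * score
    u <- stats::runif(n)
    t_event <- config$weibull_scale * (-log(u) / exp(lp))^(1 / config$weibull_shape)
    cens <- pmin(config$censor_time, stats::runif(n, 0, 2 * config$censor_time))
    event <- as.integer(t_event <= cens)
    time <- pmin(t_event, cens)
    time <- pmax(time, 1e-6)  # keep times strictly positive
    data.frame(subject_id = sprintf("S%04d", seq_len(n)),
               time_months = time, event = event, score = score,
               age = round(stats::rnorm(n, 65, 9)),
               stage = sample(1:4, n, replace = TRUE,
                              prob = c(0.4, 0.25, 0.25, 0.1)),
               stringsAsFactors = FALSE)
  })
}

#' Write a survival cohort as CSV
#'
#' @param records data.frame from \code{\link{generate_survival_cohort}}.
#' @param path output CSV path (header time_months,event,score,age,stage).
#' @export
write_survival_csv <- function(records, path) {
  utils::write.csv(records[, c("time_months", "event", "score", "age", "stage")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
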