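# Deconvolution benchmarking: signature-matrix construction from a
# downsampled single-cell reference, pseudobulk mixtures with known
# fractions, a non-negative least-squares deconvolution stand-in for
# external digital-cytometry services, and accuracy evaluation.

#' Build a cell-type signature matrix
#'
#' Each cell type is randomly downsampled to at most \code{max_cells}; per
#' type, a one-vs-rest Wilcoxon rank-sum scan on log-normalized expression
#' selects up to \code{genes_per_type} genes (Bonferroni-adjusted
#' p < \code{alpha}, ranked by fold change toward the type). The signature
#' matrix holds per-type mean linear-scale normalized expression on the
#' union of selected genes.
#'
#' @param ref a \code{\link{cell_matrix}} with type labels.
#' @param labels per-cell type labels (default \code{true_type} metadata).
#' @param max_cells downsampling cap per type (default 500).
#' @param genes_per_type genes selected per type.
#' @param alpha adjusted-p threshold for selection.
#' @param seed integer seed for downsampling.
#' @return An object of class \code{signature_matrix}: \code{matrix}
#'   (genes x types, linear scale), \code{n_cells_used}, \code{selection}
#'   (per-type selected genes).
#' @export
build_signature_matrix <- function(ref, labels = NULL, max_cells = 500,
                                   genes_per_type = 50, alpha = 0.01,
                                   seed = 1) {
  stopifnot(inherits(ref, "cell_matrix"))
  if (is.null(labels)) labels <- ref$cell_meta$true_type
  labels <- as.character(labels)
  types <- sort(unique(labels))
  if (length(types) < 2) stopf("need at least 2 cell types")
  sizes <- table(labels)
  if (any(sizes < 10)) {
    stopf("cell type '%s' has fewer than 10 cells", names(sizes)[which.min(sizes)])
  }
  keep <- with_seed(seed, {
    unlist(lapply(types, function(ty) {
      cells <- which(labels == ty)
      if (length(cells) > max_cells) sample(cells, max_cells) else cells
    }))
  })
  sub_labels <- labels[keep]
  ln <- ref$lognorm[, keep, drop = FALSE]
  lin <- expm1(ln)
  selection <- list()
  for (ty in types) {
    a <- which(sub_labels == ty); b <- which(sub_labels != ty)
    res <- row_ranksum(ln, a, b)
    adj <- pmin(1, res[, "p"] * nrow(ln))
    lfc <- log2fc_expm1(rowMeans(ln[, a, drop = FALSE]),
                        rowMeans(ln[, b, drop = FALSE]))
    cand <- which(adj < alpha & lfc > 0)
    if (!length(cand)) stopf("cell type '%s' yields no significant genes", ty)
    cand <- cand[order(-lfc[cand])]
    selection[[ty]] <- ref$genes[cand[seq_len(min(genes_per_type, length(cand)))]]
  }
  sig_genes <- sort(unique(unlist(selection)))
  mat <- vapply(types, function(ty) {
    rowMeans(lin[sig_genes, sub_labels == ty, drop = FALSE])
  }, numeric(length(sig_genes)))
  rownames(mat) <- sig_genes
  structure(list(matrix = mat,
                 n_cells_used = stats::setNames(
                   as.integer(table(sub_labels)[types]), types),
                 selection = selection),
            class = "signature_matrix")
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat(sprintf("<signature_matrix> %d genes x %d types\n",
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Simulate pseudobulk mixtures with known composition
#'
#' For each sample, \code{cells_per_sample} cells are drawn from
#' \code{patients_per_sample} randomly chosen patients, then the fibroblast
#' content is topped up or down to a target fraction drawn uniformly from
#' \code{fib_fraction_range} (fibroblast cells are swapped in or out while
#' the total cell count is kept fixed). Mixtures are summed counts scaled to
#' counts-per-million; truth fractions are the realized cell-type shares.
#'
#' @param ref a \code{\link{cell_matrix}} with type labels.
#' @param labels per-cell type labels (default \code{true_type}).
#' @param fibroblast_types labels counted as fibroblast subpopulations.
#' @param n_samples number of pseudobulk samples (default 200).
#' @param cells_per_sample cells per sample (default 1000).
#' @param patients_per_sample source patients per sample (default 3).
#' @param fib_fraction_range target fibroblast fraction range
#'   (default c(0.01, 0.5)).
#' @param seed integer seed.
#' @return An object of class \code{pseudobulk_set}: \code{mixtures}
#'   (genes x samples, CPM), \code{truth} (samples x types, rows sum to 1),
#'   \code{source_patients}.
#' @export
simulate_pseudobulk <- function(ref, labels = NULL,
                                fibroblast_types = c("adventitial", "alveolar",
                                                     "myofibroblast"),
                                n_samples = 200, cells_per_sample = 1000,
                                patients_per_sample = 3,
                                fib_fraction_range = c(0.01, 0.50), seed = 1) {
  stopifnot(inherits(ref, "cell_matrix"))
  if (is.null(labels)) labels <- ref$cell_meta$true_type
  labels <- as.character(labels)
  patients <- as.character(ref$cell_meta$patient_id)
  pat_levels <- unique(patients)
  if (length(pat_levels) < patients_per_sample) {
    stopf("reference has %d patients; need >= %d", length(pat_levels),
          patients_per_sample)
  }
  is_fib <- labels %in% fibroblast_types
  if (!any(is_fib) || all(is_fib)) {
    stopf("reference must contain both fibroblast and non-fibroblast cells")
  }
  types <- sort(unique(labels))
  with_seed(seed, {
    mix <- matrix(0, nrow(ref$counts), n_samples,
                  dimnames = list(ref$genes, sprintf("pb%03d", seq_len(n_samples))))
    truth <- matrix(0, n_samples, length(types),
                    dimnames = list(colnames(mix), types))
    src <- vector("list", n_samples)
    for (s in seq_len(n_samples)) {
      target <- stats::runif(1, fib_fraction_range[1], fib_fraction_range[2])
      n_fib_target <- round(target * cells_per_sample)
      chosen <- NULL
      for (attempt in seq_len(100)) {
        pats <- sample(pat_levels, patients_per_sample)
        pool <- which(patients %in% pats)
        if (length(pool) < cells_per_sample) next
        base <- sample(pool, cells_per_sample)
        fib_pool_all <- which(is_fib)           # top-up may draw cohort-wide
        base_fib <- base[is_fib[base]]
        n_fib <- length(base_fib)
        if (n_fib > n_fib_target) {
          drop_fib <- sample(base_fib, n_fib - n_fib_target)
          non_fib_extra <- setdiff(pool[!is_fib[pool]], base)
          if (length(non_fib_extra) < length(drop_fib)) next
          base <- c(setdiff(base, drop_fib),
                    sample(non_fib_extra, length(drop_fib)))
        } else if (n_fib < n_fib_target) {
          need <- n_fib_target - n_fib
          fib_extra <- setdiff(fib_pool_all, base)
          base_non_fib <- base[!is_fib[base]]
          if (length(fib_extra) < need || length(base_non_fib) < need) next
          base <- c(setdiff(base, sample(base_non_fib, need)),
                    sample(fib_extra, need))
        }
        chosen <- base
        break
      }
      if (is.null(chosen)) {
        stopf("could not attain fibroblast fraction %.3f after 100 attempts", target)
      }
      counts <- rowSums(ref$counts[, chosen, drop = FALSE])
      mix[, s] <- counts / sum(counts) * 1e6
      tt <- table(factor(labels[chosen], levels = types))
      truth[s, ] <- as.numeric(tt) / length(chosen)
      src[[s]] <- unique(patients[chosen])
    }
    structure(list(mixtures = mix, truth = truth, source_patients = src,
                   fibroblast_types = fibroblast_types),
              class = "pseudobulk_set")
  })
}

#' Non-negative least-squares deconvolution
#'
#' Per sample, the mixture restricted to the signature genes (linear scale)
#' is regressed on the signature-matrix columns under a non-negativity
#' constraint. Absolute scores are the NNLS coefficients; relative
#' fibroblast subpopulation percentages are each fibroblast coefficient as
#' a share of the summed fibroblast coefficients (x 100).
#'
#' @param mixtures a \code{\link{pseudobulk_set}} or genes x samples matrix
#'   (e.g. read from an external CSV).
#' @param sig a \code{\link{signature_matrix}}.
#' @param fibroblast_types labels treated as fibroblast subpopulations.
#' @return An object of class \code{deconv_result}: \code{scores}
#'   (samples x types, >= 0) and \code{fib_percent} (samples x fibroblast
#'   types, rows summing to 100).
#' @export
deconvolve <- function(mixtures, sig,
                       fibroblast_types = c("adventitial", "alveolar",
                                            "myofibroblast")) {
  stopifnot(inherits(sig, "signature_matrix"))
  M <- if (inherits(mixtures, "pseudobulk_set")) mixtures$mixtures else as.matrix(mixtures)
  shared <- intersect(rownames(sig$matrix), rownames(M))
  if (length(shared) < 20) {
    stopf("only %d signature genes shared with the mixture (need >= 20)",
          length(shared))
  }
  S <- sig$matrix[shared, , drop = FALSE]
  types <- colnames(S)
  scores <- matrix(0, ncol(M), length(types),
                   dimnames = list(colnames(M), types))
  for (s in seq_len(ncol(M))) {
    y <- M[shared, s]
    if (all(y == 0)) stopf("mixture column '%s' is all zero", colnames(M)[s])
    scores[s, ] <- pracma::lsqnonneg(S, y)$x
  }
  fib <- intersect(types, fibroblast_types)
  fib_percent <- NULL
  if (length(fib)) {
    denom <- rowSums(scores[, fib, drop = FALSE])
    denom[denom == 0] <- NA_real_
    fib_percent <- 100 * scores[, fib, drop = FALSE] / denom
  }
  structure(list(scores = scores, fib_percent = fib_percent,
                 n_genes_used = length(shared),
                 scale_note = "fibroblast percentages are relative to total fibroblast score"),
            class = "deconv_result")
}

#' Evaluate deconvolution accuracy against known fractions
#'
#' Ordinary least squares of estimated score on true fraction, per type.
#'
#' @param result a \code{\link{deconvolve}} result (or samples x types
#'   matrix of estimates).
#' @param truth samples x types matrix of true fractions.
#' @return data.frame (type, r_squared, slope, n); \code{r_squared} is NA
#'   when the truth is constant.
#' @export
evaluate_deconvolution <- function(result, truth) {
  est <- if (inherits(result, "deconv_result")) result$scores else as.matrix(result)
  truth <- as.matrix(truth)
  types <- intersect(colnames(est), colnames(truth))
  if (!length(types)) stopf("no shared cell types between estimates and truth")
  if (nrow(est) != nrow(truth)) stopf("estimates and truth differ in samples")
  if (!is.null(rownames(truth)) && !is.null(rownames(est))) {
    est <- est[rownames(truth), , drop = FALSE]
  }
  out <- lapply(types, function(ty) {
    x <- truth[, ty]; y <- est[, ty]
    if (stats::var(x) == 0) {
      return(data.frame(type = ty, r_squared = NA_real_, slope = NA_real_,
                        n = length(x)))
    }
    fit <- stats::lm(y ~ x)
    data.frame(type = ty, r_squared = summary(fit)$r.squared,
               slope = unname(stats::coef(fit)[2]), n = length(x))
  })
  do.call(rbind, out)
}

#' Write a signature matrix or mixtures as TSV (gene symbols in column 1)
#'
#' @param x a \code{signature_matrix}, \code{pseudobulk_set}, or matrix.
#' @param path output TSV path.
#' @export
write_deconv_tsv <- function(x, path) {
  m <- if (inherits(x, "signature_matrix")) x$matrix else
    if (inherits(x, "pseudobulk_set")) x$mixtures else as.matrix(x)
  utils::write.table(data.frame(gene = rownames(m), m, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
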