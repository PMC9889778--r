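# Gene-module scoring, consensus signature derivation, the stromal
# demarcation rule, and a centroid-correlation subpopulation classifier.

#' Score a gene module with expression-matched controls
#'
#' Per-cell module score: mean log-normalized expression of the set genes
#' minus the mean over control genes sampled from expression-matched bins.
#' Genes are binned by their average log-normalized expression into
#' \code{n_bins}; for each set gene, \code{n_ctrl} control genes are drawn
#' from its bin (excluding set genes; with replacement when the bin holds
#' fewer candidates). Control draws are pooled across set genes.
#'
#' @param expr a \code{\link{cell_matrix}}.
#' @param set a \code{\link{gene_set}}; at least one gene must be present.
#' @param n_bins number of expression bins (>= 2).
#' @param n_ctrl control genes sampled per set gene.
#' @param seed integer seed for control sampling.
#' @return Named numeric vector of per-cell scores.
#' @export
score_gene_module <- function(expr, set, n_bins = 25, n_ctrl = 100, seed = 1) {
  stopifnot(inherits(expr, "cell_matrix"), inherits(set, "gene_set"))
  if (n_bins < 2) stopf("n_bins must be >= 2")
  genes <- expr$genes
  set_present <- intersect(set$genes, genes)
  if (!length(set_present)) {
    stopf("no genes of set '%s' are present in the matrix", set$name)
  }
  if (length(set_present) == length(genes)) {
    stopf("set '%s' covers every gene; no control genes available", set$name)
  }
  avg <- rowMeans(expr$lognorm)
  # equal-occupancy bins on the rank of average expression
  r <- rank(avg, ties.method = "first")
  bin <- ceiling(r * n_bins / length(genes))
  set_idx <- match(set_present, genes)
  in_set <- logical(length(genes)); in_set[set_idx] <- TRUE
  ctrl_idx <- with_seed(seed, {
    unlist(lapply(set_idx, function(i) {
      cand <- which(bin == bin[i] & !in_set)
      if (!length(cand)) {
        cand <- which(!in_set)  # degenerate bin: fall back to all non-set genes
      }
      cand[sample.int(length(cand), n_ctrl, replace = length(cand) < n_ctrl)]
    }))
  })
  score <- colMeans(expr$lognorm[set_idx, , drop = FALSE]) -
    colMeans(expr$lognorm[ctrl_idx, , drop = FALSE])
  stats::setNames(score, colnames(expr$counts))
}

#' Derive consensus marker signatures for two stromal classes
#'
#' Per-gene two-group Wilcoxon rank-sum on log-normalized expression with
#' Bonferroni adjustment; genes pass at \code{adj_p < alpha} and
#' \code{|log2FC| > lfc_min} (fold change on the linear scale reconstructed
#' from mean log-normalized values), signed toward the respective class, and
#' are intersected with a whitelist of previously described genes.
#'
#' @param expr a \code{\link{cell_matrix}}.
#' @param labels per-cell labels; only cells labeled \code{"fibroblast"} or
#'   \code{"mural"} enter the test (each class needs >= 3 cells).
#' @param whitelist a \code{\link{gene_set}} restricting candidates.
#' @param alpha Bonferroni-adjusted significance threshold.
#' @param lfc_min minimum absolute log2 fold change.
#' @return List with \code{gene_set}s \code{fibroblast} and \code{mural}
#'   (always disjoint; possibly empty with a warning) and the full
#'   \code{table} of per-gene statistics.
#' @export
derive_consensus_signature <- function(expr, labels, whitelist,
                                       alpha = 0.01, lfc_min = 0.5) {
  stopifnot(inherits(expr, "cell_matrix"), inherits(whitelist, "gene_set"))
  if (length(labels) != ncol(expr$counts)) stopf("labels length mismatch")
  fib_cells <- which(labels == "fibroblast")
  mur_cells <- which(labels == "mural")
  if (length(fib_cells) < 3 || length(mur_cells) < 3) {
    stopf("each class needs at least 3 cells (fibroblast: %d, mural: %d)",
          length(fib_cells), length(mur_cells))
  }
  res <- row_ranksum(expr$lognorm, fib_cells, mur_cells)
  p <- res[, "p"]
  adj_p <- pmin(1, p * length(p))
  lfc <- log2fc_expm1(rowMeans(expr$lognorm[, fib_cells, drop = FALSE]),
                      rowMeans(expr$lognorm[, mur_cells, drop = FALSE]))
  tab <- data.frame(gene = expr$genes, log2fc = lfc, p = p, adj_p = adj_p,
                    stringsAsFactors = FALSE)
  in_wl <- expr$genes %in% whitelist$genes
  fib_genes <- expr$genes[in_wl & adj_p < alpha & lfc > lfc_min]
  mur_genes <- expr$genes[in_wl & adj_p < alpha & lfc < -lfc_min]
  if (!length(fib_genes) || !length(mur_genes)) {
    warnf("empty signature: %d fibroblast, %d mural genes pass",
          length(fib_genes), length(mur_genes))
  }
  list(fibroblast = if (length(fib_genes)) gene_set("fibroblast", fib_genes),
       mural = if (length(mur_genes)) gene_set("mural", mur_genes),
       table = tab)
}

#' Demarcate fibroblasts from mural cells by signature scores
#'
#' A cell is called fibroblast when its fibroblast score exceeds the mural
#' score by more than \code{margin} and is itself above \code{floor}; the
#' mural branch is symmetric; all remaining cells are left unassigned.
#'
#' @param fib,mural per-cell signature scores on the same cells.
#' @param margin required score difference (default 0.1).
#' @param floor minimum winning score (default 0).
#' @return Character vector of labels in
#'   \{fibroblast, mural, unassigned\}.
#' @export
classify_stromal <- function(fib, mural, margin = 0.1, floor = 0) {
  if (length(fib) != length(mural)) stopf("score vectors differ in length")
  lab <- rep("unassigned", length(fib))
  lab[fib - mural > margin & fib > floor] <- "fibroblast"
  lab[mural - fib > margin & mural > floor] <- "mural"
  names(lab) <- names(fib)
  lab
}

#' Probabilistic subpopulation classification by centroid correlation
#'
#' A simplified cross-dataset classifier: per-class centroids of the
#' reference's log-normalized expression on the genes shared with the query;
#' per-cell Pearson correlation to each centroid; class probabilities are the
#' softmax of correlations divided by \code{temperature}.
#'
#' @param query a \code{\link{cell_matrix}} of cells to classify.
#' @param reference a \code{\link{cell_matrix}} with labels.
#' @param ref_labels per-cell reference labels (default: the reference's
#'   \code{true_type} metadata column); every class needs >= 3 cells.
#' @param temperature softmax temperature (> 0); large values flatten the
#'   probabilities toward uniform.
#' @return List with \code{class} (per-cell argmax label) and \code{prob}
#'   (cells x classes matrix, rows summing to 1).
#' @export
classify_subpopulation <- function(query, reference, ref_labels = NULL,
                                   temperature = 1.0) {
  stopifnot(inherits(query, "cell_matrix"), inherits(reference, "cell_matrix"))
  if (is.null(ref_labels)) ref_labels <- reference$cell_meta$true_type
  if (is.null(ref_labels)) stopf("ref_labels missing and reference has no true_type")
  shared <- intersect(query$genes, reference$genes)
  if (length(shared) < 50) {
    stopf("only %d genes shared between query and reference (need >= 50)",
          length(shared))
  }
  classes <- sort(unique(ref_labels))
  sizes <- table(ref_labels)
  if (any(sizes < 3)) {
    stopf("reference class '%s' has fewer than 3 cells",
          names(sizes)[which.min(sizes)])
  }
  ref_ln <- reference$lognorm[shared, , drop = FALSE]
  centroids <- vapply(classes, function(cl) {
    rowMeans(ref_ln[, ref_labels == cl, drop = FALSE])
  }, numeric(length(shared)))
  cors <- suppressWarnings(stats::cor(query$lognorm[shared, , drop = FALSE],
                                      centroids))
  cors[is.na(cors)] <- 0
  z <- cors / temperature
  z <- z - apply(z, 1, max)
  prob <- exp(z) / rowSums(exp(z))
  colnames(prob) <- classes
  rownames(prob) <- colnames(query$counts)
  cls <- classes[max.col(prob, ties.method = "first")]
  list(class = stats::setNames(cls, rownames(prob)), prob = prob)
}

#' Write subpopulation predictions as CSV
#'
#' @param pred result of \code{\link{classify_subpopulation}}.
#' @param path output CSV path (cell_id, label, prob_<class>...).
#' @export
write_predictions_csv <- function(pred, path) {
  df <- data.frame(cell_id = names(pred$class), label = unname(pred$class),
                   stringsAsFactors = FALSE)
  probs <- as.data.frame(pred$prob)
  names(probs) <- paste0("prob_", names(probs))
  utils::write.csv(cbind(df, probs), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
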