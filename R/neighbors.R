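# PCA embedding and k-nearest-neighbour / shared-nearest-neighbour graphs.

#' Select highly variable genes
#'
#' Ranks genes by their log-normalized variance in excess of the loess
#' trend of variance on mean expression, the usual mean-variance
#' de-trending. Use before PCA when the biological signal is carried by a
#' minority of genes.
#'
#' @param expr a \code{\link{cell_matrix}}.
#' @param n number of genes to keep.
#' @return Character vector of selected gene symbols.
#' @export
select_hvgs <- function(expr, n = 200) {
  stopifnot(inherits(expr, "cell_matrix"))
  v <- apply(expr$lognorm, 1, stats::var)
  m <- rowMeans(expr$lognorm)
  trend <- tryCatch(stats::predict(stats::loess(v ~ m, span = 0.3)),
                    error = function(e) rep(mean(v), length(v)))
  excess <- v - trend
  expr$genes[order(-excess)[seq_len(min(n, length(excess)))]]
}

#' Principal-component embedding of log-normalized expression
#'
#' Cells are embedded on the top principal components of the gene-centred
#' log-normalized matrix. The eigendecomposition is taken on whichever
#' covariance dimension is smaller, so large cell numbers stay cheap.
#'
#' @param expr a \code{\link{cell_matrix}} or a cells x features matrix.
#' @param n_pcs number of components.
#' @param n_hvg optional count of highly variable genes to restrict the PCA
#'   to (see \code{\link{select_hvgs}}); \code{NULL} uses all genes.
#' @return cells x n_pcs score matrix.
#' @export
pca_embed <- function(expr, n_pcs = 30, n_hvg = NULL) {
  x <- if (inherits(expr, "cell_matrix")) {
    if (!is.null(n_hvg)) t(expr$lognorm[select_hvgs(expr, n_hvg), , drop = FALSE])
    else t(expr$lognorm)
  } else as.matrix(expr)
  x <- sweep(x, 2, colMeans(x), "-")
  n_pcs <- min(n_pcs, dim(x) - 1L)
  if (ncol(x) <= nrow(x)) {
    cv <- crossprod(x) / (nrow(x) - 1)
    ev <- eigen(cv, symmetric = TRUE)
    scores <- x %*% ev$vectors[, seq_len(n_pcs), drop = FALSE]
  } else {
    sv <- svd(x, nu = n_pcs, nv = 0)
    scores <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  }
  rownames(scores) <- rownames(x)
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  scores
}

# Block-wise exact kNN by Euclidean distance; returns index and distance
# matrices (self excluded).
knn_brute <- function(emb, k, block = 512L) {
  n <- nrow(emb)
  if (k >= n) stopf("k (%d) must be smaller than the number of cells (%d)", k, n)
  sq <- rowSums(emb^2)
  idx <- matrix(0L, n, k)
  dst <- matrix(0, n, k)
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    d2 <- outer(sq[rows], sq, "+") - 2 * tcrossprod(emb[rows, , drop = FALSE], emb)
    d2[cbind(seq_along(rows), rows)] <- Inf  # drop self
    for (j in seq_along(rows)) {
      o <- order(d2[j, ])[seq_len(k)]
      idx[rows[j], ] <- o
      dst[rows[j], ] <- sqrt(pmax(d2[j, o], 0))
    }
  }
  list(idx = idx, dist = dst)
}

#' k-nearest-neighbour graph of cells
#'
#' Exact Euclidean kNN in a reduced embedding (default: top 30 principal
#' components of log-normalized expression). Accepts a precomputed embedding
#' so externally batch-corrected coordinates can be plugged in.
#'
#' @param expr a \code{\link{cell_matrix}} or a cells x dims embedding matrix.
#' @param k neighbours per cell (self excluded).
#' @param n_pcs components used when \code{expr} is a \code{cell_matrix}.
#' @return An object of class \code{neighbor_graph}: list with \code{idx}
#'   (cells x k neighbour indices), \code{dist}, \code{k}, \code{embedding}.
#' @export
knn_graph <- function(expr, k = 20, n_pcs = 30) {
  emb <- if (inherits(expr, "cell_matrix")) pca_embed(expr, n_pcs) else as.matrix(expr)
  res <- knn_brute(emb, k)
  structure(list(idx = res$idx, dist = res$dist, k = k, embedding = emb),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("<neighbor_graph> %d cells, k = %d, %d-dim embedding\n",
              nrow(x$idx), x$k, ncol(x$embedding)))
  invisible(x)
}

# Shared-nearest-neighbour graph with Jaccard weights, pruned below `prune`.
# Returns an igraph object.
snn_igraph <- function(graph, prune = 1 / 15) {
  stopifnot(inherits(graph, "neighbor_graph"))
  n <- nrow(graph$idx); k <- graph$k
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(graph$idx),
                            x = 1, dims = c(n, n))
  diag(A) <- 1  # count the cell itself, as SNN implementations conventionally do
  shared <- Matrix::tcrossprod(A)
  shared <- as(shared, "TsparseMatrix")
  keep <- shared@i < shared@j
  i <- shared@i[keep] + 1L; j <- shared@j[keep] + 1L; s <- shared@x[keep]
  jac <- s / (2 * (k + 1) - s)
  ok <- jac >= prune
  igraph::graph_from_data_frame(
    data.frame(from = i[ok], to = j[ok], weight = jac[ok]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
}
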