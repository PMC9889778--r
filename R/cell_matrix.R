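#' Single-cell expression container
#'
#' A light-weight carrier for a genes-by-cells count matrix together with a
#' log-normalized layer and per-cell metadata. The log-normalized layer is
#' \code{log1p(counts scaled to a fixed per-cell total)} (default 10,000
#' counts per cell), the standard droplet-data normalization.
#'
#' @param counts genes x cells matrix of non-negative integers (dense matrix
#'   or \code{Matrix} sparse matrix), with gene symbols as rownames.
#' @param cell_meta data.frame with one row per cell; must contain
#'   \code{patient_id} and \code{sample_id}; typically also
#'   \code{tissue_type} and \code{dataset_id}, plus truth columns when the
#'   matrix was simulated.
#' @param lognorm optional precomputed log-normalized layer; computed from
#'   \code{counts} when \code{NULL}.
#' @param target_sum per-cell total used for normalization before
#'   \code{log1p}.
#' @return An object of class \code{cell_matrix} with elements
#'   \code{counts}, \code{lognorm}, \code{genes}, \code{cell_meta},
#'   \code{target_sum}.
#' @export
cell_matrix <- function(counts, cell_meta, lognorm = NULL, target_sum = 1e4) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("gene%05d", seq_len(nrow(counts)))
  }
  if (anyDuplicated(rownames(counts))) stopf("gene symbols must be unique")
  if (any(counts < 0)) stopf("counts must be non-negative")
  if (any(counts != round(counts))) stopf("counts must be integers")
  if (!is.data.frame(cell_meta) || nrow(cell_meta) != ncol(counts)) {
    stopf("cell_meta must have one row per cell (%d cells)", ncol(counts))
  }
  for (col in c("patient_id", "sample_id")) {
    if (is.null(cell_meta[[col]])) stopf("cell_meta lacks required column '%s'", col)
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("cell%06d", seq_len(ncol(counts)))
  }
  rownames(cell_meta) <- colnames(counts)
  if (is.null(lognorm)) {
    totals <- colSums(counts)
    totals[totals == 0] <- 1
    lognorm <- log1p(sweep(counts, 2, totals / target_sum, "/"))
  }
  structure(
    list(counts = counts, lognorm = lognorm, genes = rownames(counts),
         cell_meta = cell_meta, target_sum = target_sum),
    class = "cell_matrix"
  )
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("<cell_matrix> %d genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  patients: %d; samples: %d\n",
              length(unique(x$cell_meta$patient_id)),
              length(unique(x$cell_meta$sample_id))))
  extra <- setdiff(colnames(x$cell_meta), c("patient_id", "sample_id"))
  if (length(extra)) cat("  metadata:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.cell_matrix <- function(x) dim(x$counts)

#' Subset a cell_matrix by cells
#'
#' @param x a \code{cell_matrix}.
#' @param cells logical, integer, or character index into the cells.
#' @return A \code{cell_matrix} restricted to the selected cells.
#' @export
subset_cells <- function(x, cells) {
  stopifnot(inherits(x, "cell_matrix"))
  cell_matrix(x$counts[, cells, drop = FALSE],
              x$cell_meta[cells, , drop = FALSE],
              lognorm = x$lognorm[, cells, drop = FALSE],
              target_sum = x$target_sum)
}

#' Write a cell_matrix to disk
#'
#' Writes either MatrixMarket (\code{matrix.mtx} + \code{genes.tsv} +
#' \code{barcodes.tsv}) or a single dense CSV, plus a metadata TSV.
#'
#' @param x a \code{cell_matrix}.
#' @param dir output directory (created if absent).
#' @param format \code{"mtx"} or \code{"csv"}.
#' @return Invisibly, the output directory.
#' @export
write_cell_matrix <- function(x, dir, format = c("mtx", "csv")) {
  stopifnot(inherits(x, "cell_matrix"))
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(x$counts, sparse = TRUE),
                    file.path(dir, "matrix.mtx"))
    writeLines(x$genes, file.path(dir, "genes.tsv"))
    writeLines(colnames(x$counts), file.path(dir, "barcodes.tsv"))
  } else {
    utils::write.csv(as.data.frame(x$counts), file.path(dir, "counts.csv"))
  }
  utils::write.table(cbind(cell_id = colnames(x$counts), x$cell_meta),
                     file.path(dir, "cell_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a cell_matrix written by write_cell_matrix
#'
#' @param dir directory containing either \code{matrix.mtx}/\code{genes.tsv}/
#'   \code{barcodes.tsv} or \code{counts.csv}, plus \code{cell_meta.tsv}.
#' @return A \code{cell_matrix}.
#' @export
read_cell_matrix <- function(dir) {
  meta <- utils::read.delim(file.path(dir, "cell_meta.tsv"),
                            stringsAsFactors = FALSE)
  rownames(meta) <- meta$cell_id
  meta$cell_id <- NULL
  if (file.exists(file.path(dir, "matrix.mtx"))) {
    counts <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
    rownames(counts) <- readLines(file.path(dir, "genes.tsv"))
    colnames(counts) <- readLines(file.path(dir, "barcodes.tsv"))
  } else {
    counts <- as.matrix(utils::read.csv(file.path(dir, "counts.csv"),
                                        row.names = 1, check.names = FALSE))
  }
  cell_matrix(counts, meta)
}
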