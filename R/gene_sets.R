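#' Named gene set
#'
#' @param name set name.
#' @param genes character vector of unique gene symbols (non-empty).
#' @return An object of class \code{gene_set}.
#' @export
gene_set <- function(name, genes) {
  genes <- as.character(genes)
  if (!length(genes)) stopf("gene set '%s' is empty", name)
  if (anyDuplicated(genes)) stopf("gene set '%s' contains duplicates", name)
  structure(list(name = name, genes = genes), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' Read gene sets from plain text or JSON
#'
#' Plain text holds one gene symbol per line (set name = file name without
#' extension); JSON holds an object mapping set names to symbol arrays.
#'
#' @param path file path (.txt or .json).
#' @return A \code{gene_set} (text) or list of \code{gene_set}s (JSON).
#' @export
read_gene_sets <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    out <- lapply(names(raw), function(nm) gene_set(nm, raw[[nm]]))
    names(out) <- names(raw)
    out
  } else {
    lines <- trimws(readLines(path))
    gene_set(sub("\\.[^.]*$", "", basename(path)), lines[nzchar(lines)])
  }
}

#' Write gene sets
#'
#' @param sets a \code{gene_set} or list of them.
#' @param path output path; .json writes a name-to-list object, otherwise
#'   one symbol per line (single set only).
#' @export
write_gene_sets <- function(sets, path) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- stats::setNames(lapply(sets, `[[`, "genes"),
                           vapply(sets, `[[`, character(1), "name"))
    jsonlite::write_json(obj, path)
  } else {
    if (length(sets) != 1) stopf("plain-text format holds a single gene set")
    writeLines(sets[[1]]$genes, path)
  }
  invisible(path)
}
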