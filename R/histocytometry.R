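# Histo-cytometry numeric rules for multiplexed IHC: 8-bit pseudo-
# immunofluorescence conversion, moving-average background subtraction with
# the red/brown colour guard, and marker-based stromal cell classification.

#' Convert hue-saturation-density float values to the 8-bit-like range
#'
#' The float value is divided by 1.5, multiplied by 256, rounded up, and
#' capped at 256. (The capped range 0-256 exceeds a true 8-bit container by
#' one; values are therefore stored as plain integers.)
#'
#' @param value numeric vector or matrix of non-negative finite values.
#' @return Integer values in [0, 256], same shape as the input.
#' @export
hsd_to_pif8 <- function(value) {
  if (any(!is.finite(value))) stopf("values must be finite")
  if (any(value < 0)) stopf("values must be non-negative")
  out <- pmin(256, ceiling(value / 1.5 * 256))
  storage.mode(out) <- "integer"
  out
}

# Moving average over a window x window neighbourhood with edge-replicated
# padding, via a summed-area table.
moving_average <- function(mat, window) {
  h <- (window - 1) / 2
  nr <- nrow(mat); nc <- ncol(mat)
  padded <- mat[pmin(pmax(seq(1 - h, nr + h), 1), nr),
                pmin(pmax(seq(1 - h, nc + h), 1), nc), drop = FALSE]
  sat <- apply(apply(padded, 2, cumsum), 1, cumsum)  # transposed SAT
  sat <- t(sat)
  sat <- rbind(0, cbind(0, sat))
  r1 <- seq_len(nr); c1 <- seq_len(nc)
  total <- sat[r1 + window, c1 + window, drop = FALSE] -
    sat[r1, c1 + window, drop = FALSE] -
    sat[r1 + window, c1, drop = FALSE] +
    sat[r1, c1, drop = FALSE]
  total / (window * window)
}

#' Background subtraction for pseudo-immunofluorescence channels
#'
#' The local background is the moving average over a
#' \code{window} x \code{window} pixel neighbourhood (edge-replicated
#' padding). Pixels whose original value exceeds the background by less
#' than \code{min_signal} are set to 0; all other pixels keep their
#' original value. In red-channel mode (when the registration \code{brown}
#' channel is supplied), pixels where red < \code{red_brown_ratio} x brown
#' are additionally zeroed, guarding against the spectral similarity of the
#' red and brown stains.
#'
#' @param channel integer matrix (values 0-256).
#' @param window odd moving-average window (default 151).
#' @param min_signal minimum signal above background (default 5).
#' @param brown optional registration channel of the same shape.
#' @param red_brown_ratio red/brown guard ratio (default 0.43).
#' @return Matrix of the same shape; pointwise \code{<=} the input.
#' @export
subtract_background <- function(channel, window = 151, min_signal = 5,
                                brown = NULL, red_brown_ratio = 0.43) {
  channel <- as.matrix(channel)
  if (window %% 2 != 1) stopf("window must be odd")
  if (window > nrow(channel) && window > ncol(channel)) {
    stopf("window (%d) exceeds both image dimensions", window)
  }
  if (!is.null(brown) && !all(dim(brown) == dim(channel))) {
    stopf("brown channel shape mismatch")
  }
  bg <- moving_average(channel, window)
  out <- channel
  out[channel - bg < min_signal] <- 0
  if (!is.null(brown)) {
    out[channel < red_brown_ratio * brown] <- 0
  }
  out
}

#' Classify stromal cells from histo-cytometry marker coverages
#'
#' Cells positive (coverage >= \code{positive_min_coverage}) for any of the
#' epithelial/endothelial/mural exclusion markers (PanCK, CD31, MCAM) are
#' excluded. Remaining cells negative for all four fibroblast markers
#' (ACTA2, POSTN, AOC3, CD34) are unclassified. Otherwise the subpopulation
#' is the argmax coverage over the four markers, with ACTA2 and POSTN both
#' mapping to myofibroblast, AOC3 to alveolar and CD34 to adventitial.
#' Exact coverage ties are broken by the fixed priority
#' CD34 > AOC3 > POSTN > ACTA2 and flagged.
#'
#' @param cells data.frame with one row per cell and the marker coverage
#'   columns \code{PanCK}, \code{CD31}, \code{MCAM}, \code{ACTA2},
#'   \code{POSTN}, \code{AOC3}, \code{CD34} (fractions in [0, 1]).
#' @param positive_min_coverage positivity floor (default 0.01).
#' @return data.frame with \code{label} in \{excluded, adventitial,
#'   alveolar, myofibroblast, unclassified\} and \code{tie} flag.
#' @export
classify_histocytometry <- function(cells, positive_min_coverage = 0.01) {
  exclusion <- c("PanCK", "CD31", "MCAM")
  fib_markers <- c("CD34", "AOC3", "POSTN", "ACTA2")  # tie-break priority order
  miss <- setdiff(c(exclusion, fib_markers), colnames(cells))
  if (length(miss)) stopf("missing marker column '%s'", miss[1])
  for (m in c(exclusion, fib_markers)) {
    v <- cells[[m]]
    if (any(v < 0 | v > 1, na.rm = TRUE)) stopf("coverage '%s' outside [0, 1]", m)
  }
  n <- nrow(cells)
  excl <- rowSums(as.matrix(cells[, exclusion]) >= positive_min_coverage) > 0
  fibm <- as.matrix(cells[, fib_markers])
  any_fib <- rowSums(fibm >= positive_min_coverage) > 0
  best <- max.col(fibm, ties.method = "first")  # columns ordered by priority
  tie <- vapply(seq_len(n), function(i) {
    sum(fibm[i, ] == max(fibm[i, ])) > 1
  }, logical(1))
  marker_to_label <- c(CD34 = "adventitial", AOC3 = "alveolar",
                       POSTN = "myofibroblast", ACTA2 = "myofibroblast")
  label <- rep("unclassified", n)
  label[any_fib] <- marker_to_label[fib_markers[best[any_fib]]]
  label[excl] <- "excluded"
  tie[!any_fib | excl] <- FALSE
  out <- data.frame(label = label, tie = tie, stringsAsFactors = FALSE)
  if (!is.null(cells$cell_id)) out <- cbind(cell_id = cells$cell_id, out)
  out
}

#' Marker coverage from a thresholded pseudo-IF channel
#'
#' Optional image path: the fraction of pixels within a cell mask whose
#' channel value reaches the staining threshold (default 7, excluding
#' blush/bleed/non-specific staining).
#'
#' @param channel background-subtracted \code{PifChannel} matrix.
#' @param mask logical matrix marking the cell's pixels.
#' @param threshold staining threshold (default 7).
#' @return Coverage fraction in [0, 1].
#' @export
marker_coverage <- function(channel, mask, threshold = 7) {
  if (!any(mask)) return(0)
  mean(channel[mask] >= threshold)
}
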