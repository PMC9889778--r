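# Batch-effect detection via k-nearest-neighbour overlap z-scores: the
# observed number of a cell's neighbours lying in its own sample group is
# compared with the overlap obtained for randomly sampled cell sets of the
# same size, z = (nOverlap - mean[random overlap]) / sd[random overlap];
# a group is flagged when its median z exceeds the threshold.

#' kNN-overlap batch-effect z-scores
#'
#' For each group g of m cells, the observed per-cell overlap is the number
#' of its k nearest neighbours that are also in g. The null distribution is
#' built from \code{n_random} uniform draws of m cells: for each draw the
#' same per-cell overlap is computed against the drawn set, and the pooled
#' mean and sd of these null overlaps standardize the observed values.
#' A group is flagged when the median of its per-cell z-scores exceeds
#' \code{z_threshold} (default 1.96).
#'
#' @param graph a \code{\link{neighbor_graph}}.
#' @param groups per-cell group labels (e.g. patient_id).
#' @param n_random number of null draws per group size.
#' @param z_threshold flagging threshold on the median z.
#' @param seed integer seed for the null draws.
#' @param null_sets optional list of explicit index vectors to use as the
#'   null draws (overrides \code{n_random}; used for exhaustive enumeration
#'   on small inputs).
#' @return An object of class \code{batch_report}: \code{groups} data.frame
#'   (group_id, n_cells, median_z, flagged), \code{cell_z} named list of
#'   per-cell z-scores, plus the null parameters used.
#' @export
knn_overlap_zscores <- function(graph, groups, n_random = 1000,
                                z_threshold = 1.96, seed = 1,
                                null_sets = NULL) {
  stopifnot(inherits(graph, "neighbor_graph"))
  n <- nrow(graph$idx); k <- graph$k
  if (length(groups) != n) stopf("groups length (%d) != cells (%d)", length(groups), n)
  groups <- as.character(groups)
  levels_g <- sort(unique(groups))
  sizes <- table(groups)
  too_small <- names(sizes)[sizes < k + 1]
  if (length(too_small)) {
    stopf("group '%s' has fewer than k + 1 = %d cells", too_small[1], k + 1)
  }

  nbr <- graph$idx
  overlap_for_set <- function(set_idx) {
    memb <- logical(n); memb[set_idx] <- TRUE
    rowSums(matrix(memb[nbr[set_idx, , drop = FALSE]], nrow = length(set_idx)))
  }

  cell_z <- vector("list", length(levels_g)); names(cell_z) <- levels_g
  med <- numeric(length(levels_g)); flag <- logical(length(levels_g))
  with_seed(seed, {
    # one null per distinct group size (sizes repeat across patients often)
    null_cache <- list()
    for (gi in seq_along(levels_g)) {
      g <- levels_g[gi]
      members <- which(groups == g)
      m <- length(members)
      key <- as.character(m)
      if (!is.null(null_sets)) {
        draws <- null_sets
      } else if (!is.null(null_cache[[key]])) {
        draws <- NULL
      } else {
        draws <- replicate(n_random, sample.int(n, m), simplify = FALSE)
      }
      if (!is.null(draws)) {
        null_overlaps <- unlist(lapply(draws, overlap_for_set))
        null_cache[[key]] <- c(mean(null_overlaps), stats::sd(null_overlaps))
      }
      mu <- null_cache[[key]][1]; sdv <- null_cache[[key]][2]
      obs <- overlap_for_set(members)
      if (!is.finite(sdv) || sdv == 0) {
        warnf("null overlap sd is 0 for group '%s'; z undefined, not flagged", g)
        z <- rep(NA_real_, m)
        med[gi] <- NA_real_; flag[gi] <- FALSE
      } else {
        z <- (obs - mu) / sdv
        med[gi] <- stats::median(z)
        flag[gi] <- med[gi] > z_threshold
      }
      names(z) <- members
      cell_z[[gi]] <- z
    }
  })
  structure(list(
    groups = data.frame(group_id = levels_g, n_cells = as.integer(sizes[levels_g]),
                        median_z = med, flagged = flag, stringsAsFactors = FALSE),
    cell_z = cell_z, n_random = n_random, z_threshold = z_threshold,
    k = k, seed = seed), class = "batch_report")
}

#' @export
print.batch_report <- function(x, ...) {
  cat(sprintf("<batch_report> k = %d, %d groups, %d flagged (median z > %.2f)\n",
              x$k, nrow(x$groups), sum(x$groups$flagged, na.rm = TRUE),
              x$z_threshold))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Write a batch report
#'
#' @param report a \code{batch_report}.
#' @param csv_path per-group CSV path.
#' @param json_path optional JSON summary path.
#' @export
write_batch_report <- function(report, csv_path, json_path = NULL) {
  utils::write.csv(report$groups, csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      k = report$k, n_random = report$n_random,
      z_threshold = report$z_threshold,
      n_groups = nrow(report$groups),
      n_flagged = sum(report$groups$flagged, na.rm = TRUE)),
      json_path, auto_unbox = TRUE)
  }
  invisible(csv_path)
}
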