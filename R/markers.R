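# Sample-level marker discovery: pseudo-sample expression profiles, the
# marker criterion (sample-level average log fold change > 1, adj.P < 0.01,
# expressed by >= 50% of samples), and the clustering-resolution sweep that
# keeps only resolutions at which every cluster retains markers.

#' Pseudo-sample expression profiles
#'
#' Mean log-normalized expression per (sample, cluster) pair; pairs with
#' fewer than \code{min_cells} cells are dropped with a warning.
#'
#' @param expr a \code{\link{cell_matrix}} (requires \code{sample_id}).
#' @param clusters per-cell cluster labels.
#' @param min_cells minimum cells per (sample, cluster) column.
#' @return An object of class \code{sample_profiles}: \code{profiles}
#'   (genes x columns), \code{col_meta} (sample_id, cluster, n_cells).
#' @export
pseudo_sample_profiles <- function(expr, clusters, min_cells = 3) {
  stopifnot(inherits(expr, "cell_matrix"))
  if (!length(clusters)) stopf("empty clustering")
  if (length(clusters) != ncol(expr$counts)) stopf("clusters length mismatch")
  clusters <- as.character(clusters)
  samples <- as.character(expr$cell_meta$sample_id)
  key <- paste(samples, clusters, sep = "|")
  tab <- table(key)
  kept <- names(tab)[tab >= min_cells]
  dropped <- sum(tab < min_cells)
  if (dropped > 0) {
    warnf("%d (sample, cluster) pairs with fewer than %d cells dropped",
          dropped, min_cells)
  }
  if (!length(kept)) stopf("no (sample, cluster) pair has >= %d cells", min_cells)
  prof <- vapply(kept, function(kk) {
    rowMeans(expr$lognorm[, key == kk, drop = FALSE])
  }, numeric(nrow(expr$lognorm)))
  parts <- strsplit(kept, "|", fixed = TRUE)
  col_meta <- data.frame(sample_id = vapply(parts, `[`, character(1), 1),
                         cluster = vapply(parts, `[`, character(1), 2),
                         n_cells = as.integer(tab[kept]),
                         stringsAsFactors = FALSE)
  structure(list(profiles = prof, col_meta = col_meta),
            class = "sample_profiles")
}

# Weighted per-sample collapse of the non-target clusters ("rest" side).
rest_profile <- function(prof, col_meta, sample, target_cluster) {
  cols <- which(col_meta$sample_id == sample & col_meta$cluster != target_cluster)
  if (!length(cols)) return(NULL)
  w <- col_meta$n_cells[cols]
  as.vector(prof[, cols, drop = FALSE] %*% (w / sum(w)))
}

marker_one_contrast <- function(prof, a_cols, b_cols, cluster_label,
                                min_lfc, alpha, min_frac, paired,
                                pair_index = NULL) {
  genes <- rownames(prof)
  A <- prof[, a_cols, drop = FALSE]
  B <- prof[, b_cols, drop = FALSE]
  p <- vapply(seq_along(genes), function(i) {
    if (paired) {
      d <- A[i, pair_index$a] - B[i, pair_index$b]
      if (all(d == 0)) return(1)
      suppressWarnings(stats::wilcox.test(d, exact = FALSE)$p.value)
    } else {
      suppressWarnings(stats::wilcox.test(A[i, ], B[i, ])$p.value)
    }
  }, numeric(1))
  p[is.na(p)] <- 1
  adj_p <- pmin(1, p * length(p))
  lfc <- log2fc_expm1(rowMeans(A), rowMeans(B))
  frac <- rowMeans(A > 0)
  data.frame(gene = genes, cluster = cluster_label, sample_log2fc = lfc,
             p = p, adj_p = adj_p, frac_samples_expressing = frac,
             passes = lfc > min_lfc & adj_p < alpha & frac >= min_frac,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Sample-level marker test
#'
#' Cluster-vs-rest marker discovery or a two-group contrast, computed on
#' pseudo-sample profiles. The default is an unpaired Wilcoxon rank-sum over
#' profile columns; \code{paired = TRUE} switches to a signed-rank test over
#' samples present on both sides. P-values are Bonferroni-adjusted over
#' tested genes within each contrast. A gene passes when its sample-level
#' average log2 fold change exceeds \code{min_lfc}, its adjusted p is below
#' \code{alpha}, and it is expressed (profile value > 0) in at least
#' \code{min_frac} of target-side samples.
#'
#' @param profiles a \code{\link{pseudo_sample_profiles}} result.
#' @param cluster optional cluster subset for cluster-vs-rest mode (default:
#'   all clusters).
#' @param groups optional list \code{list(a = sample_ids, b = sample_ids)}
#'   for a group-vs-group contrast (e.g. tumour vs control) within a single
#'   cluster; requires \code{cluster} of length 1.
#' @param min_lfc,alpha,min_frac the marker criterion thresholds.
#' @param paired use a paired signed-rank test.
#' @return data.frame of marker records (gene, cluster, sample_log2fc, p,
#'   adj_p, frac_samples_expressing, passes).
#' @export
sample_level_markers <- function(profiles, cluster = NULL, groups = NULL,
                                 min_lfc = 1.0, alpha = 0.01, min_frac = 0.5,
                                 paired = FALSE) {
  stopifnot(inherits(profiles, "sample_profiles"))
  prof <- profiles$profiles; cm <- profiles$col_meta
  if (!is.null(groups)) {
    if (is.null(cluster) || length(cluster) != 1) {
      stopf("a group contrast requires a single target cluster")
    }
    a_cols <- which(cm$cluster == cluster & cm$sample_id %in% groups$a)
    b_cols <- which(cm$cluster == cluster & cm$sample_id %in% groups$b)
    if (length(a_cols) < 3 || length(b_cols) < 3) {
      stopf("contrast '%s' needs >= 3 samples per side (got %d vs %d)",
            cluster, length(a_cols), length(b_cols))
    }
    pair_index <- NULL
    if (paired) {
      common <- intersect(cm$sample_id[a_cols], cm$sample_id[b_cols])
      if (length(common) < 3) stopf("contrast '%s': fewer than 3 paired samples", cluster)
      pair_index <- list(a = match(common, cm$sample_id[a_cols]),
                         b = match(common, cm$sample_id[b_cols]))
    }
    return(marker_one_contrast(prof, a_cols, b_cols, cluster,
                               min_lfc, alpha, min_frac, paired, pair_index))
  }
  clusters <- if (is.null(cluster)) sort(unique(cm$cluster)) else as.character(cluster)
  out <- lapply(clusters, function(cl) {
    a_cols <- which(cm$cluster == cl)
    a_samples <- cm$sample_id[a_cols]
    if (paired) {
      rest <- lapply(a_samples, rest_profile, prof = prof, col_meta = cm,
                     target_cluster = cl)
      keep <- !vapply(rest, is.null, logical(1))
      if (sum(keep) < 3) stopf("contrast '%s': fewer than 3 paired samples", cl)
      B <- do.call(cbind, rest[keep])
      A <- prof[, a_cols[keep], drop = FALSE]
      genes <- rownames(A)
      p <- vapply(seq_along(genes), function(i) {
        d <- A[i, ] - B[i, ]
        if (all(d == 0)) return(1)
        suppressWarnings(stats::wilcox.test(d, exact = FALSE)$p.value)
      }, numeric(1))
      p[is.na(p)] <- 1
      adj_p <- pmin(1, p * length(p))
      lfc <- log2fc_expm1(rowMeans(A), rowMeans(B))
      frac <- rowMeans(A > 0)
      data.frame(gene = genes, cluster = cl, sample_log2fc = lfc, p = p,
                 adj_p = adj_p, frac_samples_expressing = frac,
                 passes = lfc > min_lfc & adj_p < alpha & frac >= min_frac,
                 stringsAsFactors = FALSE, row.names = NULL)
    } else {
      b_cols <- which(cm$cluster != cl)
      if (length(unique(a_samples)) < 3 || length(unique(cm$sample_id[b_cols])) < 3) {
        stopf("contrast '%s' needs >= 3 samples per side", cl)
      }
      marker_one_contrast(prof, a_cols, b_cols, cl, min_lfc, alpha, min_frac,
                          paired = FALSE)
    }
  })
  do.call(rbind, out)
}

#' Write a marker table as TSV
#'
#' @param markers data.frame from \code{\link{sample_level_markers}}.
#' @param path output TSV path.
#' @export
write_marker_tsv <- function(markers, path) {
  utils::write.table(markers, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Leiden partition of the SNN graph at one resolution, clusters relabelled
# 1..K by decreasing size (ties by lowest original index).
cluster_snn <- function(snn, resolution, seed = 1) {
  memb <- with_seed(seed, {
    igraph::cluster_leiden(snn, objective_function = "modularity",
                           resolution = resolution,
                           n_iterations = 5)$membership
  })
  sizes <- table(memb)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  relab <- match(as.character(memb), names(sizes)[ord])
  relab
}

#' Clustering-resolution sweep guarded by the marker criterion
#'
#' Partitions the shared-nearest-neighbour graph by modularity optimisation
#' at each resolution and counts, per cluster, the markers passing the
#' sample-level criterion. A resolution is supported when every cluster has
#' at least \code{marker_min} passing markers; the chosen resolution is the
#' largest supported one (over-clustering yields clusters with no or very
#' few markers and is rejected).
#'
#' @param expr a \code{\link{cell_matrix}}.
#' @param graph a \code{\link{neighbor_graph}} on the same cells.
#' @param resolutions ascending numeric vector of resolution parameters.
#' @param marker_min minimum passing markers per cluster.
#' @param min_lfc,alpha,min_frac marker criterion (see
#'   \code{\link{sample_level_markers}}).
#' @param paired paired test switch, passed through.
#' @param min_cells per (sample, cluster) profile floor.
#' @param seed integer seed for modularity optimisation.
#' @return An object of class \code{resolution_sweep}: \code{table}
#'   (resolution, n_clusters, min_markers, all_clusters_supported),
#'   \code{chosen_resolution}, \code{memberships} (list of per-resolution
#'   cluster vectors), \code{marker_counts} (list of per-cluster counts).
#' @export
resolution_sweep <- function(expr, graph, resolutions, marker_min = 1,
                             min_lfc = 1.0, alpha = 0.01, min_frac = 0.5,
                             paired = FALSE, min_cells = 3, seed = 1) {
  stopifnot(inherits(expr, "cell_matrix"), inherits(graph, "neighbor_graph"))
  if (is.unsorted(resolutions)) stopf("resolutions must be sorted ascending")
  snn <- snn_igraph(graph)
  n_comp <- igraph::components(snn)$no
  if (n_comp > nrow(graph$idx) / 10) {
    warnf("SNN graph splits into %d components; clustering may be unstable", n_comp)
  }
  rows <- list(); memberships <- list(); marker_counts <- list()
  for (r in resolutions) {
    memb <- cluster_snn(snn, r, seed = seed)
    k <- length(unique(memb))
    counts <- integer(k); names(counts) <- as.character(seq_len(k))
    supported <- TRUE
    prof <- suppressWarnings(pseudo_sample_profiles(expr, memb, min_cells = min_cells))
    for (cl in seq_len(k)) {
      cnt <- tryCatch({
        mk <- sample_level_markers(prof, cluster = as.character(cl),
                                   min_lfc = min_lfc, alpha = alpha,
                                   min_frac = min_frac, paired = paired)
        sum(mk$passes)
      }, error = function(e) 0L)
      counts[cl] <- cnt
      if (cnt < marker_min) supported <- FALSE
    }
    if (k == 1) supported <- TRUE  # a single cluster has no contrast to fail
    rows[[length(rows) + 1]] <- data.frame(
      resolution = r, n_clusters = k,
      min_markers = if (k == 1) NA_integer_ else min(counts),
      all_clusters_supported = supported)
    memberships[[as.character(r)]] <- memb
    marker_counts[[as.character(r)]] <- counts
  }
  tab <- do.call(rbind, rows)
  supported_res <- tab$resolution[tab$all_clusters_supported]
  chosen <- if (length(supported_res)) max(supported_res) else NA_real_
  structure(list(table = tab, chosen_resolution = chosen,
                 memberships = memberships, marker_counts = marker_counts),
            class = "resolution_sweep")
}

#' @export
print.resolution_sweep <- function(x, ...) {
  cat("<resolution_sweep>\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("chosen resolution: %s\n", format(x$chosen_resolution)))
  invisible(x)
}
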