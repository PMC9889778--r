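# Diffusion-map pseudotime and cross-dataset trajectory meta-analysis:
# adaptive-kernel diffusion map, diffusion pseudotime with tip-based branch
# assignment, loess pseudotime differential expression, Stouffer combination
# of per-dataset p-values, Ward consensus modules on 1 - r, and
# pseudotime-quintile tissue comparisons.

#' Diffusion-map embedding
#'
#' Gaussian kernel on k-nearest-neighbour distances with adaptive per-cell
#' width (distance to the ceiling(k/2)-th neighbour), density normalization
#' (kernel divided by the product of row sums), row-normalization to a
#' Markov transition matrix, and symmetric eigendecomposition. Components
#' are eigenvectors 2..n_comps+1 scaled by their eigenvalues.
#'
#' @param expr a \code{\link{cell_matrix}} (embedded on top principal
#'   components of highly variable genes) or a cells x dims coordinate
#'   matrix used as-is.
#' @param k neighbours for the kernel support.
#' @param n_comps number of diffusion components returned.
#' @param n_pcs principal components used when \code{expr} is a
#'   \code{cell_matrix}.
#' @param n_hvg highly variable genes feeding the PCA (trajectory signal is
#'   typically carried by a minority of genes; see \code{\link{select_hvgs}}).
#' @return An object of class \code{diffusion_embedding}: \code{eigenvalues}
#'   (descending, stationary component excluded), \code{components}
#'   (cells x n_comps), \code{k}, and the transition matrix provenance.
#' @export
diffusion_map <- function(expr, k = 30, n_comps = 10, n_pcs = 10, n_hvg = 200) {
  emb <- if (inherits(expr, "cell_matrix")) pca_embed(expr, n_pcs, n_hvg = n_hvg)
    else as.matrix(expr)
  n <- nrow(emb)
  if (n < n_comps + 2) stopf("need at least n_comps + 2 = %d cells", n_comps + 2)
  nn <- knn_brute(emb, min(k, n - 1))
  sigma <- nn$dist[, ceiling(k / 2)]
  sigma[sigma == 0] <- min(sigma[sigma > 0], 1e-12)
  # symmetric kernel supported on the kNN union (dense; trajectory inputs
  # are at most a few thousand cells)
  i <- rep(seq_len(n), ncol(nn$idx)); j <- as.vector(nn$idx)
  d <- as.vector(nn$dist)
  w <- exp(-d^2 / (sigma[i] * sigma[j]))
  K <- matrix(0, n, n)
  K[cbind(i, j)] <- w
  K <- pmax(K, t(K))
  if (igraph::components(igraph::graph_from_adjacency_matrix(
    K > 0, mode = "undirected"))$no > 1) {
    stopf("kNN kernel graph is disconnected; increase k")
  }
  # density normalization: K_ij / (z_i z_j)
  z <- rowSums(K)
  K <- K / (z %o% z)
  # symmetrized transition operator D^{-1/2} K D^{-1/2}
  dsum <- rowSums(K)
  S <- K / sqrt(dsum %o% dsum)
  eig <- eigen(S, symmetric = TRUE)
  # map back to right eigenvectors of the row-normalized operator
  psi <- eig$vectors / sqrt(dsum)
  # normalize sign and scale per component
  sel <- 2:(n_comps + 1)
  evals <- eig$values[sel]
  comps <- sweep(psi[, sel, drop = FALSE], 2,
                 sqrt(colSums(psi[, sel, drop = FALSE]^2)), "/")
  comps <- sweep(comps, 2, evals, "*")
  rownames(comps) <- rownames(emb)
  structure(list(eigenvalues = evals, components = comps, k = k,
                 kernel = "gaussian-adaptive (sigma = dist to ceil(k/2)-th NN)",
                 n_cells = n),
            class = "diffusion_embedding")
}

#' @export
print.diffusion_embedding <- function(x, ...) {
  cat(sprintf("<diffusion_embedding> %d cells, %d components, k = %d\n",
              x$n_cells, length(x$eigenvalues), x$k))
  cat("eigenvalues:", paste(signif(x$eigenvalues, 4), collapse = " "), "\n")
  invisible(x)
}

#' Diffusion pseudotime with tip-based branch assignment
#'
#' Pseudotime is the Euclidean distance from the root cell in the space of
#' diffusion components rescaled by lambda/(1 - lambda), min-max normalized
#' to [0, 1]. Branches are assigned by proximity to automatically selected
#' tip cells: tips are chosen by farthest-point sampling in the rescaled
#' diffusion space starting from the cell farthest from the root, and every
#' cell joins the branch of its nearest tip. This tip-proximity rule is a
#' simplified stand-in for full DPT branch triangulation.
#'
#' When expression data is supplied, the tip assignment is refined by a
#' seeded expression contrast: the half of each branch's cells closest to
#' their own tip serve as high-confidence seeds, the genes best separating
#' each pair of seed sets define a contrast score, and every cell is
#' re-assigned by majority vote over the pairwise contrasts. This learns the
#' branch-identity genes from the data and recovers cells whose position in
#' diffusion space is ambiguous.
#'
#' @param emb a \code{\link{diffusion_map}} result.
#' @param root root cell (index or cell name).
#' @param n_branches number of tips/branches.
#' @param expr optional \code{\link{cell_matrix}} (or log-normalized
#'   genes x cells matrix) on the same cells, enabling contrast refinement
#'   of the branch labels.
#' @param n_contrast_genes genes per pairwise contrast in the refinement.
#' @return An object of class \code{pseudotime_assignment}: \code{dpt} in
#'   [0, 1] (0 at the root), \code{branch} labels \code{branch1..n},
#'   \code{root}, \code{tips}.
#' @export
diffusion_pseudotime <- function(emb, root, n_branches = 3, expr = NULL,
                                 n_contrast_genes = 100) {
  stopifnot(inherits(emb, "diffusion_embedding"))
  comps <- emb$components
  n <- nrow(comps)
  if (n_branches > n) stopf("n_branches exceeds number of cells")
  if (is.character(root)) root <- match(root, rownames(comps))
  if (is.na(root) || root < 1 || root > n) stopf("invalid root cell")
  lam <- emb$eigenvalues
  space <- sweep(comps, 2, lam / (1 - lam) / lam, "*")  # components carry a
  # lambda factor already; the net per-component scale is lambda/(1-lambda)
  dist_from <- function(i) {
    sqrt(rowSums(sweep(space, 2, space[i, ], "-")^2))
  }
  d_root <- dist_from(root)
  dpt <- d_root / max(d_root)
  # farthest-point tips
  tips <- integer(n_branches)
  tips[1] <- which.max(d_root)
  if (n_branches > 1) {
    mind <- dist_from(tips[1])
    for (b in 2:n_branches) {
      tips[b] <- which.max(pmin(mind, d_root))
      if (b < n_branches) mind <- pmin(mind, dist_from(tips[b]))
    }
  }
  tip_d <- vapply(tips, dist_from, numeric(n))
  memb <- max.col(-tip_d, ties.method = "first")
  if (!is.null(expr) && n_branches > 1) {
    ln <- if (inherits(expr, "cell_matrix")) expr$lognorm else as.matrix(expr)
    if (ncol(ln) != n) stopf("expr has %d cells; embedding has %d", ncol(ln), n)
    # high-confidence seeds: cells close to their assigned tip (cells near a
    # convergence point are far from every tip and are excluded)
    own_d <- tip_d[cbind(seq_len(n), memb)]
    close <- own_d <= stats::quantile(own_d, 0.6)
    seeds <- lapply(seq_len(n_branches), function(b) which(close & memb == b))
    if (all(lengths(seeds) >= 5)) {
      votes <- matrix(0L, n, n_branches)
      for (a in seq_len(n_branches - 1)) {
        for (b in (a + 1):n_branches) {
          contrast <- rowMeans(ln[, seeds[[a]], drop = FALSE]) -
            rowMeans(ln[, seeds[[b]], drop = FALSE])
          top <- order(-abs(contrast))[seq_len(min(n_contrast_genes,
                                                   nrow(ln)))]
          sc <- as.vector(crossprod(ln[top, , drop = FALSE], contrast[top]))
          thr <- (mean(sc[seeds[[a]]]) + mean(sc[seeds[[b]]])) / 2
          votes[cbind(seq_len(n), ifelse(sc > thr, a, b))] <-
            votes[cbind(seq_len(n), ifelse(sc > thr, a, b))] + 1L
        }
      }
      best <- apply(votes, 1, function(v) {
        w <- which(v == max(v))
        if (length(w) == 1) w else NA_integer_
      })
      memb <- ifelse(is.na(best), memb, best)  # vote ties keep tip label
    }
  }
  branch <- paste0("branch", memb)
  structure(list(dpt = stats::setNames(dpt, rownames(comps)),
                 branch = stats::setNames(branch, rownames(comps)),
                 root = root, tips = tips),
            class = "pseudotime_assignment")
}

#' Pseudotime differential expression by local regression
#'
#' Per gene, a loess fit of log-normalized expression on pseudotime
#' (degree 2, tricube weights) is compared with an intercept-only fit by the
#' approximate F-test of local-regression analysis of variance (using the
#' smoother's effective degrees of freedom). Fitted profiles are evaluated
#' on a fixed 100-point pseudotime grid.
#'
#' @param expr a \code{\link{cell_matrix}}.
#' @param pt a \code{\link{pseudotime_assignment}} (or numeric pseudotime
#'   vector in [0, 1]).
#' @param span loess span.
#' @param genes optional gene subset.
#' @param cells optional cell subset (e.g. one branch path); at least 50
#'   cells required.
#' @return An object of class \code{pseudotime_fit}: data.frame \code{table}
#'   (gene, p) and matrix \code{profiles} (genes x 100 grid points), plus
#'   \code{grid} and \code{span}.
#' @export
pseudotime_de <- function(expr, pt, span = 0.5, genes = NULL, cells = NULL) {
  stopifnot(inherits(expr, "cell_matrix"))
  t_all <- if (inherits(pt, "pseudotime_assignment")) pt$dpt else pt
  if (is.null(cells)) cells <- seq_len(ncol(expr$counts))
  tt <- t_all[cells]
  if (length(tt) < 50) stopf("need >= 50 cells on the analysed path (got %d)", length(tt))
  if (is.null(genes)) genes <- expr$genes
  grid <- seq(min(tt), max(tt), length.out = 100)
  Y <- expr$lognorm[genes, cells, drop = FALSE]
  p <- numeric(length(genes)); prof <- matrix(NA_real_, length(genes), 100)
  for (gi in seq_along(genes)) {
    y <- Y[gi, ]
    if (stats::var(y) == 0) {
      p[gi] <- 1
      prof[gi, ] <- rep(mean(y), 100)
      next
    }
    fit <- stats::loess(y ~ tt, span = span, degree = 2,
                        family = "gaussian",
                        control = stats::loess.control(surface = "direct"))
    # approximate F-test vs the intercept-only model using the smoother's
    # effective degrees of freedom (one-delta / two-delta corrections)
    rss1 <- sum(fit$residuals^2)
    rss0 <- sum((y - mean(y))^2)
    nu1 <- fit$one.delta; nu2 <- fit$two.delta
    df_model <- fit$trace.hat - 1
    Fstat <- ((rss0 - rss1) / df_model) / (rss1 / nu1)
    p[gi] <- if (df_model <= 0 || rss1 <= 0) 1 else
      stats::pf(Fstat, df_model, nu1^2 / nu2, lower.tail = FALSE)
    prof[gi, ] <- stats::predict(fit, newdata = data.frame(tt = grid))
  }
  rownames(prof) <- genes
  structure(list(table = data.frame(gene = genes, p = p,
                                    stringsAsFactors = FALSE),
                 profiles = prof, grid = grid, span = span),
            class = "pseudotime_fit")
}

#' Stouffer meta-analysis of per-dataset p-values
#'
#' Per gene, z_d = qnorm(1 - p_d) over the datasets where the gene was
#' testable, Z = sum(z_d) / sqrt(D), meta_p = 1 - pnorm(Z), Bonferroni
#' adjustment over genes. A gene is significant when its adjusted meta-p is
#' below \code{adj_threshold} and it is nominally significant
#' (p < \code{nominal_threshold}) in at least \code{min_nominal} datasets.
#'
#' @param p_by_dataset genes x datasets matrix of p-values in (0, 1]; NA
#'   marks a gene untestable in a dataset.
#' @param adj_threshold adjusted meta-p threshold (default 1e-10).
#' @param nominal_threshold per-dataset nominal threshold (default 0.05).
#' @param min_nominal minimum nominally significant datasets (default 3).
#' @return data.frame (gene, meta_p, adj_meta_p, n_nominal, significant).
#' @export
stouffer_meta <- function(p_by_dataset, adj_threshold = 1e-10,
                          nominal_threshold = 0.05, min_nominal = 3) {
  p_by_dataset <- as.matrix(p_by_dataset)
  if (!ncol(p_by_dataset)) stopf("need at least one dataset column")
  if (any(p_by_dataset <= 0, na.rm = TRUE)) {
    warnf("p-values of 0 clamped to the smallest representable positive value")
    p_by_dataset[p_by_dataset <= 0] <- .Machine$double.xmin
  }
  if (any(p_by_dataset > 1, na.rm = TRUE)) stopf("p-values must be <= 1")
  z <- stats::qnorm(1 - p_by_dataset)
  # qnorm(1 - p) loses precision for tiny p; use the upper-tail form
  tiny <- !is.na(p_by_dataset) & p_by_dataset < 1e-8
  z[tiny] <- stats::qnorm(p_by_dataset[tiny], lower.tail = FALSE)
  D <- rowSums(!is.na(p_by_dataset))
  Z <- rowSums(z, na.rm = TRUE) / sqrt(pmax(D, 1))
  meta_p <- stats::pnorm(Z, lower.tail = FALSE)
  adj <- pmin(1, meta_p * nrow(p_by_dataset))
  n_nom <- rowSums(p_by_dataset < nominal_threshold, na.rm = TRUE)
  genes <- rownames(p_by_dataset)
  if (is.null(genes)) genes <- sprintf("gene%d", seq_len(nrow(p_by_dataset)))
  data.frame(gene = genes, meta_p = meta_p, adj_meta_p = adj,
             n_nominal = n_nom,
             significant = adj < adj_threshold & n_nom >= min_nominal,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Consensus pseudotime modules across datasets
#'
#' Each gene's fitted pseudotime profile is z-scaled within each dataset,
#' the pointwise median across datasets is taken, genes are correlated
#' (Pearson r) on these median profiles, and Ward agglomeration on the
#' distance 1 - r is cut into \code{k_modules} modules. Modules are named by
#' the pseudotime position of their mean profile's peak (ascending:
#' progenitor, early-activation, proto-differentiation, differentiation for
#' k = 4; otherwise module1..k in peak order).
#'
#' @param fits list of \code{\link{pseudotime_de}} results (one per dataset).
#' @param significant_genes character vector of genes to cluster (typically
#'   the significant genes of \code{\link{stouffer_meta}}).
#' @param k_modules number of modules (default 4).
#' @return An object of class \code{module_assignment}: \code{modules}
#'   (named per-gene module label), \code{module_index}, \code{profiles}
#'   (median consensus profiles), \code{hclust}, \code{peak_order}.
#' @export
consensus_modules <- function(fits, significant_genes, k_modules = 4) {
  if (length(significant_genes) < k_modules) {
    stopf("fewer significant genes (%d) than requested modules (%d)",
          length(significant_genes), k_modules)
  }
  zscale <- function(m) {
    mu <- rowMeans(m); sdv <- apply(m, 1, stats::sd)
    sdv[sdv == 0] <- 1
    (m - mu) / sdv
  }
  scaled <- lapply(fits, function(f) {
    present <- intersect(significant_genes, rownames(f$profiles))
    zscale(f$profiles[present, , drop = FALSE])
  })
  med <- matrix(NA_real_, length(significant_genes), 100,
                dimnames = list(significant_genes, NULL))
  for (g in significant_genes) {
    rows <- lapply(scaled, function(m) if (g %in% rownames(m)) m[g, ] else NULL)
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows)) stopf("gene '%s' has no fitted profile in any dataset", g)
    med[g, ] <- apply(do.call(rbind, rows), 2, stats::median)
  }
  r <- suppressWarnings(stats::cor(t(med)))
  r[is.na(r)] <- 0
  d <- stats::as.dist(1 - r)
  if (all(d < 1e-12)) {
    warnf("degenerate distance matrix (all profiles identical); forcing singleton split")
    idx <- c(seq_len(k_modules - 1), rep(k_modules, length(significant_genes) - k_modules + 1))
    hc <- NULL
  } else {
    hc <- stats::hclust(d, method = "ward.D2")
    idx <- stats::cutree(hc, k = k_modules)
  }
  # order modules by peak position of their mean consensus profile
  peaks <- vapply(seq_len(k_modules), function(m) {
    which.max(colMeans(med[idx == m, , drop = FALSE]))
  }, numeric(1))
  ord <- order(peaks)
  default_names <- c("progenitor", "early-activation",
                     "proto-differentiation", "differentiation")
  mod_names <- if (k_modules == 4) default_names else
    sprintf("module%d", seq_len(k_modules))
  renum <- match(idx, ord)
  structure(list(modules = stats::setNames(mod_names[renum], significant_genes),
                 module_index = stats::setNames(renum, significant_genes),
                 profiles = med, hclust = hc,
                 peak_order = peaks[ord]),
            class = "module_assignment")
}

#' Pseudotime-quintile module comparison between tissue types
#'
#' Cells are binned into five groups at the global pseudotime quintiles;
#' per (sample, quintile) mean module scores are compared between tumour and
#' control samples with a two-sided Wilcoxon rank-sum test per quintile.
#'
#' @param scores per-cell module score vector.
#' @param pt a \code{\link{pseudotime_assignment}} or numeric pseudotime.
#' @param tissue per-cell tissue labels; values containing "control" form
#'   the control side, everything else the tumour side.
#' @param sample_id per-cell sample labels.
#' @param min_samples minimum samples per side per quintile.
#' @return An object of class \code{quintile_comparison}: \code{sample_means}
#'   (sample, quintile, tissue, mean_score) and \code{tests} (quintile, p).
#' @export
quintile_module_comparison <- function(scores, pt, tissue, sample_id,
                                       min_samples = 3) {
  dpt <- if (inherits(pt, "pseudotime_assignment")) pt$dpt else pt
  stopifnot(length(scores) == length(dpt), length(tissue) == length(dpt),
            length(sample_id) == length(dpt))
  qs <- stats::quantile(dpt, probs = seq(0, 1, by = 0.2))
  quint <- cut(dpt, breaks = unique(qs), include.lowest = TRUE,
               labels = FALSE)
  side <- ifelse(grepl("control", tissue, ignore.case = TRUE),
                 "control", "tumour")
  agg <- stats::aggregate(scores,
                          by = list(sample = sample_id, quintile = quint,
                                    tissue = side),
                          FUN = mean)
  names(agg)[4] <- "mean_score"
  tests <- data.frame(quintile = sort(unique(quint)), p = NA_real_)
  for (i in seq_len(nrow(tests))) {
    q <- tests$quintile[i]
    a <- agg$mean_score[agg$quintile == q & agg$tissue == "tumour"]
    b <- agg$mean_score[agg$quintile == q & agg$tissue == "control"]
    if (length(a) < min_samples || length(b) < min_samples) {
      warnf("quintile %d has fewer than %d samples on one side; p = NA", q, min_samples)
      next
    }
    tests$p[i] <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
  }
  structure(list(sample_means = agg, tests = tests),
            class = "quintile_comparison")
}
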