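# Diffusion map, diffusion pseudotime, loess pseudotime DE, Stouffer
# meta-analysis, Ward consensus modules and quintile comparisons.

test_that("diffusion map matches a dense brute-force eigendecomposition", {
  set.seed(3)
  emb <- matrix(rnorm(50 * 4), 50, 4)
  dm <- diffusion_map(emb, k = 10, n_comps = 5)

  # independent dense construction of the same transition operator
  n <- 50
  d <- as.matrix(dist(emb))
  nn_d <- apply(d, 1, function(r) sort(r[r > 0])[1:10])
  sigma <- apply(d, 1, function(r) sort(r[r > 0])[5])  # ceil(10/2)-th NN
  K <- matrix(0, n, n)
  for (i in 1:n) {
    nb <- order(d[i, ])[2:11]
    K[i, nb] <- exp(-d[i, nb]^2 / (sigma[i] * sigma[nb]))
  }
  K <- pmax(K, t(K))
  z <- rowSums(K); K <- K / (z %o% z)
  ds <- rowSums(K); S <- K / sqrt(ds %o% ds)
  eig <- eigen(S, symmetric = TRUE)
  expect_equal(dm$eigenvalues, eig$values[2:6], tolerance = 1e-8)
  psi <- eig$vectors / sqrt(ds)
  for (j in 1:5) {
    ref <- psi[, j + 1] / sqrt(sum(psi[, j + 1]^2)) * eig$values[j + 1]
    # eigenvector sign is arbitrary
    expect_lt(min(max(abs(dm$components[, j] - ref)),
                  max(abs(dm$components[, j] + ref))), 1e-8)
  }
})

test_that("the first diffusion component recovers a 1-D manifold", {
  pos <- seq(0, 1, length.out = 80)
  emb <- cbind(pos, 0)
  dm <- diffusion_map(emb, k = 10, n_comps = 3)
  expect_equal(abs(cor(dm$components[, 1], pos, method = "spearman")), 1)
})

test_that("pseudotime starts at zero and orders a planted trajectory", {
  cm <- cached("traj_single", function() {
    generate_trajectory_dataset(trajectory_config(
      n_cells = 500, n_datasets = 1,
      branch_spec = list(branchA = list(genes = 40, log2fc = 2)),
      seed = 11))[[1]]
  })
  tt <- cm$cell_meta$true_pseudotime
  dm <- diffusion_map(cm, k = 15)
  pt <- diffusion_pseudotime(dm, root = which.min(tt), n_branches = 1)
  expect_equal(unname(pt$dpt[which.min(tt)]), 0)
  expect_true(all(pt$dpt >= 0 & pt$dpt <= 1))
  expect_gte(cor(pt$dpt, tt, method = "spearman"), 0.9)
  expect_error(diffusion_pseudotime(dm, root = which.min(tt),
                                    n_branches = 10000), "exceeds")
})

test_that("dpt is invariant to global scaling of the expression input", {
  cm <- cached("traj_single", function() {
    generate_trajectory_dataset(trajectory_config(
      n_cells = 500, n_datasets = 1,
      branch_spec = list(branchA = list(genes = 40, log2fc = 2)),
      seed = 11))[[1]]
  })
  emb <- pca_embed(cm, 10, n_hvg = 200)
  pt1 <- diffusion_pseudotime(diffusion_map(emb, k = 15), root = 1,
                              n_branches = 1)
  pt2 <- diffusion_pseudotime(diffusion_map(emb * 7, k = 15), root = 1,
                              n_branches = 1)
  expect_equal(pt1$dpt, pt2$dpt, tolerance = 1e-8)
})

test_that("branch assignment separates two planted progenitor arms", {
  cm <- cached("traj_bifurc", function() {
    generate_trajectory_dataset(trajectory_config(n_cells = 600,
                                                  n_datasets = 1,
                                                  seed = 4))[[1]]
  })
  tt <- cm$cell_meta$true_pseudotime
  dm <- diffusion_map(cm, k = 30)
  pt <- diffusion_pseudotime(dm, root = which.max(tt), n_branches = 2,
                             expr = cm)
  acc <- mapped_accuracy(pt$branch, cm$cell_meta$true_branch)
  expect_gte(acc, 0.85)
  # refinement only sharpens the purely geometric tip assignment
  pt0 <- diffusion_pseudotime(dm, root = which.max(tt), n_branches = 2)
  expect_gte(acc, mapped_accuracy(pt0$branch, cm$cell_meta$true_branch) - 0.02)
})

test_that("loess pseudotime DE detects strong signals and planted bumps", {
  set.seed(6)
  n <- 200
  tt <- runif(n)
  counts <- matrix(rpois(3 * n, 20), 3, n,
                   dimnames = list(c("lin", "bump", "flat"), NULL))
  counts["lin", ] <- rpois(n, exp(1 + 2 * tt))
  counts["bump", ] <- rpois(n, 5 + 40 * exp(-((tt - 0.45) / 0.07)^2))
  cm <- toy_cell_matrix(counts)
  fit <- pseudotime_de(cm, tt, span = 0.4)
  expect_lt(fit$table$p[fit$table$gene == "lin"], 1e-6)
  prof <- fit$profiles["lin", ]
  # essentially monotone increasing fit
  expect_gte(cor(prof, fit$grid, method = "spearman"), 0.9)
  expect_gt(prof[100], prof[1])
  # the planted bump peaks inside its window
  peak_t <- fit$grid[which.max(fit$profiles["bump", ])]
  expect_gte(peak_t, 0.3); expect_lte(peak_t, 0.6)
  # constant gene: p = 1, flat profile
  counts2 <- counts; counts2["flat", ] <- 7L
  cm2 <- toy_cell_matrix(counts2)
  # a constant count still varies after per-cell normalization; use a truly
  # constant log-normalized row instead
  cm2$lognorm["flat", ] <- 1
  fit2 <- pseudotime_de(cm2, tt, genes = "flat")
  expect_equal(fit2$table$p, 1)
  expect_true(all(fit2$profiles == fit2$profiles[1]))
})

test_that("stouffer meta combines p-values exactly and monotonically", {
  # identity at a single dataset
  expect_equal(stouffer_meta(matrix(0.05, 1))$meta_p, 0.05, tolerance = 1e-12)
  # closed form at D in {2, 5}
  for (D in c(2, 5)) {
    p <- rep(0.01, D)
    m <- stouffer_meta(matrix(p, 1))
    direct <- pnorm(D * qnorm(0.99) / sqrt(D), lower.tail = FALSE)
    expect_equal(m$meta_p, direct, tolerance = 1e-12)
  }
  # counting rule
  m <- stouffer_meta(matrix(c(0.01, 0.01, 0.01, 0.9), 1), min_nominal = 3)
  expect_equal(m$n_nominal, 3)
  m2 <- stouffer_meta(matrix(c(0.01, 0.01, 0.01, NA), 1), min_nominal = 3)
  expect_equal(m2$n_nominal, 3)  # D adapts to observed columns
  expect_lt(m2$meta_p, stouffer_meta(matrix(c(0.01, 0.01, 0.01, 0.5), 1))$meta_p)
  # monotonicity: decreasing any p never increases meta_p
  base <- c(0.2, 0.05, 0.5)
  m_base <- stouffer_meta(matrix(base, 1))$meta_p
  for (j in 1:3) {
    dec <- base; dec[j] <- dec[j] / 2
    expect_lte(stouffer_meta(matrix(dec, 1))$meta_p, m_base)
  }
  # p = 0 clamps with a warning
  expect_warning(stouffer_meta(matrix(c(0, 0.5), 1)), "clamped")
})

test_that("ward module clustering matches a Lance-Williams oracle", {
  set.seed(12)
  # 20 genes with profiles drawn from 3 shapes plus noise
  grid <- seq(0, 1, length.out = 100)
  shapes <- rbind(sin(pi * grid), cos(pi * grid), grid^2)
  prof <- shapes[rep(1:3, length.out = 20), ] + rnorm(2000, 0, 0.05)
  r <- cor(t(prof))
  d <- 1 - r

  # independent Ward (ward.D2) agglomeration via the Lance-Williams update
  lw_ward <- function(d0) {
    n <- nrow(d0)
    D <- d0^2          # ward.D2 operates on squared dissimilarities
    sizes <- rep(1, n)
    active <- 1:n
    merges <- list()
    Dm <- D; diag(Dm) <- Inf
    repeat {
      if (length(active) == 1) break
      sub <- Dm[active, active, drop = FALSE]
      ij <- which(sub == min(sub), arr.ind = TRUE)[1, ]
      a <- active[ij[1]]; b <- active[ij[2]]
      merges[[length(merges) + 1]] <- sort(c(a, b))
      na <- sizes[a]; nb <- sizes[b]
      for (k in setdiff(active, c(a, b))) {
        nk <- sizes[k]
        Dm[a, k] <- Dm[k, a] <-
          ((na + nk) * Dm[a, k] + (nb + nk) * Dm[b, k] - nk * Dm[a, b]) /
          (na + nb + nk)
      }
      sizes[a] <- na + nb
      active <- setdiff(active, b)
    }
    merges
  }
  oracle_merges <- lw_ward(d)
  hc <- hclust(as.dist(d), method = "ward.D2")
  # reconstruct hclust merge leaf sets
  members <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    members[[i]] <- sort(unlist(lapply(hc$merge[i, ], function(x)
      if (x < 0) -x else members[[x]])))
  }
  # oracle: accumulate cluster membership through its merge list
  oracle_members <- list()
  clusters <- as.list(1:20)
  for (m in oracle_merges) {
    ca <- which(vapply(clusters, function(cl) m[1] %in% cl, logical(1)))
    cb <- which(vapply(clusters, function(cl) m[2] %in% cl, logical(1)))
    merged <- sort(unique(c(clusters[[ca]], clusters[[cb]])))
    clusters[[ca]] <- merged
    clusters[[cb]] <- NULL
    oracle_members[[length(oracle_members) + 1]] <- merged
  }
  expect_equal(members, oracle_members)
})

test_that("consensus modules recover planted membership and peak-order names", {
  ds <- cached("traj_3ds", function() {
    generate_trajectory_dataset(trajectory_config(n_cells = 300,
                                                  n_genes = 800,
                                                  n_datasets = 3, seed = 3))
  })
  mg <- attr(ds, "module_genes")
  fits <- lapply(ds, function(cm)
    pseudotime_de(cm, cm$cell_meta$true_pseudotime,
                  genes = unlist(mg, use.names = FALSE)))
  genes <- unlist(mg, use.names = FALSE)
  ma <- consensus_modules(fits, genes, k_modules = 4)
  truth <- rep(names(mg), lengths(mg))
  expect_gte(adjusted_rand_index(ma$module_index, truth), 0.8)
  # peak-order naming is stable under dataset permutation
  ma2 <- consensus_modules(fits[c(3, 1, 2)], genes, k_modules = 4)
  expect_identical(ma$modules, ma2$modules)
  expect_error(consensus_modules(fits, genes[1:2], k_modules = 4), "fewer")
})

test_that("identical profiles degenerate with a warning and forced split", {
  prof <- matrix(rep(sin(seq(0, pi, length.out = 100)), each = 6), 6, 100,
                 byrow = FALSE,
                 dimnames = list(sprintf("g%d", 1:6), NULL))
  fit <- structure(list(table = data.frame(gene = rownames(prof), p = 0),
                        profiles = prof, grid = seq(0, 1, length.out = 100),
                        span = 0.5), class = "pseudotime_fit")
  expect_warning(ma <- consensus_modules(list(fit), rownames(prof),
                                         k_modules = 2), "degenerate")
  expect_equal(length(unique(ma$module_index)), 2)
})

test_that("quintile comparison bins cells evenly and tests per quintile", {
  # 10 cells evenly spread: exactly 2 per quintile
  dpt <- seq(0.05, 0.95, by = 0.1)
  qs <- quantile(dpt, seq(0, 1, 0.2))
  quint <- cut(dpt, unique(qs), include.lowest = TRUE, labels = FALSE)
  expect_true(all(table(quint) == 2))

  set.seed(15)
  n <- 600
  dpt <- runif(n)
  sample_id <- sample(sprintf("s%02d", 1:12), n, replace = TRUE)
  tissue <- ifelse(as.integer(sub("s", "", sample_id)) <= 6, "control", "LUAD")
  score <- rnorm(n)
  # planted tumour-only shift in quintile 3
  q3 <- dpt >= quantile(dpt, 0.4) & dpt < quantile(dpt, 0.6)
  score[q3 & tissue == "LUAD"] <- score[q3 & tissue == "LUAD"] + 3
  qc <- quintile_module_comparison(score, dpt, tissue, sample_id)
  expect_lt(qc$tests$p[3], 0.01)
  expect_true(all(qc$tests$p[-3] > 0.01))
})
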