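# Module scoring, consensus signature derivation, the demarcation rule and
# the centroid-correlation subpopulation classifier.

test_that("module score equals hand-computed set-minus-control means", {
  counts <- matrix(rpois(50, 5), 10, 5,
                   dimnames = list(sprintf("g%02d", 1:10), NULL))
  cm <- toy_cell_matrix(counts)
  set <- gene_set("s", c("g01", "g04", "g07"))
  score <- score_gene_module(cm, set, n_bins = 2, n_ctrl = 2, seed = 42)

  # brute-force oracle: replicate binning and seeded sampling independently
  avg <- rowMeans(cm$lognorm)
  r <- rank(avg, ties.method = "first")
  bin <- ceiling(r * 2 / 10)
  set_idx <- match(set$genes, rownames(counts))
  in_set <- seq_len(10) %in% set_idx
  ctrl <- fibroscape:::with_seed(42, unlist(lapply(set_idx, function(i) {
    cand <- which(bin == bin[i] & !in_set)
    cand[sample.int(length(cand), 2, replace = length(cand) < 2)]
  })))
  expected <- colMeans(cm$lognorm[set_idx, ]) - colMeans(cm$lognorm[ctrl, ])
  expect_equal(unname(score), unname(expected))
})

test_that("module score is zero on a constant matrix", {
  counts <- matrix(3L, 20, 6, dimnames = list(sprintf("g%02d", 1:20), NULL))
  cm <- toy_cell_matrix(counts)
  s <- score_gene_module(cm, gene_set("s", c("g01", "g02")), n_bins = 2,
                         n_ctrl = 5, seed = 1)
  expect_true(all(abs(s) < 1e-12))
})

test_that("module scores are robust to the control-sampling seed", {
  cm <- cached("cohort_sig", function() {
    generate_cohort(cohort_config(n_patients = 4, cells_per_patient = 150,
                                  n_genes = 2000, seed = 17))
  })
  sig <- attr(cm, "signature_genes")
  s1 <- score_gene_module(cm, gene_set("f", sig$fibroblast), seed = 1)
  s2 <- score_gene_module(cm, gene_set("f", sig$fibroblast), seed = 999)
  expect_gte(cor(s1, s2), 0.95)
})

test_that("module score errors on absent or all-covering sets", {
  counts <- matrix(rpois(40, 5), 10, 4,
                   dimnames = list(sprintf("g%02d", 1:10), NULL))
  cm <- toy_cell_matrix(counts)
  expect_error(score_gene_module(cm, gene_set("missing", c("x1", "x2"))),
               "missing")
  expect_error(score_gene_module(cm, gene_set("all", sprintf("g%02d", 1:10))),
               "control")
})

test_that("consensus signature recovers planted markers within a whitelist", {
  cm <- fibmur_cohort()
  sig <- attr(cm, "signature_genes")
  wl <- gene_set("whitelist", c(sig$fibroblast, sig$mural))
  res <- derive_consensus_signature(cm, cm$cell_meta$true_type, wl)
  expect_gte(sum(sig$fibroblast %in% res$fibroblast$genes), 27)
  expect_equal(sum(sig$mural %in% res$fibroblast$genes), 0)
  # returned sets always disjoint
  expect_length(intersect(res$fibroblast$genes, res$mural$genes), 0)
})

test_that("consensus signature handles disjoint whitelists and disabled thresholds", {
  cm <- fibmur_cohort()
  sig <- attr(cm, "signature_genes")
  planted <- c(sig$fibroblast, sig$mural)
  other <- setdiff(cm$genes, planted)[1:20]
  expect_warning(
    res <- derive_consensus_signature(cm, cm$cell_meta$true_type,
                                      gene_set("off", other)),
    "empty")
  # thresholds disabled: whitelist genes with nonzero fold change split by sign
  wl <- gene_set("wl", planted)
  res2 <- derive_consensus_signature(cm, cm$cell_meta$true_type, wl,
                                     alpha = 1 + 1e-9, lfc_min = 0)
  got <- c(res2$fibroblast$genes, res2$mural$genes)
  lfc <- res2$table$log2fc[match(planted, res2$table$gene)]
  expect_setequal(got, planted[lfc != 0])
  expect_error(derive_consensus_signature(
    subset_cells(cm, 1:4), cm$cell_meta$true_type[1:4], wl), "3 cells")
})

test_that("stromal demarcation applies the score-difference rule", {
  expect_equal(classify_stromal(0.5, 0.2), "fibroblast")
  expect_equal(classify_stromal(0.05, 0.0), "unassigned")   # margin not met
  expect_equal(classify_stromal(0.2, 0.5), "mural")
  expect_equal(classify_stromal(-0.5, -0.8), "unassigned")  # floor not met
  expect_error(classify_stromal(c(1, 2), 1), "length")
  # invariance under adding a common constant (rule uses differences and a
  # floor; with floor disabled the labels depend only on the difference)
  fib <- rnorm(50); mur <- rnorm(50)
  l1 <- classify_stromal(fib, mur, floor = -Inf)
  l2 <- classify_stromal(fib + 3, mur + 3, floor = -Inf)
  expect_identical(l1, l2)
})

test_that("demarcation recovers planted fibroblast/mural labels", {
  cm <- demarcation_cohort()
  sig <- attr(cm, "signature_genes")
  fib <- score_gene_module(cm, gene_set("fib", sig$fibroblast), seed = 1)
  mur <- score_gene_module(cm, gene_set("mural", sig$mural), seed = 2)
  lab <- classify_stromal(fib, mur)
  truth <- cm$cell_meta$true_type
  scope <- truth %in% c("fibroblast", "mural")
  expect_gte(mean(lab[scope] == truth[scope]), 0.97)
})

test_that("subpopulation classifier is probabilistic and recovers truth", {
  cm <- cached("cohort_3pop", function() three_pop_cohort())
  idx <- seq_len(ncol(cm$counts))
  ref <- subset_cells(cm, idx %% 2 == 0)
  query <- subset_cells(cm, idx %% 2 == 1)
  pred <- classify_subpopulation(query, ref)
  expect_equal(unname(rowSums(pred$prob)), rep(1, ncol(query$counts)),
               tolerance = 1e-9)
  expect_gte(mean(pred$class == query$cell_meta$true_type), 0.90)
  # temperature -> infinity flattens probabilities
  flat <- classify_subpopulation(query, ref, temperature = 1e9)
  expect_equal(max(abs(flat$prob - 1 / 3)), 0, tolerance = 1e-6)
  # tiny reference class errors
  labs <- ref$cell_meta$true_type
  labs[labs == "alveolar"] <- "adventitial"
  labs[1:2] <- "alveolar"
  expect_error(classify_subpopulation(query, ref, ref_labels = labs),
               "fewer than 3")
})

test_that("identical centroids tie and self-match wins", {
  counts <- matrix(rpois(400, 8), 100, 4,
                   dimnames = list(sprintf("g%03d", 1:100), NULL))
  counts <- cbind(counts, counts[, 1:4], counts[, 1:4])
  ref <- toy_cell_matrix(counts)
  labs <- rep(c("x", "y", "z"), each = 4)  # x and y identical blocks
  q <- toy_cell_matrix(counts[, 1:4, drop = FALSE])
  pred <- classify_subpopulation(q, ref, ref_labels = labs)
  expect_equal(pred$prob[, "x"], pred$prob[, "y"], tolerance = 1e-12)
  expect_gte(min(pred$prob[, "x"] - pred$prob[, "z"] + 1e-12), 0)
})

test_that("gene sets round-trip through text and JSON", {
  dir <- withr::local_tempdir()
  s <- gene_set("markers", c("ACTA2", "POSTN", "CD34"))
  write_gene_sets(s, file.path(dir, "markers.txt"))
  back <- read_gene_sets(file.path(dir, "markers.txt"))
  expect_equal(back$genes, s$genes)
  write_gene_sets(list(s, gene_set("other", "AOC3")),
                  file.path(dir, "sets.json"))
  both <- read_gene_sets(file.path(dir, "sets.json"))
  expect_equal(both$markers$genes, s$genes)
  expect_equal(both$other$genes, "AOC3")
  expect_error(gene_set("dup", c("A", "A")), "duplicates")
})
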