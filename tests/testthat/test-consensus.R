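test_that("trimmed mean matches the sort-and-slice definition", {
  expect_equal(trimmed_mean(c(1, 2, 3, 4), 0.25), 2.5)
  expect_equal(trimmed_mean(rep(7, 9), 0.4), 7)
  x <- rnorm(31)
  expect_equal(trimmed_mean(x, 0), mean(x))
  # base mean() implements the same each-tail convention
  expect_equal(trimmed_mean(x, 0.25), mean(x, trim = 0.25))
  expect_error(trimmed_mean(numeric(0)), "empty")
  expect_error(trimmed_mean(1:4, 0.5), "trim")
})

test_that("pairwise marker panel pools top genes per pair and finds planted markers", {
  cfg <- generator_config(n_types = 2, n_genes = 80, n_cells_per_type = 40,
                          markers_per_type = 5, type_separation = 5,
                          dropout_rate = 0, doublet_rate = 0, seed = 71)
  atlas <- make_reference_atlas(cfg)
  sim <- simulate_cells(atlas, cfg)
  norm <- normalize_expression(sim$counts)
  labels <- data.frame(barcode = sim$truth$barcode,
                       label = sim$truth$true_label)
  panel <- pairwise_marker_panel(norm, labels, top_k = 30)
  expect_lte(length(panel$genes), 30L)  # single pair
  # the ten planted disjoint markers (5 per type) must all be selected
  planted <- sprintf("gene-%04d", 1:10)
  expect_true(all(planted %in% panel$genes))

  # three types: at most 3 * top_k genes after the union
  cfg3 <- tiny_config(seed = 72, doublet_rate = 0)
  sim3 <- simulate_cells(make_reference_atlas(cfg3), cfg3)
  lab3 <- data.frame(barcode = sim3$truth$barcode,
                     label = sim3$truth$true_label)
  panel3 <- pairwise_marker_panel(normalize_expression(sim3$counts), lab3,
                                  top_k = 10)
  expect_lte(length(panel3$genes), 30L)
  expect_setequal(unique(paste(panel3$provenance$type_a,
                               panel3$provenance$type_b)),
                  c("type-01 type-02", "type-01 type-03",
                    "type-02 type-03"))

  # a pair with an undersized type is skipped with a warning
  lab_small <- lab3
  lab_small$label[lab_small$label == "type-03"][-(1:2)] <- "type-01"
  w <- capture_warnings(pairwise_marker_panel(normalize_expression(sim3$counts),
                                              lab_small, top_k = 10))
  expect_match(w, "fewer than 3 cells", all = TRUE)
  expect_length(w, 2L)  # both pairs involving the undersized type
})

test_that("cluster tree cuts are nested from root to singletons and split planted clouds", {
  set.seed(81)
  n_per <- 30
  cloud <- function(center) matrix(rnorm(10 * n_per, center, 0.1),
                                   nrow = 10)
  x <- cbind(cloud(0), cloud(50))
  rownames(x) <- paste0("g", 1:10)
  colnames(x) <- paste0("c", seq_len(2 * n_per))
  tree <- build_cluster_tree(Matrix::Matrix(x, sparse = TRUE),
                             paste0("g", 1:10), k_neighbors = 10)
  expect_equal(unname(cut_tree(tree, 1)), rep(1L, 2 * n_per))
  expect_equal(length(unique(cut_tree(tree, 2 * n_per))), 2 * n_per)
  two <- cut_tree(tree, 2)
  expect_equal(length(unique(two[1:n_per])), 1L)
  expect_equal(length(unique(two[n_per + 1:n_per])), 1L)
  expect_false(two[1] == two[n_per + 1])
  # nestedness: each cluster at k+1 lies inside one cluster at k
  for (k in c(2, 5, 10, 30)) {
    a <- cut_tree(tree, k); b <- cut_tree(tree, k + 1)
    expect_true(all(tapply(a, b, function(v) length(unique(v))) == 1L))
  }
  expect_warning(build_cluster_tree(Matrix::Matrix(x[, 1:5], sparse = TRUE),
                                    paste0("g", 1:10), k_neighbors = 20),
                 "clamped")
})

test_that("consensus walk handles degenerate and well-separated cases", {
  set.seed(91)
  x <- matrix(rnorm(200), nrow = 10,
              dimnames = list(paste0("g", 1:10), paste0("c", 1:20)))
  tree <- build_cluster_tree(Matrix::Matrix(x, sparse = TRUE),
                             paste0("g", 1:10), k_neighbors = 5)
  # single retained type: everything gets it, after exactly patience + 1 cuts
  corr1 <- matrix(runif(20, 0.4, 0.9), 20, 1,
                  dimnames = list(paste0("c", 1:20), "only"))
  res <- consensus_walk(tree, corr1, patience = 10)
  expect_true(all(res$label == "only"))
  expect_equal(attr(res, "iterations"), 11L)

  # patience = 1 stops at the first repeated labeling
  res1 <- consensus_walk(tree, corr1, patience = 1)
  expect_equal(attr(res1, "iterations"), 2L)

  # the walk refuses to run past max_iterations
  corr2 <- matrix(runif(40, -1, 1), 20, 2,
                  dimnames = list(paste0("c", 1:20), c("a", "b")))
  expect_error(consensus_walk(tree, corr2, patience = 50,
                              max_iterations = 3),
               "did not converge")
})

test_that("walk recovers truth on well-separated synthetic types", {
  cfg <- generator_config(n_types = 3, n_genes = 150, n_cells_per_type = 50,
                          markers_per_type = 8, type_separation = 5,
                          dropout_rate = 0, doublet_rate = 0, seed = 101)
  atlas <- make_reference_atlas(cfg)
  sim <- simulate_cells(atlas, cfg)
  norm <- normalize_expression(sim$counts)
  corr <- correlate_cells(norm, atlas)
  pr <- prune_rare_types(corr)
  panel <- pairwise_marker_panel(norm, pr$labels)
  tree <- build_cluster_tree(norm, panel)
  res <- consensus_walk(tree, pr$corr)
  m <- match(res$barcode, sim$truth$barcode)
  expect_true(all(res$label == sim$truth$true_label[m]))
  expect_true(all(res$label %in% colnames(pr$corr)))  # never "ambiguous"
})

test_that("projection keeps sketch labels and labels coincident cells identically", {
  set.seed(111)
  x <- matrix(rnorm(300), nrow = 10,
              dimnames = list(paste0("g", 1:10), paste0("c", 1:30)))
  x[, 21:30] <- x[, 1:10]  # each held-out cell coincides with a sketch cell
  sketch_labels <- data.frame(barcode = paste0("c", 1:20),
                              label = rep(c("t1", "t2"), 10),
                              provenance = "sketch")
  proj <- project_labels(sketch_labels, Matrix::Matrix(x, sparse = TRUE),
                         paste0("g", 1:10), k_neighbors = 1)
  expect_identical(proj$label[1:20], sketch_labels$label)
  expect_identical(proj$provenance,
                   rep(c("sketch", "projected"), c(20, 10)))
  expect_identical(proj$label[21:30], sketch_labels$label[1:10])
})

test_that("projection recovers truth on a half-sketched two-type simulation", {
  cfg <- generator_config(n_types = 2, n_genes = 120, n_cells_per_type = 100,
                          markers_per_type = 8, type_separation = 4,
                          doublet_rate = 0.02, seed = 121)
  atlas <- make_reference_atlas(cfg)
  sim <- simulate_cells(atlas, cfg)
  norm <- normalize_expression(sim$counts)
  sk <- sketch_sample(sim$counts, 100, seed = 2)
  corr <- correlate_cells(norm[, sk], atlas)
  pr <- prune_rare_types(corr)
  panel <- pairwise_marker_panel(norm[, sk], pr$labels)
  tree <- build_cluster_tree(norm[, sk], panel)
  res <- consensus_walk(tree, pr$corr)
  proj <- project_labels(res, norm, panel)
  m <- match(proj$barcode, sim$truth$barcode)
  ok <- !sim$truth$is_doublet[m]
  expect_gte(mean(proj$label[ok] == sim$truth$true_label[m][ok]), 0.95)
})

test_that("condition balancing takes the per-type minimum from each condition", {
  labels <- data.frame(barcode = sprintf("c%03d", 1:40),
                       label = rep(c("T", "M"), c(17, 23)))
  cond <- setNames(rep(c("A", "B", "A", "B"), c(10, 7, 13, 10)),
                   labels$barcode)
  kept <- balance_conditions(labels, cond, c("T", "M"), seed = 3)
  kt <- kept[kept %in% labels$barcode[labels$label == "T"]]
  km <- kept[kept %in% labels$barcode[labels$label == "M"]]
  expect_length(kt, 14L)  # min(10, 7) per condition
  expect_length(km, 20L)  # min(13, 10) per condition
  expect_equal(unname(table(cond[kt])), c(7L, 7L), ignore_attr = TRUE)
  expect_equal(unname(table(cond[km])), c(10L, 10L), ignore_attr = TRUE)
  # equal counts per condition: the type is kept in full
  labels2 <- data.frame(barcode = sprintf("c%03d", 1:40),
                        label = rep(c("T", "M"), c(16, 24)))
  cond2 <- setNames(rep(c("A", "B"), 20), labels2$barcode)
  kept2 <- balance_conditions(labels2, cond2, "T", seed = 3)
  expect_setequal(kept2, labels2$barcode[labels2$label == "T"])
  # absent type is a named error
  expect_error(balance_conditions(labels, setNames(rep("A", 40),
                                                   labels$barcode),
                                  "T", seed = 1), "two conditions")
  cond3 <- cond; cond3[labels$label == "T" & cond == "B"] <- "A"
  expect_error(balance_conditions(labels, cond3, "T", seed = 1),
               "absent in one condition")
})
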