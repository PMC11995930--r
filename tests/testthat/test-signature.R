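test_that("wilcoxon DE reports zero log2FC for identical groups and filters by pct", {
  set.seed(131)
  x <- matrix(rpois(300, 2), nrow = 10,
              dimnames = list(paste0("g", 1:10), paste0("c", 1:30)))
  x <- Matrix::Matrix(x, sparse = TRUE)
  # two disjoint groups with identical values column-for-column
  x[, 16:30] <- x[, 1:15]
  de <- wilcoxon_de(x, 1:15, 16:30, min_frac = 0)
  expect_equal(de$log2_fold_change, rep(0, nrow(de)))
  expect_true(all(de$p_value > 0.9))

  # min.pct-style filter: a gene expressed in 1 of 100 cells per group is
  # dropped at min_frac = 0.05
  y <- Matrix::Matrix(0, nrow = 2, ncol = 200, sparse = TRUE,
                      dimnames = list(c("rare", "common"), paste0("c", 1:200)))
  y["rare", c(1, 101)] <- 1
  y["common", ] <- rpois(200, 3)
  de2 <- wilcoxon_de(y, 1:100, 101:200, min_frac = 0.05)
  expect_false("rare" %in% de2$gene)
  expect_true("common" %in% de2$gene)

  expect_error(wilcoxon_de(x, 1:10, 5:20), "disjoint")
  expect_error(wilcoxon_de(x, 1:2, 3:30), "at least 3 cells")
})

test_that("exact Wilcoxon p-values match enumeration, including the textbook case", {
  # group1 = {5,6,7} vs group2 = {1,2,3}: all group1 ranks on top, exact
  # two-sided p = 2/20
  m <- Matrix::Matrix(matrix(c(5, 6, 7, 1, 2, 3), nrow = 1), sparse = TRUE,
                      dimnames = list("g1", paste0("c", 1:6)))
  de <- wilcoxon_de(m, 1:3, 4:6, min_frac = 0)
  expect_equal(de$p_value, 0.1)

  set.seed(141)
  for (sizes in list(c(3, 3), c(4, 3), c(5, 5), c(4, 6))) {
    for (rep_i in 1:5) {
      v1 <- rnorm(sizes[1]); v2 <- rnorm(sizes[2])
      if (rep_i %% 2 == 0) {  # force ties through integer values
        v1 <- sample(0:2, sizes[1], replace = TRUE)
        v2 <- sample(0:2, sizes[2], replace = TRUE)
      }
      mm <- Matrix::Matrix(matrix(c(v1, v2), nrow = 1), sparse = TRUE,
                           dimnames = list("g",
                                           paste0("c", seq_len(sum(sizes)))))
      de_i <- wilcoxon_de(mm, seq_len(sizes[1]),
                          sizes[1] + seq_len(sizes[2]), min_frac = 0)
      expect_equal(de_i$p_value, oracle_wilcox_p(v1, v2), tolerance = 1e-12)
    }
  }
})

test_that("log2FC ranking is a permutation with documented tie rules", {
  de <- data.frame(gene = c("a", "b", "c"),
                   log2_fold_change = c(2, -1, 0.5),
                   p_value = c(0.1, 0.2, 0.3))
  expect_identical(names(rank_by_log2fc(de)), c("a", "c", "b"))

  tie <- data.frame(gene = c("z", "y", "x"),
                    log2_fold_change = c(1, 1, 1),
                    p_value = c(0.5, 0.1, 0.5))
  expect_identical(names(rank_by_log2fc(tie)), c("y", "x", "z"))
  set.seed(151)
  big <- data.frame(gene = paste0("g", 1:50),
                    log2_fold_change = rnorm(50), p_value = runif(50))
  expect_setequal(names(rank_by_log2fc(big)), big$gene)
})

test_that("GSEA running sum, ES, and leading edge match the weighted-KS definition", {
  ranked <- setNames(c(3, 2, 1, -1, -2), paste0("g", 1:5))
  res <- gsea_preranked(ranked, c("g1", "g2"), n_perm = 100, seed = 1)
  expect_equal(res$running_sum, c(0.6, 1, 2/3, 1/3, 0), tolerance = 1e-12)
  expect_equal(res$es, 1)
  expect_identical(res$leading_edge, c("g1", "g2"))

  # a set at the bottom of a symmetric ranking scores negatively, and its
  # leading edge sits at or after the peak
  res2 <- gsea_preranked(ranked, c("g4", "g5"), n_perm = 100, seed = 1)
  expect_lt(res2$es, 0)
  expect_identical(res2$leading_edge, c("g4", "g5"))

  # determinism under a fixed seed
  res3 <- gsea_preranked(ranked, c("g1", "g2"), n_perm = 100, seed = 1)
  expect_identical(res3$p_value, res$p_value)

  expect_error(gsea_preranked(ranked, c("nope")), "does not intersect")
  expect_error(gsea_preranked(ranked, paste0("g", 1:5)), "whole ranked list")
})

test_that("GSEA ES agrees with an independent implementation on random lists", {
  set.seed(161)
  for (i in 1:10) {
    n <- 60
    scores <- sort(rnorm(n, sd = 2), decreasing = TRUE)
    names(scores) <- paste0("g", 1:n)
    genes <- sample(names(scores), 12)
    ours <- gsea_preranked(scores, genes, n_perm = 10, seed = 1)$es
    ref <- fgsea::calcGseaStat(stats = scores,
                               selectedStats = which(names(scores) %in% genes),
                               gseaParam = 1, scoreType = "std")
    expect_equal(ours, ref, tolerance = 1e-8)
  }
})

test_that("per-cell scores follow max-normalization, core-mean and rescale steps", {
  m <- Matrix::Matrix(matrix(c(2, 6), nrow = 1), sparse = TRUE,
                      dimnames = list("core1", c("lo", "hi")))
  sc <- score_cells(m, "core1")
  expect_equal(unname(sc), c(0, 1))

  set.seed(171)
  x <- matrix(rpois(200, 4) + 1, nrow = 10,
              dimnames = list(paste0("g", 1:10), paste0("c", 1:20)))
  xm <- Matrix::Matrix(x, sparse = TRUE)
  core <- paste0("g", 1:4)
  s1 <- score_cells(xm, core)
  expect_equal(range(s1), c(0, 1))
  # rescale endpoints are the extreme core-mean cells
  means <- colMeans(x[core, ] / apply(x[core, ], 1, max))
  expect_equal(names(which.max(s1)), names(which.max(means)))
  expect_equal(names(which.min(s1)), names(which.min(means)))
  # multiplying a gene row by a positive constant changes nothing
  x2 <- x; x2[2, ] <- x2[2, ] * 13
  expect_equal(s1, score_cells(Matrix::Matrix(x2, sparse = TRUE), core))

  # all-zero core genes are dropped with a warning; empty intersection errors
  x3 <- x; x3[1, ] <- 0
  expect_warning(score_cells(Matrix::Matrix(x3, sparse = TRUE), core),
                 "all-zero")
  expect_error(score_cells(xm, "absent"), "no core genes")

  flat <- Matrix::Matrix(matrix(3, 2, 4), sparse = TRUE,
                         dimnames = list(c("a", "b"), paste0("c", 1:4)))
  expect_warning(s0 <- score_cells(flat, c("a", "b")), "degenerate")
  expect_equal(unname(s0), rep(0, 4))
})

test_that("KS statistic and p-values match ECDF enumeration and ks.test", {
  expect_equal(ks_compare(1:9, 1:9)$D, 0)
  expect_equal(ks_compare(c(0, 0, 0), c(1, 1, 1))$D, 1)
  expect_equal(ks_compare(c(1, 2, 3, 4), c(1.5, 2.5))$D, 0.5)
  expect_error(ks_compare(numeric(0), 1:3), "nonempty")

  set.seed(181)
  for (i in 1:20) {
    a <- rnorm(sample(5:60, 1))
    b <- rnorm(sample(5:60, 1), mean = runif(1, -1, 1))
    if (i %% 3 == 0) { a <- round(a); b <- round(b) }  # ties
    res <- ks_compare(a, b)
    expect_equal(res$D, oracle_ks_D(a, b), tolerance = 1e-12)
    ref <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
    expect_equal(res$D, unname(ref$statistic), tolerance = 1e-12)
    # both asymptotic, but ks.test evaluates its series to ~1e-6
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-3)
  }
  # exact small-sample mode agrees with ks.test's exact computation
  a <- rnorm(8); b <- rnorm(9)
  expect_equal(ks_compare(a, b, exact = TRUE)$p_value,
               stats::ks.test(a, b, exact = TRUE)$p.value, tolerance = 1e-12)
})
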