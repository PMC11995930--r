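#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' For every gene expressed in at least `min_frac` of the cells of either
#' group, reports a two-sided Wilcoxon rank-sum p-value and the log2 fold
#' change of pseudocounted group means (group1 vs group2). Small samples
#' (combined n at most `exact_max_n`) use the exact null distribution
#' (closed form when the pooled values are tie-free, enumeration over group
#' assignments otherwise); larger samples use the normal approximation with
#' tie correction and continuity correction.
#'
#' @param normalized genes x cells matrix of normalized expression.
#' @param group1,group2 disjoint cell selections (indices or barcodes), each
#'   with at least 3 cells.
#' @param min_frac minimum expressed fraction (`min.pct`-style filter,
#'   default 0.05).
#' @param pseudocount added to each group's mean before the log2 ratio
#'   (default 1).
#' @param exact_max_n combined group size at or below which the exact
#'   p-value is computed (default 25).
#' @return data.frame with columns `gene`, `log2_fold_change`, `p_value`,
#'   `pct_1`, `pct_2`.
#' @export
wilcoxon_de <- function(normalized, group1, group2, min_frac = 0.05,
                        pseudocount = 1, exact_max_n = 25L) {
  if (is.character(group1)) group1 <- match(group1, colnames(normalized))
  if (is.character(group2)) group2 <- match(group2, colnames(normalized))
  if (anyNA(group1) || anyNA(group2)) stop("unknown cells in a group")
  if (length(intersect(group1, group2)) > 0L)
    stop("group1 and group2 must be disjoint")
  if (length(group1) < 3L || length(group2) < 3L)
    stop("each group needs at least 3 cells")
  x1 <- as.matrix(normalized[, group1, drop = FALSE])
  x2 <- as.matrix(normalized[, group2, drop = FALSE])
  pct1 <- rowMeans(x1 > 0)
  pct2 <- rowMeans(x2 > 0)
  keep <- pmax(pct1, pct2) >= min_frac
  if (!any(keep)) {
    return(data.frame(gene = character(0), log2_fold_change = numeric(0),
                      p_value = numeric(0), pct_1 = numeric(0),
                      pct_2 = numeric(0), stringsAsFactors = FALSE))
  }
  x1 <- x1[keep, , drop = FALSE]
  x2 <- x2[keep, , drop = FALSE]
  lfc <- log2((rowMeans(x1) + pseudocount) / (rowMeans(x2) + pseudocount))
  n1 <- ncol(x1); n2 <- ncol(x2); n <- n1 + n2
  if (n <= exact_max_n) {
    p <- vapply(seq_len(nrow(x1)), function(g)
      wilcox_exact_p(x1[g, ], x2[g, ]), numeric(1))
  } else {
    p <- wilcox_normal_p(x1, x2)
  }
  data.frame(gene = rownames(x1), log2_fold_change = lfc, p_value = p,
             pct_1 = pct1[keep], pct_2 = pct2[keep],
             stringsAsFactors = FALSE, row.names = NULL)
}

# Vectorized two-sided normal approximation with tie and continuity
# correction; rows are genes.
wilcox_normal_p <- function(x1, x2, continuity = TRUE) {
  n1 <- ncol(x1); n2 <- ncol(x2); n <- n1 + n2
  pooled <- cbind(x1, x2)
  vapply(seq_len(nrow(pooled)), function(g) {
    r <- rank(pooled[g, ])
    w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    ties <- table(pooled[g, ])
    sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) return(1)
    z <- w - mu
    if (continuity) z <- z - sign(z) * 0.5
    min(1, 2 * pnorm(-abs(z) / sqrt(sig2)))
  }, numeric(1))
}

# Exact two-sided rank-sum p-value: 2 * min(P(W <= w), P(W >= w)) capped at
# 1, under the permutation distribution of group assignments given the
# pooled values. Tie-free: closed form via pwilcox. Ties: enumeration over
# assignments (capped; falls back to the normal approximation beyond it).
wilcox_exact_p <- function(v1, v2, max_combinations = 1e5) {
  n1 <- length(v1); n2 <- length(v2); n <- n1 + n2
  pooled <- c(v1, v2)
  r <- rank(pooled)
  w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (!anyDuplicated(pooled)) {
    p_le <- pwilcox(w, n1, n2)
    p_ge <- 1 - pwilcox(w - 1, n1, n2)
    return(min(1, 2 * min(p_le, p_ge)))
  }
  if (choose(n, n1) > max_combinations) {
    warning("too many tied-assignment combinations for exact mode; ",
            "using normal approximation")
    return(wilcox_normal_p(matrix(v1, 1), matrix(v2, 1)))
  }
  combos <- combn(n, n1)
  offset <- n1 * (n1 + 1) / 2
  ws <- colSums(matrix(r[combos], nrow = n1)) - offset
  p_le <- mean(ws <= w)
  p_ge <- mean(ws >= w)
  min(1, 2 * min(p_le, p_ge))
}

#' Rank genes by descending log2 fold-change
#'
#' Orders a [wilcoxon_de()] result from most up- to most down-regulated:
#' log2 fold-change descending, ties broken by p-value ascending, then gene
#' name. The result is the preranked input for [gsea_preranked()].
#'
#' @param de data.frame from [wilcoxon_de()].
#' @return Named numeric vector of log2 fold-changes, names are genes, in
#'   rank order.
#' @export
rank_by_log2fc <- function(de) {
  if (nrow(de) == 0L) stop("empty differential-expression result")
  ord <- order(-de$log2_fold_change, de$p_value, de$gene)
  setNames(de$log2_fold_change[ord], de$gene[ord])
}

#' Preranked gene-set enrichment with leading-edge extraction
#'
#' Classic weighted Kolmogorov–Smirnov running statistic over a ranked gene
#' list: at an in-set gene ("hit") the running sum increases by
#' `|score|^weight` normalized over the in-set genes; at a miss it decreases
#' by `1/(N - Nh)`. The enrichment score (ES) is the running-sum value of
#' maximal absolute deviation from zero. The leading edge (core enrichment
#' genes) comprises the in-set genes at or before the peak for a positive
#' ES, or at or after it for a negative ES. The permutation p-value
#' randomizes which positions of the ranked list are in-set (gene-label
#' permutation) and is one-sided on the observed sign, with the +1
#' correction.
#'
#' @param ranked named numeric vector of ranking scores, in descending rank
#'   order (e.g. from [rank_by_log2fc()]).
#' @param set a gene set: character vector, or a `gene_set` from
#'   [read_gmt()].
#' @param weight exponent on `|score|` for hit increments (default 1; 0
#'   gives the unweighted KS statistic).
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed for the permutations.
#' @return A `gsea_result`: list with `es`, `p_value`, `leading_edge`,
#'   `running_sum` (per position), `n_hits` and `set_name`.
#' @export
gsea_preranked <- function(ranked, set, weight = 1, n_perm = 1000L,
                           seed = 1L) {
  set_name <- if (inherits(set, "gene_set")) set$name else "gene_set"
  genes_in_set <- if (inherits(set, "gene_set")) set$genes else set
  genes <- names(ranked)
  if (is.null(genes)) stop("'ranked' must be named by gene")
  hits <- genes %in% genes_in_set
  nh <- sum(hits)
  if (nh == 0L) stop("gene set does not intersect the ranked list")
  if (nh == length(genes))
    stop("gene set covers the whole ranked list; miss penalty undefined")
  wts <- abs(ranked)^weight
  rs <- gsea_running_sum(wts, hits)
  peak <- running_sum_peak(rs)
  es <- rs[peak]
  le <- if (es >= 0) genes[hits & seq_along(genes) <= peak]
        else genes[hits & seq_along(genes) >= peak]
  perm_es <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_perm), function(i) {
      h <- logical(length(genes))
      h[sample.int(length(genes), nh)] <- TRUE
      r <- gsea_running_sum(wts, h)
      r[running_sum_peak(r)]
    }, numeric(1))
  })
  p <- if (es >= 0) (1 + sum(perm_es >= es)) / (n_perm + 1)
       else (1 + sum(perm_es <= es)) / (n_perm + 1)
  structure(list(es = es, p_value = p, leading_edge = le,
                 running_sum = rs, n_hits = nh, set_name = set_name),
            class = "gsea_result")
}

# First position whose |running sum| is within floating-point tolerance of
# the maximal deviation; keeps the peak (and the ES sign at exact +/- ties)
# independent of cumsum rounding order.
running_sum_peak <- function(rs) {
  a <- abs(rs)
  m <- max(a)
  which(a >= m - 1e-9 * max(1, m))[1L]
}

gsea_running_sum <- function(wts, hits) {
  hit_total <- sum(wts[hits])
  inc <- if (hit_total > 0) wts / hit_total else
    rep(1 / sum(hits), length(wts))  # all-zero scores: unweighted steps
  step <- ifelse(hits, inc, -1 / (length(hits) - sum(hits)))
  cumsum(step)
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("gsea_result '%s': ES = %.3f, p = %.4g, leading edge %d/%d genes\n",
              x$set_name, x$es, x$p_value, length(x$leading_edge), x$n_hits))
  invisible(x)
}

#' Per-cell gene-signature scores
#'
#' Three steps: (1) every gene's expression is normalized by its maximal
#' value over the scored cells (all-zero genes are dropped with a warning);
#' (2) each cell's score is the mean of the normalized core genes; (3) the
#' per-cell scores are rescaled to `[0, 1]` by `(x - min)/(max - min)` over
#' the whole scored population, so every signature shares the same range.
#' If all cells tie (degenerate rescale), all scores are set to 0 with a
#' warning.
#'
#' @param normalized genes x cells matrix over the population to score.
#' @param core_genes signature genes (e.g. a GSEA leading edge); must
#'   intersect the matrix genes.
#' @return Named numeric vector of per-cell scores in `[0, 1]`.
#' @export
score_cells <- function(normalized, core_genes) {
  genes <- intersect(core_genes, rownames(normalized))
  if (length(genes) == 0L)
    stop("no core genes present in the matrix")
  x <- as.matrix(normalized[genes, , drop = FALSE])
  mx <- apply(x, 1L, max)
  if (any(mx == 0)) {
    warning(sum(mx == 0), " all-zero core gene(s) dropped from scoring")
    x <- x[mx > 0, , drop = FALSE]
    mx <- mx[mx > 0]
    if (nrow(x) == 0L) stop("all core genes are zero across cells")
  }
  x <- x / mx
  m <- colMeans(x)
  rng <- range(m)
  if (rng[1] == rng[2]) {
    warning("degenerate rescale: all per-cell means equal; scores set to 0")
    return(setNames(rep(0, length(m)), colnames(normalized)))
  }
  setNames((m - rng[1]) / (rng[2] - rng[1]), colnames(normalized))
}

#' Two-sample Kolmogorov–Smirnov comparison
#'
#' Computes `D = sup_x |ECDF_a(x) - ECDF_b(x)|` and a two-sided p-value,
#' asymptotic by default (the Kolmogorov distribution evaluated at
#' `sqrt(n1 n2 / (n1 + n2)) * D`); `exact = TRUE` delegates the p-value to
#' [stats::ks.test()]'s exact small-sample computation.
#'
#' @param scores_a,scores_b nonempty numeric samples.
#' @param exact use the exact small-sample p-value.
#' @return List with `D` and `p_value`.
#' @export
ks_compare <- function(scores_a, scores_b, exact = FALSE) {
  a <- scores_a[!is.na(scores_a)]
  b <- scores_b[!is.na(scores_b)]
  if (length(a) == 0L || length(b) == 0L)
    stop("both samples must be nonempty")
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  ord <- order(pooled)
  steps <- cumsum(ifelse(ord <= n1, 1 / n1, -1 / n2))
  # at tied pooled values only the last step of the tie run counts
  sorted <- pooled[ord]
  last_of_run <- c(diff(sorted) != 0, TRUE)
  D <- max(abs(steps[last_of_run]))
  if (exact) {
    p <- suppressWarnings(stats::ks.test(a, b, exact = TRUE)$p.value)
  } else {
    t_stat <- sqrt(n1 * n2 / (n1 + n2)) * D
    p <- kolmogorov_sf(t_stat)
  }
  list(D = D, p_value = p)
}

# Survival function of the Kolmogorov distribution:
# Q(t) = 2 * sum_{k>=1} (-1)^(k-1) exp(-2 k^2 t^2)
kolmogorov_sf <- function(t) {
  if (t < 1e-8) return(1)
  k <- seq_len(101)
  terms <- (-1)^(k - 1) * exp(-2 * k^2 * t^2)
  min(1, max(0, 2 * sum(terms)))
}
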