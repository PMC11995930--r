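#' Pooled pairwise marker panel
#'
#' For every unordered pair of retained types, runs a Wilcoxon rank-sum test
#' per gene ([wilcoxon_de()]) and takes the top `top_k` genes by ascending
#' p-value (ties broken by descending absolute log2 fold-change, then gene
#' name). The panel is the deduplicated union over all pairs; provenance
#' records, per selected gene, which pair and rank produced it. Ambiguous
#' cells are excluded; a pair in which either type has fewer than 3 cells is
#' skipped with a warning.
#'
#' @param normalized genes x cells matrix from [normalize_expression()].
#' @param labels a label data.frame (columns `barcode`, `label`) covering
#'   the columns of `normalized`.
#' @param top_k markers kept per pairwise comparison (default 30).
#' @param min_frac expressed-fraction filter forwarded to [wilcoxon_de()];
#'   0 here so the panel considers all genes.
#' @return A `marker_panel`: list with `genes` (unique character vector) and
#'   `provenance` (data.frame gene/type_a/type_b/rank).
#' @export
pairwise_marker_panel <- function(normalized, labels, top_k = 30L,
                                  min_frac = 0) {
  lab <- labels$label[match(colnames(normalized), labels$barcode)]
  types <- sort(setdiff(unique(lab[!is.na(lab)]), "ambiguous"))
  if (length(types) < 2L)
    stop("need >= 2 retained types to build a marker panel")
  prov <- list()
  for (i in seq_len(length(types) - 1L)) {
    for (j in seq(i + 1L, length(types))) {
      cells_a <- which(lab == types[i])
      cells_b <- which(lab == types[j])
      if (length(cells_a) < 3L || length(cells_b) < 3L) {
        warning(sprintf("pair (%s, %s) skipped: fewer than 3 cells in a type",
                        types[i], types[j]))
        next
      }
      de <- wilcoxon_de(normalized, cells_a, cells_b, min_frac = min_frac)
      ord <- order(de$p_value, -abs(de$log2_fold_change), de$gene)
      top <- de$gene[head(ord, top_k)]
      if (length(top) > 0L)
        prov[[length(prov) + 1L]] <- data.frame(
          gene = top, type_a = types[i], type_b = types[j],
          rank = seq_along(top), stringsAsFactors = FALSE)
    }
  }
  if (length(prov) == 0L) stop("no type pair had enough cells")
  prov <- do.call(rbind, prov)
  structure(list(genes = unique(prov$gene), provenance = prov),
            class = "marker_panel")
}

#' Cluster tree over cells from shared-nearest-neighbor distances
#'
#' Restricts the matrix to the panel genes, embeds cells with PCA, builds a
#' k-nearest-neighbor graph, converts it to a shared-nearest-neighbor (SNN)
#' Jaccard similarity, and agglomerates the distance `1 - similarity` into a
#' dendrogram whose `cut_tree(tree, k)` cuts give nested partitions.
#'
#' @param normalized genes x cells matrix.
#' @param panel a `marker_panel` (or character vector of genes).
#' @param n_pcs number of principal components (clamped to the data).
#' @param k_neighbors neighborhood size for the SNN graph (includes the cell
#'   itself; clamped with a warning when there are fewer cells).
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @return A `cluster_tree`: list with the `hclust` object, `cell_ids` and
#'   `n_cells`.
#' @export
build_cluster_tree <- function(normalized, panel, n_pcs = 20L,
                               k_neighbors = 20L, linkage = "average") {
  genes <- if (inherits(panel, "marker_panel")) panel$genes else panel
  genes <- intersect(genes, rownames(normalized))
  if (length(genes) == 0L) stop("panel shares no genes with the matrix")
  n <- ncol(normalized)
  if (n < 2L) stop("need >= 2 cells to build a tree")
  if (k_neighbors > n) {
    warning("k_neighbors clamped from ", k_neighbors, " to ", n)
    k_neighbors <- n
  }
  emb <- pca_embed(normalized, genes, n_pcs)$scores
  d <- as.matrix(dist(emb))
  nn <- t(apply(d, 1L, function(r) order(r)[seq_len(k_neighbors)]))
  # SNN Jaccard: |shared neighbors| / |union of neighborhoods|
  adj <- matrix(0L, n, n)
  adj[cbind(rep(seq_len(n), each = k_neighbors), as.vector(t(nn)))] <- 1L
  shared <- tcrossprod(adj)
  jac <- shared / (2 * k_neighbors - shared)
  hc <- hclust(as.dist(1 - jac), method = linkage)
  hc$labels <- colnames(normalized)
  structure(list(hclust = hc, cell_ids = colnames(normalized), n_cells = n),
            class = "cluster_tree")
}

#' Cut a cluster tree into k clusters
#'
#' `k = 1` returns a single cluster; `k >= n_cells` the singleton partition;
#' partitions are nested as `k` grows.
#'
#' @param tree a `cluster_tree`.
#' @param k requested number of clusters.
#' @return Integer cluster membership named by cell id.
#' @export
cut_tree <- function(tree, k) {
  if (!inherits(tree, "cluster_tree")) stop("'tree' must be a cluster_tree")
  cutree(tree$hclust, k = min(k, tree$n_cells))
}

# PCA embedding of cells over a gene subset; optionally fit on a subset of
# cells and project the rest with the same centering and rotation.
pca_embed <- function(normalized, genes, n_pcs, fit_cells = NULL) {
  x <- t(as.matrix(normalized[genes, , drop = FALSE]))
  fit_x <- if (is.null(fit_cells)) x else x[fit_cells, , drop = FALSE]
  rank <- min(n_pcs, ncol(fit_x), nrow(fit_x) - 1L)
  keep <- which(apply(fit_x, 2L, function(v) stats::sd(v) > 0))
  if (length(keep) == 0L) stop("all panel genes are constant across cells")
  pc <- prcomp(fit_x[, keep, drop = FALSE], center = TRUE, scale. = FALSE,
               rank. = max(rank, 1L))
  scores <- scale(x[, keep, drop = FALSE], center = pc$center,
                  scale = FALSE) %*% pc$rotation
  list(scores = scores, rotation = pc$rotation, center = pc$center)
}

#' Trimmed mean
#'
#' Mean of the values remaining after removing the `floor(trim * n)`
#' smallest and `floor(trim * n)` largest observations — i.e. `trim` is the
#' fraction removed from each tail, the convention of [base::mean()]'s
#' `trim` argument. `NA` values are dropped first.
#'
#' @param values nonempty numeric vector.
#' @param trim fraction in `[0, 0.5)` removed from each tail (default 0.25).
#' @return The trimmed mean (scalar).
#' @export
trimmed_mean <- function(values, trim = 0.25) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("trimmed_mean of empty input")
  if (trim < 0 || trim >= 0.5) stop("trim must be in [0, 0.5)")
  s <- sort(values)
  g <- floor(trim * length(s))
  mean(s[(g + 1L):(length(s) - g)])
}

# Assign each cluster of a partition the type with the maximal trimmed-mean
# correlation over its member cells; ties go to the lexicographically first
# type (columns are name-sorted).
assign_clusters <- function(partition, corr, trim) {
  vals <- unclass(corr)
  types <- colnames(corr)
  labels <- character(length(partition))
  for (cl in unique(partition)) {
    members <- which(partition == cl)
    tm <- vapply(seq_along(types), function(j) {
      v <- vals[members, j]
      v <- v[!is.na(v)]
      if (length(v) == 0L) -Inf else trimmed_mean(v, trim)
    }, numeric(1))
    labels[members] <- types[which.max(tm)]
  }
  labels
}

#' Iterative dendrogram walk to consensus labels
#'
#' Cuts the tree at k = 1, 2, 3, ... clusters. At each cut, every cluster is
#' assigned the retained type with the maximal trimmed-mean correlation over
#' its member cells, and all member cells take that label. When the full
#' label vector equals the previous iteration's the consensus score is
#' incremented, otherwise it resets to 0; the walk stops, and the current
#' labels become final, as soon as the score reaches `patience`. Termination
#' is guaranteed because the singleton cut (k >= n cells) is a fixed point.
#'
#' @param tree a `cluster_tree` over the sketch cells.
#' @param corr a `correlation_table` covering the same cells (any order).
#' @param patience consecutive unchanged iterations required (default 10).
#' @param trim trimmed-mean tail fraction (default 0.25).
#' @param max_iterations safety cap; default `n_cells + patience + 1`, the
#'   worst case.
#' @return A label data.frame (`barcode`, `label`, `provenance = "sketch"`,
#'   `best_correlation` of the assigned type) with attribute `iterations`.
#' @export
consensus_walk <- function(tree, corr, patience = 10L, trim = 0.25,
                           max_iterations = NULL) {
  if (!inherits(tree, "cluster_tree")) stop("'tree' must be a cluster_tree")
  if (patience < 1L) stop("patience must be >= 1")
  idx <- match(tree$cell_ids, rownames(corr))
  if (anyNA(idx))
    stop("correlation table does not cover all sketch cells")
  corr_m <- unclass(corr)[idx, , drop = FALSE]
  class(corr_m) <- "matrix"
  n <- tree$n_cells
  max_iterations <- max_iterations %||% (n + patience + 1L)
  prev <- NULL
  score <- 0L
  labels <- NULL
  k_done <- 0L
  for (k in seq_len(max_iterations)) {
    part <- cut_tree(tree, k)
    labels <- assign_clusters(part, corr_m, trim)
    if (!is.null(prev) && identical(labels, prev)) score <- score + 1L
    else score <- 0L
    prev <- labels
    k_done <- k
    if (score >= patience) break
  }
  if (score < patience)
    stop(sprintf(paste0("consensus_walk did not converge within %d ",
                        "iterations (last consensus score %d, %d clusters)"),
                 max_iterations, score, length(unique(cut_tree(tree, k_done)))))
  best_r <- corr_m[cbind(seq_len(n), match(labels, colnames(corr_m)))]
  out <- data.frame(barcode = tree$cell_ids, label = labels,
                    provenance = "sketch", best_correlation = best_r,
                    stringsAsFactors = FALSE)
  attr(out, "iterations") <- k_done
  out
}

#' Project sketch labels to the whole dataset
#'
#' Fits a PCA embedding of panel-gene space on the sketch cells, projects
#' every cell into it, and gives each non-sketch cell the majority label of
#' its `k_neighbors` nearest sketch cells (Euclidean distance in the
#' embedding); ties are broken by the nearest neighbor carrying a tied
#' label. Sketch cells keep their own labels. Provenance records
#' `"sketch"` vs `"projected"`.
#'
#' @param sketch_labels label data.frame from [consensus_walk()].
#' @param normalized_full genes x cells matrix over all cells.
#' @param panel a `marker_panel` or gene vector.
#' @param k_neighbors neighbors consulted per projected cell (default 5;
#'   clamped to the sketch size with a warning).
#' @param n_pcs embedding dimension (default 20).
#' @return Label data.frame over all cells (`barcode`, `label`,
#'   `provenance`).
#' @export
project_labels <- function(sketch_labels, normalized_full, panel,
                           k_neighbors = 5L, n_pcs = 20L) {
  genes <- if (inherits(panel, "marker_panel")) panel$genes else panel
  genes <- intersect(genes, rownames(normalized_full))
  all_cells <- colnames(normalized_full)
  sk <- match(sketch_labels$barcode, all_cells)
  if (anyNA(sk)) stop("sketch cells must be a subset of the full dataset")
  if (k_neighbors > length(sk)) {
    warning("k_neighbors clamped to sketch size ", length(sk))
    k_neighbors <- length(sk)
  }
  emb <- pca_embed(normalized_full, genes, n_pcs, fit_cells = sk)$scores
  other <- setdiff(seq_along(all_cells), sk)
  label <- character(length(all_cells))
  label[sk] <- sketch_labels$label
  if (length(other) > 0L) {
    d2 <- euclid_cross_sq(emb[other, , drop = FALSE],
                          emb[sk, , drop = FALSE])
    for (i in seq_along(other)) {
      ord <- order(d2[i, ])[seq_len(k_neighbors)]
      votes <- table(sketch_labels$label[ord])
      winners <- names(votes)[votes == max(votes)]
      if (length(winners) == 1L) label[other[i]] <- winners
      else {
        # tie: the closest neighbor among the tied labels decides
        cand <- ord[sketch_labels$label[ord] %in% winners]
        label[other[i]] <- sketch_labels$label[cand[1L]]
      }
    }
  }
  prov <- rep("projected", length(all_cells))
  prov[sk] <- "sketch"
  data.frame(barcode = all_cells, label = label, provenance = prov,
             stringsAsFactors = FALSE)
}

# Squared Euclidean cross-distances between rows of a and rows of b.
euclid_cross_sq <- function(a, b) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  pmax(outer(an, bn, `+`) - 2 * tcrossprod(a, b), 0)
}

#' Balance cell-type counts across two conditions
#'
#' For each target type, takes `n = min(count in A, count in B)` and samples
#' exactly `n` cells of that type from each condition without replacement,
#' so neither condition over-represents the type in downstream differential
#' expression.
#'
#' @param labels label data.frame covering the cells.
#' @param conditions per-cell condition, named by barcode (or aligned with
#'   `labels`).
#' @param target_types types to balance.
#' @param seed integer seed for the sampling.
#' @return Character vector of retained barcodes.
#' @export
balance_conditions <- function(labels, conditions, target_types, seed) {
  if (is.null(names(conditions)))
    names(conditions) <- labels$barcode
  cond <- conditions[labels$barcode]
  levs <- sort(unique(as.character(cond)))
  if (length(levs) != 2L) stop("exactly two conditions are required")
  kept <- character(0)
  withr::with_seed(as.integer(seed), {
    for (tt in target_types) {
      in_a <- labels$barcode[labels$label == tt & cond == levs[1]]
      in_b <- labels$barcode[labels$label == tt & cond == levs[2]]
      if (length(in_a) == 0L || length(in_b) == 0L)
        stop("type '", tt, "' absent in one condition")
      n <- min(length(in_a), length(in_b))
      kept <- c(kept,
                if (length(in_a) == n) in_a else sample(in_a, n),
                if (length(in_b) == n) in_b else sample(in_b, n))
    }
  })
  kept
}
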