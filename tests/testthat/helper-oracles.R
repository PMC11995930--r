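# Independent brute-force oracles and small fixture builders used across
# the suite. Each oracle re-derives the quantity by the most naive route
# available, without sharing code with the implementation.

# Two-sample KS statistic: literal sup over ECDF differences evaluated at
# every pooled sample point.
oracle_ks_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(vapply(pts, function(x)
    abs(mean(a <= x) - mean(b <= x)), numeric(1)))
}

# GSEA enrichment score: position-by-position running sum, no
# vectorization, following the weighted-KS definition directly.
oracle_es <- function(scores, in_set, weight = 1) {
  n <- length(scores)
  nh <- sum(in_set)
  denom_hit <- sum(abs(scores[in_set])^weight)
  run <- 0
  best <- 0
  for (i in seq_len(n)) {
    if (in_set[i]) {
      run <- run + if (denom_hit > 0) abs(scores[i])^weight / denom_hit
                   else 1 / nh
    } else {
      run <- run - 1 / (n - nh)
    }
    # first-peak convention with a floating-point guard, as documented
    if (abs(run) > abs(best) + 1e-9) best <- run
  }
  unname(best)
}

# Builds a small two-condition dataset on disk and returns the input paths.
pipeline_fixture <- function(seed = 221, shift = 2) {
  cfg <- generator_config(n_types = 2, n_cells_per_type = 100, n_genes = 150,
                          markers_per_type = 8, seed = seed)
  atlas <- make_reference_atlas(cfg)
  sig <- sprintf("gene-%04d", 40:54)
  pair <- simulate_condition_pair(atlas, cfg, sig, shift_log2fc = shift)
  da <- withr::local_tempdir(.local_envir = parent.frame())
  db <- withr::local_tempdir(.local_envir = parent.frame())
  write_counts_10x(pair$counts_a, da)
  write_counts_10x(pair$counts_b, db)
  at_csv <- file.path(da, "atlas.csv")
  write_atlas_csv(atlas, at_csv)
  gmt <- file.path(da, "sets.gmt")
  write_gmt(list(make_gene_set("shifted_signature", sig),
                 make_gene_set("unrelated", sprintf("gene-%04d", 100:109))),
            gmt)
  list(da = da, db = db, atlas = at_csv, gmt = gmt, truth = pair)
}

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of all
# assignments of the pooled observations to group 1.
oracle_wilcox_p <- function(v1, v2) {
  n1 <- length(v1)
  pooled <- c(v1, v2)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  assignments <- combn(length(pooled), n1)
  ws <- apply(assignments, 2L, function(idx)
    sum(r[idx]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(ws <= obs), mean(ws >= obs)))
}

# Naive reimplementation of the dendrogram walk: cut at k = 1, 2, ...,
# recompute every cluster assignment from scratch, track the consensus
# score literally as described.
oracle_consensus_walk <- function(hc, corr_m, patience, trim) {
  n <- nrow(corr_m)
  types <- colnames(corr_m)
  prev <- NULL
  score <- 0
  for (k in 1:(n + patience + 1)) {
    part <- stats::cutree(hc, k = min(k, n))
    labels <- character(n)
    for (cl in unique(part)) {
      cells <- which(part == cl)
      best_val <- -Inf
      best_type <- NA_character_
      for (ty in types) {
        v <- corr_m[cells, ty]
        v <- v[!is.na(v)]
        if (length(v) == 0) next
        s <- sort(v)
        g <- floor(trim * length(s))
        tm <- mean(s[(g + 1):(length(s) - g)])
        if (tm > best_val) { best_val <- tm; best_type <- ty }
      }
      labels[cells] <- best_type
    }
    if (!is.null(prev) && all(labels == prev)) score <- score + 1
    else score <- 0
    prev <- labels
    if (score == patience) return(list(labels = labels, iterations = k))
  }
  stop("oracle walk did not converge")
}

# Toy count matrix with exact per-cell totals and mitochondrial fractions:
# one mt- gene carries the mitochondrial mass, one gene the rest.
toy_mito_matrix <- function(totals, mito_frac) {
  stopifnot(length(totals) == length(mito_frac))
  mt <- round(totals * mito_frac)
  m <- rbind(`gene-a` = totals - mt, `mt-1` = mt)
  colnames(m) <- sprintf("cell-%02d", seq_along(totals))
  Matrix::Matrix(m, sparse = TRUE)
}

# Small generator configuration shared by module tests.
tiny_config <- function(seed, ...) {
  generator_config(n_types = 3, n_genes = 120, n_cells_per_type = 60,
                   markers_per_type = 6, seed = seed, ...)
}

make_gene_set <- function(name, genes) {
  structure(list(name = name, description = "synthetic", genes = genes),
            class = "gene_set")
}
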