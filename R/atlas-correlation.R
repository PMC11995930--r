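#' Translate an atlas into the sample's gene space via homologs
#'
#' Re-indexes atlas profiles by `target_genes` using a homolog map. Several
#' source genes mapping to one target are collapsed by their mean profile
#' value; one source gene mapping to several targets contributes its value to
#' each of them. Target genes with no mapped source are dropped from the
#' correlation support (not carried as zeros). Mapping statistics are
#' reported via `message()`.
#'
#' @param atlas a [reference_atlas()].
#' @param map data.frame with columns `source_id`, `target_id` (see
#'   [read_homolog_map()]), or `NULL` for the identity map (atlas and sample
#'   share a gene space).
#' @param target_genes gene identifiers of the sample.
#' @return A [reference_atlas()] indexed by the mapped subset of
#'   `target_genes`.
#' @export
translate_homologs <- function(atlas, map, target_genes) {
  if (!inherits(atlas, "reference_atlas")) stop("'atlas' must be a reference_atlas")
  if (is.null(map)) {
    map <- data.frame(source_id = atlas$gene_ids,
                      target_id = atlas$gene_ids,
                      stringsAsFactors = FALSE)
  }
  if (!all(c("source_id", "target_id") %in% names(map)))
    stop("homolog map needs columns source_id and target_id")
  map <- unique(map[, c("source_id", "target_id")])
  map <- map[map$source_id %in% atlas$gene_ids &
               map$target_id %in% target_genes, , drop = FALSE]
  if (nrow(map) == 0L)
    stop("no overlapping genes between atlas and target after translation")
  src_idx <- match(map$source_id, atlas$gene_ids)
  kept_targets <- target_genes[target_genes %in% map$target_id]
  prof <- matrix(0, nrow = length(kept_targets),
                 ncol = ncol(atlas$profiles))
  for (j in seq_along(kept_targets)) {
    rows <- src_idx[map$target_id == kept_targets[j]]
    prof[j, ] <- if (length(rows) == 1L) atlas$profiles[rows, ]
                 else colMeans(atlas$profiles[rows, , drop = FALSE])
  }
  message(sprintf(
    "translate_homologs: %d/%d target genes mapped from %d source genes (%d pairs)",
    length(kept_targets), length(target_genes),
    length(unique(map$source_id)), nrow(map)))
  reference_atlas(prof, type_name = atlas$type_name, source = atlas$source,
                  gene_ids = kept_targets)
}

#' Normalize expression before correlation and scoring
#'
#' Default scheme: per-cell library-size scaling to a fixed total followed
#' by `log1p` — the common transform ahead of correlation-based typing.
#' `"raw"` leaves counts untouched; `"rank"` replaces each cell's values by
#' their within-cell ranks (average ties), which makes the downstream Pearson
#' correlation a Spearman correlation.
#'
#' @param counts genes x cells count matrix; no cell may have a zero total
#'   (such cells should already be removed by QC).
#' @param method `"lognorm"` (default), `"raw"` or `"rank"`.
#' @param target_total fixed per-cell total for `"lognorm"`.
#' @return A matrix of the same shape (sparse for `"lognorm"`/`"raw"`).
#' @export
normalize_expression <- function(counts, method = c("lognorm", "raw", "rank"),
                                 target_total = 1e4) {
  assert_count_matrix(counts)
  method <- match.arg(method)
  totals <- Matrix::colSums(counts)
  if (any(totals == 0))
    stop("cell(s) with zero total counts: ",
         paste(head(colnames(counts)[totals == 0], 5), collapse = ", "))
  if (method == "raw") return(counts)
  if (method == "rank") {
    dense <- as.matrix(counts)
    return(apply(dense, 2L, rank))
  }
  scaled <- counts %*% Matrix::Diagonal(x = target_total / totals)
  scaled <- as(scaled, "CsparseMatrix")
  scaled@x <- log1p(scaled@x)
  dimnames(scaled) <- dimnames(counts)
  scaled
}

#' Sketch-subsample cells
#'
#' Draws `min(n, n_cells)` distinct cells uniformly at random, deterministic
#' given the seed; indices are returned in increasing order so the original
#' cell order is preserved. Intended to be applied once per condition.
#'
#' @param counts genes x cells matrix (only `ncol` is used).
#' @param n sketch size.
#' @param seed integer seed.
#' @return Integer vector of column indices.
#' @export
sketch_sample <- function(counts, n, seed) {
  if (n < 1) stop("sketch size n must be >= 1")
  n_cells <- ncol(counts)
  if (n >= n_cells) return(seq_len(n_cells))
  withr::with_seed(as.integer(seed), sort(sample.int(n_cells, n)))
}

#' Correlate cells with atlas entries, best per type
#'
#' Computes the Pearson correlation between every cell and every atlas entry
#' over the intersection of the sample and atlas gene spaces, then keeps,
#' for each unique type name, the maximum over that type's entries
#' (best-of-duplicates). Atlas profiles are put on the same scale as the
#' cells before correlating (library-size scaling to `target_total` +
#' `log1p` by default; `profile_transform = "raw"` correlates against the
#' linear profiles). Zero-variance vectors give an undefined correlation,
#' stored as `NA` and treated as `-Inf` when picking the best type.
#'
#' @param normalized genes x cells matrix from [normalize_expression()].
#' @param atlas a [reference_atlas()] in the sample's gene space.
#' @param profile_transform transform applied to atlas profiles.
#' @param target_total per-entry total used by the `"lognorm"` transform.
#' @return A `correlation_table`: cells x unique-types numeric matrix
#'   (columns in lexicographic type order) with attributes
#'   `n_shared_genes` and `entry_support` (entries per type).
#' @export
correlate_cells <- function(normalized, atlas,
                            profile_transform = c("lognorm", "raw"),
                            target_total = 1e4) {
  profile_transform <- match.arg(profile_transform)
  shared <- intersect(rownames(normalized), atlas$gene_ids)
  if (length(shared) < 3L)
    stop("need >= 3 shared genes between sample and atlas, got ",
         length(shared))
  prof <- atlas$profiles[match(shared, atlas$gene_ids), , drop = FALSE]
  if (profile_transform == "lognorm") {
    tot <- colSums(prof)
    tot[tot == 0] <- 1
    prof <- log1p(sweep(prof, 2L, target_total / tot, `*`))
  }
  cells <- as.matrix(normalized[shared, , drop = FALSE])
  entry_cor <- suppressWarnings(cor(cells, prof))

  types <- sort(unique(atlas$type_name))
  out <- matrix(NA_real_, nrow = ncol(cells), ncol = length(types),
                dimnames = list(colnames(normalized), types))
  for (j in seq_along(types)) {
    cols <- which(atlas$type_name == types[j])
    block <- entry_cor[, cols, drop = FALSE]
    best <- apply(block, 1L, function(r)
      if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
    out[, j] <- best
  }
  structure(out, class = c("correlation_table", class(out)),
            n_shared_genes = length(shared),
            entry_support = table(atlas$type_name))
}

# Per-cell argmax type with NA treated as -Inf; ties broken by the first
# (lexicographically smallest) type, since columns are name-sorted.
best_type <- function(corr) {
  vals <- unclass(corr)
  vals[is.na(vals)] <- -Inf
  colnames(corr)[max.col(vals, ties.method = "first")]
}

#' Prune rare predicted types and label their cells ambiguous
#'
#' Each sketch cell gets an initial label: the type with its best
#' correlation. Types whose share of initial labels is strictly below
#' `min_frac` are dropped from the table; their cells are labeled
#' `"ambiguous"`. Cells initially assigned to surviving types keep their
#' label. Shares are computed over all sketch cells, including those about
#' to become ambiguous.
#'
#' @param corr a `correlation_table` from [correlate_cells()].
#' @param min_frac minimum share of sketch cells a type must claim
#'   (default 0.0005, i.e. 0.05%).
#' @return A list with `corr` (pruned table) and `labels`, a data.frame with
#'   columns `barcode`, `label`, `provenance` (= `"sketch"`) and
#'   `best_correlation`.
#' @export
prune_rare_types <- function(corr, min_frac = 5e-4) {
  if (ncol(corr) < 1L) stop("correlation table has no types")
  initial <- best_type(corr)
  share <- table(factor(initial, levels = colnames(corr))) / nrow(corr)
  keep <- share >= min_frac
  if (!any(keep)) stop("all types pruned at min_frac = ", min_frac)
  label <- ifelse(initial %in% colnames(corr)[keep], initial, "ambiguous")
  best_r <- unclass(corr)[cbind(seq_len(nrow(corr)),
                                match(initial, colnames(corr)))]
  pruned <- corr[, keep, drop = FALSE]
  structure_attrs <- attributes(corr)
  attr(pruned, "n_shared_genes") <- structure_attrs$n_shared_genes
  class(pruned) <- class(corr)
  list(corr = pruned,
       labels = data.frame(barcode = rownames(corr),
                           label = label,
                           provenance = "sketch",
                           best_correlation = best_r,
                           stringsAsFactors = FALSE))
}
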