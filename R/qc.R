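#' Cell quality-control thresholds
#'
#' @param min_umis keep cells with total UMIs strictly greater than this.
#' @param max_mito_frac keep cells whose mitochondrial UMI fraction is
#'   strictly below this. The default 0.01 reads the conventional "percent
#'   mitochondrial content" cutoff as the fraction 1%; the literal 0.01%
#'   (0.0001) is reachable by setting it explicitly.
#' @param gene_count_bounds optional `c(low, high)` open-interval bounds on
#'   detected genes per cell, used to drop putative doublets (high tail) and
#'   dead cells (low tail). `NULL` disables the filter; there is no silent
#'   default because these bounds are meant to be set by inspecting the
#'   detected-genes distribution (see [propose_gene_count_bounds()]).
#' @param min_cells_per_gene genes must be quantified in at least this many
#'   cells to be kept by [filter_genes()]. The default 2 removes genes seen
#'   in only one cell.
#'
#' @return A validated list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_umis = 1000L, max_mito_frac = 0.01,
                          gene_count_bounds = NULL,
                          min_cells_per_gene = 2L) {
  if (min_umis < 0) stop("min_umis must be >= 0")
  if (max_mito_frac < 0 || max_mito_frac > 1)
    stop("max_mito_frac must be in [0, 1]")
  if (!is.null(gene_count_bounds)) {
    if (length(gene_count_bounds) != 2L ||
        !(gene_count_bounds[1] < gene_count_bounds[2]))
      stop("gene_count_bounds must be c(low, high) with low < high")
  }
  if (min_cells_per_gene < 0) stop("min_cells_per_gene must be >= 0")
  structure(list(min_umis = min_umis,
                 max_mito_frac = max_mito_frac,
                 gene_count_bounds = gene_count_bounds,
                 min_cells_per_gene = as.integer(min_cells_per_gene)),
            class = "qc_thresholds")
}

#' Filter cells on UMI depth, mitochondrial content and detected genes
#'
#' Retains exactly the cells with total UMIs strictly greater than
#' `min_umis`, mitochondrial fraction strictly below `max_mito_frac`, and
#' (when bounds are set) detected genes strictly inside
#' `(low, high)`. The mitochondrial fraction is computed on the raw,
#' unfiltered gene set, so gene filtering can never change cell QC outcomes.
#' Cell order is preserved.
#'
#' @param counts genes x cells count matrix with dimnames.
#' @param thresholds a [qc_thresholds()].
#' @return A list with `counts` (filtered matrix) and `report`, a
#'   `qc_report` recording input/output sizes, per-filter removal counts and
#'   the thresholds used.
#' @export
filter_cells <- function(counts, thresholds = qc_thresholds()) {
  assert_count_matrix(counts)
  if (!inherits(thresholds, "qc_thresholds"))
    stop("'thresholds' must come from qc_thresholds()")
  totals <- Matrix::colSums(counts)
  mt <- mito_gene_index(rownames(counts))
  if (length(mt) == 0L) {
    warning("no mitochondrial genes found by name prefix 'mt-'; ",
            "mitochondrial filter skipped")
    mito_pass <- rep(TRUE, ncol(counts))
  } else if (thresholds$max_mito_frac >= 1) {
    # vacuous threshold: every fraction (including exactly 1) passes
    mito_pass <- rep(TRUE, ncol(counts))
  } else {
    mito_frac <- Matrix::colSums(counts[mt, , drop = FALSE]) /
      pmax(totals, 1)
    mito_pass <- mito_frac < thresholds$max_mito_frac
  }
  umi_pass <- totals > thresholds$min_umis
  if (is.null(thresholds$gene_count_bounds)) {
    bounds_pass <- rep(TRUE, ncol(counts))
  } else {
    detected <- Matrix::colSums(counts > 0)
    bounds_pass <- detected > thresholds$gene_count_bounds[1] &
      detected < thresholds$gene_count_bounds[2]
  }
  keep <- umi_pass & mito_pass & bounds_pass
  report <- structure(list(
    n_cells_in = ncol(counts),
    n_cells_out = sum(keep),
    n_genes_in = nrow(counts),
    n_genes_out = nrow(counts),
    removed_low_umi = sum(!umi_pass),
    removed_high_mito = sum(!mito_pass),
    removed_gene_count_bounds = sum(!bounds_pass),
    mito_filter_applied = length(mt) > 0L,
    thresholds = unclass(thresholds)), class = "qc_report")
  list(counts = counts[, keep, drop = FALSE], report = report)
}

#' Remove genes quantified in too few cells
#'
#' Keeps genes with nonzero counts in at least `min_cells_per_gene` cells.
#' The default 2 removes genes quantified in only one cell (and all-zero
#' genes). Gene order is preserved.
#'
#' @param counts genes x cells count matrix.
#' @param min_cells_per_gene minimum number of cells with a nonzero count.
#' @return The filtered count matrix (possibly with zero genes).
#' @export
filter_genes <- function(counts, min_cells_per_gene = 2L) {
  assert_count_matrix(counts)
  n_cells_expressing <- Matrix::rowSums(counts > 0)
  counts[n_cells_expressing >= min_cells_per_gene, , drop = FALSE]
}

#' Propose detected-genes bounds from the per-cell distribution
#'
#' Returns the requested quantiles of the detected-genes-per-cell
#' distribution as candidate `(low, high)` bounds for the doublet/dead-cell
#' filter. Purely advisory: the bounds must still be passed explicitly to
#' [qc_thresholds()], mirroring a manual choice made by inspecting the
#' distribution.
#'
#' @param counts genes x cells count matrix.
#' @param low_quantile,high_quantile quantiles in `[0, 1]` with
#'   `low_quantile < high_quantile`.
#' @return Named numeric `c(low, high)`.
#' @export
propose_gene_count_bounds <- function(counts, low_quantile = 0.01,
                                      high_quantile = 0.99) {
  assert_count_matrix(counts)
  if (ncol(counts) < 2L) stop("need at least 2 cells to propose bounds")
  if (!(low_quantile >= 0 && low_quantile < high_quantile &&
        high_quantile <= 1))
    stop("need 0 <= low_quantile < high_quantile <= 1")
  detected <- Matrix::colSums(counts > 0)
  q <- quantile(detected, c(low_quantile, high_quantile), names = FALSE)
  c(low = q[1], high = q[2])
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d -> %d cells (low UMI: %d, high mito: %d, gene-count bounds: %d)\n",
              x$n_cells_in, x$n_cells_out, x$removed_low_umi,
              x$removed_high_mito, x$removed_gene_count_bounds))
  invisible(x)
}
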