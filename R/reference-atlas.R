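#' Reference atlas of cell-type expression profiles
#'
#' A reference atlas is a collection of per-gene expression profiles, one per
#' atlas entry. An entry is a (type name, source) pair; the same type name may
#' appear under several sources (e.g. the same type profiled by different
#' atlases), in which case downstream correlation takes the best entry per
#' type.
#'
#' @param profiles numeric matrix, genes x entries, strictly nonnegative.
#' @param type_name character vector, one per entry (column).
#' @param source character vector, one per entry.
#' @param gene_ids gene identifiers; defaults to `rownames(profiles)`.
#'
#' @return An object of class `reference_atlas`: a list with elements
#'   `gene_ids`, `type_name`, `source` and `profiles` (genes x entries).
#' @export
reference_atlas <- function(profiles, type_name, source = "user",
                            gene_ids = rownames(profiles)) {
  profiles <- as.matrix(profiles)
  if (is.null(gene_ids)) stop("gene identifiers are required")
  if (length(gene_ids) != nrow(profiles))
    stop("gene_ids length must equal nrow(profiles)")
  if (length(type_name) != ncol(profiles))
    stop("one type_name per profile column is required")
  source <- rep_len(source, ncol(profiles))
  if (any(profiles < 0)) stop("atlas profiles must be nonnegative")
  if (ncol(profiles) == 0L) stop("atlas has no entries")
  rownames(profiles) <- gene_ids
  colnames(profiles) <- make.unique(paste(type_name, source, sep = "|"))
  structure(
    list(gene_ids = as.character(gene_ids),
         type_name = as.character(type_name),
         source = as.character(source),
         profiles = profiles),
    class = "reference_atlas")
}

#' @export
print.reference_atlas <- function(x, ...) {
  cat(sprintf("reference_atlas: %d entries (%d unique types), %d genes\n",
              length(x$type_name), length(unique(x$type_name)),
              length(x$gene_ids)))
  invisible(x)
}

#' @export
length.reference_atlas <- function(x) length(x$type_name)
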