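#' Read a 10x-style count directory
#'
#' Expects `matrix.mtx` (Matrix Market coordinate), `features.tsv` and
#' `barcodes.tsv` (uncompressed). Feature and barcode order is preserved.
#' Duplicate feature identifiers are disambiguated deterministically with
#' [make.unique()] suffixes and reported via `message()`.
#'
#' @param dir directory containing the three files.
#' @return Sparse integer genes x cells matrix with dimnames.
#' @export
read_counts_10x <- function(dir) {
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  missing_f <- paths[!file.exists(paths)]
  if (length(missing_f) > 0L)
    stop("missing file(s): ", paste(missing_f, collapse = ", "))
  m <- as(readMM(paths[1]), "CsparseMatrix")
  features <- read.delim(paths[2], header = FALSE,
                         stringsAsFactors = FALSE)
  barcodes <- read.delim(paths[3], header = FALSE,
                         stringsAsFactors = FALSE)
  if (nrow(features) != nrow(m))
    stop(sprintf("matrix.mtx declares %d genes but features.tsv has %d lines",
                 nrow(m), nrow(features)))
  if (nrow(barcodes) != ncol(m))
    stop(sprintf("matrix.mtx declares %d cells but barcodes.tsv has %d lines",
                 ncol(m), nrow(barcodes)))
  ids <- as.character(features[[1]])
  if (anyDuplicated(ids)) {
    message(sum(duplicated(ids)), " duplicate feature id(s) suffixed")
    ids <- make.unique(ids)
  }
  dimnames(m) <- list(ids, as.character(barcodes[[1]]))
  m
}

#' Write a count matrix as 10x-style triplets
#'
#' Writes `matrix.mtx` in Matrix Market *integer* coordinate format
#' (1-based indices), `features.tsv` (id and name columns) and
#' `barcodes.tsv`.
#'
#' @param counts genes x cells matrix with dimnames.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_counts_10x <- function(counts, dir) {
  assert_count_matrix(counts)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  trip <- Matrix::summary(as(Matrix(counts, sparse = TRUE),
                             "CsparseMatrix"))
  con <- file(file.path(dir, "matrix.mtx"), "w")
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", nrow(counts), ncol(counts), nrow(trip))),
             con)
  if (nrow(trip) > 0L)
    writeLines(sprintf("%d %d %d", trip$i, trip$j, as.integer(trip$x)), con)
  close(con)
  writeLines(paste(rownames(counts), rownames(counts), sep = "\t"),
             file.path(dir, "features.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Write a synthetic truth table as TSV
#'
#' @param truth truth data.frame from [simulate_cells()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth[, c("barcode", "true_label", "is_doublet",
                               "condition")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then genes, tab-separated. Lines
#' with fewer than 3 fields raise an error naming the line; duplicate genes
#' within a set are deduplicated with a warning.
#'
#' @param path GMT file.
#' @return Named list of `gene_set` objects (`name`, `description`,
#'   `genes`).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop(sprintf("malformed GMT line %d: expected >= 3 tab-separated fields, got %d",
                   i, length(fields)))
    genes <- fields[-(1:2)]
    if (anyDuplicated(genes)) {
      warning(sprintf("duplicate gene(s) in set '%s' deduplicated",
                      fields[1]))
      genes <- unique(genes)
    }
    structure(list(name = fields[1], description = fields[2],
                   genes = genes), class = "gene_set")
  })
  setNames(sets, vapply(sets, `[[`, character(1), "name"))
}

#' Write gene sets to a GMT file
#'
#' @param sets list of `gene_set` objects, or a named list of character
#'   vectors.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    if (!inherits(s, "gene_set"))
      s <- list(name = names(sets)[i], description = "", genes = s)
    paste(c(s$name, if (nzchar(s$description %||% "")) s$description else ".",
            s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a reference atlas from CSV
#'
#' Expected columns: `type_name`, `source`, then one column per gene.
#'
#' @param path CSV file.
#' @return A [reference_atlas()].
#' @export
read_atlas_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("type_name", "source") %in% names(df)))
    stop("atlas CSV needs 'type_name' and 'source' columns first")
  gene_cols <- setdiff(names(df), c("type_name", "source"))
  if (length(gene_cols) == 0L) stop("atlas CSV has no gene columns")
  prof <- t(as.matrix(df[, gene_cols, drop = FALSE]))
  reference_atlas(prof, type_name = df$type_name, source = df$source,
                  gene_ids = gene_cols)
}

#' Write a reference atlas to CSV
#'
#' @param atlas a [reference_atlas()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_atlas_csv <- function(atlas, path) {
  df <- data.frame(type_name = atlas$type_name, source = atlas$source,
                   t(atlas$profiles), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("type_name", "source", atlas$gene_ids)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a homolog map from CSV
#'
#' Two columns, `source_id` and `target_id`; may be many-to-one and
#' one-to-many. Self-contradictory duplicate rows are collapsed.
#'
#' @param path CSV file.
#' @return data.frame with columns `source_id`, `target_id`.
#' @export
read_homolog_map <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("homolog map needs two columns")
  names(df)[1:2] <- c("source_id", "target_id")
  unique(df[, c("source_id", "target_id")])
}

#' Write a label table as TSV
#'
#' @param labels label data.frame (`barcode`, `label`, `provenance`, ...).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_labels_tsv <- function(labels, path) {
  utils::write.table(labels, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
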