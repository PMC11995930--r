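#' Configuration for the end-to-end pipeline
#'
#' Collects all paths and module parameters. Paths are validated here so a
#' bad configuration fails before any computation. Every stochastic stage
#' derives its own seed from the root `seed`, so a config fully determines
#' the outputs.
#'
#' @param counts_dir_a,counts_dir_b 10x-style count directories, one per
#'   condition.
#' @param atlas_csv reference-atlas CSV (see [read_atlas_csv()]).
#' @param gmt_path gene sets in GMT format.
#' @param out_dir output directory.
#' @param seed root integer seed.
#' @param homolog_csv optional homolog map CSV; `NULL` when atlas and
#'   sample share a gene space.
#' @param condition_names names for the two conditions.
#' @param qc a [qc_thresholds()].
#' @param normalization method for [normalize_expression()].
#' @param sketch_n sketch size per condition (default 5000).
#' @param min_type_frac rare-type pruning threshold (default 0.0005).
#' @param top_k markers per pairwise comparison (default 30).
#' @param trim trimmed-mean tail fraction (default 0.25).
#' @param patience consensus-walk patience (default 10).
#' @param k_neighbors projection neighbors (default 5).
#' @param snn_k SNN neighborhood size (default 20).
#' @param n_pcs embedding dimension (default 20).
#' @param de_min_frac expressed-fraction filter for condition DE
#'   (default 0.05).
#' @param n_perm GSEA permutations (default 1000).
#' @param target_types types to balance and compare across conditions;
#'   `NULL` means every final type present in both conditions.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts_dir_a, counts_dir_b, atlas_csv, gmt_path,
                            out_dir, seed,
                            homolog_csv = NULL,
                            condition_names = c("A", "B"),
                            qc = qc_thresholds(),
                            normalization = "lognorm",
                            sketch_n = 5000L,
                            min_type_frac = 5e-4,
                            top_k = 30L,
                            trim = 0.25,
                            patience = 10L,
                            k_neighbors = 5L,
                            snn_k = 20L,
                            n_pcs = 20L,
                            de_min_frac = 0.05,
                            n_perm = 1000L,
                            target_types = NULL) {
  for (d in c(counts_dir_a, counts_dir_b))
    if (!dir.exists(d)) stop("counts directory not found: ", d)
  for (f in c(atlas_csv, gmt_path, homolog_csv))
    if (!is.null(f) && !file.exists(f)) stop("file not found: ", f)
  if (missing(seed)) stop("a root 'seed' is required")
  structure(list(counts_dir_a = counts_dir_a, counts_dir_b = counts_dir_b,
                 atlas_csv = atlas_csv, gmt_path = gmt_path,
                 homolog_csv = homolog_csv, out_dir = out_dir,
                 condition_names = condition_names, qc = qc,
                 normalization = normalization,
                 sketch_n = as.integer(sketch_n),
                 min_type_frac = min_type_frac, top_k = as.integer(top_k),
                 trim = trim, patience = as.integer(patience),
                 k_neighbors = as.integer(k_neighbors),
                 snn_k = as.integer(snn_k), n_pcs = as.integer(n_pcs),
                 de_min_frac = de_min_frac, n_perm = as.integer(n_perm),
                 target_types = target_types, seed = as.integer(seed)),
            class = "pipeline_config")
}

pipeline_log <- function(log_lines, stage, ...) {
  c(log_lines, sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full annotation and scoring pipeline
#'
#' Stages, in order: QC (cell then gene filters) per condition → atlas
#' homolog translation → normalization → sketch per condition → per-cell
#' atlas correlation → rare-type pruning → pooled pairwise marker panel →
#' SNN cluster tree → consensus dendrogram walk → projection to all cells →
#' per-type condition balancing → Wilcoxon DE between conditions → log2FC
#' ranking → preranked GSEA per gene set → per-cell scoring on leading
#' edges → Kolmogorov–Smirnov comparison of score distributions. Writes
#' per-stage tables plus the resolved config and a structured log to
#' `out_dir`. Re-running with an identical config reproduces identical
#' tables.
#'
#' @param config a [pipeline_config()].
#' @return The output directory, invisibly; key results are also written as
#'   `labels.tsv`, `de.tsv`, `gsea.tsv`, `scores.tsv`, `ks.tsv`,
#'   `qc_report.json`, `config.json`, `log.txt`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stop("'config' must come from pipeline_config()")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logl <- character(0)
  cn <- config$condition_names

  # --- QC per condition, then pool ---------------------------------------
  raw_a <- read_counts_10x(config$counts_dir_a)
  raw_b <- read_counts_10x(config$counts_dir_b)
  if (!identical(rownames(raw_a), rownames(raw_b)))
    stop("the two conditions must share a gene space")
  qa <- filter_cells(raw_a, config$qc)
  qb <- filter_cells(raw_b, config$qc)
  logl <- pipeline_log(logl, "qc", "%s: %d -> %d cells; %s: %d -> %d cells",
                       cn[1], qa$report$n_cells_in, qa$report$n_cells_out,
                       cn[2], qb$report$n_cells_in, qb$report$n_cells_out)
  counts <- cbind(qa$counts, qb$counts)
  condition <- setNames(rep(cn, c(ncol(qa$counts), ncol(qb$counts))),
                        colnames(counts))
  n_genes_before <- nrow(counts)
  counts <- filter_genes(counts, config$qc$min_cells_per_gene)
  logl <- pipeline_log(logl, "qc", "genes: %d -> %d", n_genes_before,
                       nrow(counts))
  if (ncol(counts) == 0L) stop("stage qc: no cells passed the filters")

  # --- atlas, normalization, sketch --------------------------------------
  atlas <- read_atlas_csv(config$atlas_csv)
  hom <- if (is.null(config$homolog_csv)) NULL
         else read_homolog_map(config$homolog_csv)
  atlas <- suppressMessages(
    translate_homologs(atlas, hom, rownames(counts)))
  normalized <- normalize_expression(counts, config$normalization)
  sk_a <- which(condition == cn[1])[
    sketch_sample(counts[, condition == cn[1], drop = FALSE],
                  config$sketch_n, derive_seed(config$seed, 21L))]
  sk_b <- which(condition == cn[2])[
    sketch_sample(counts[, condition == cn[2], drop = FALSE],
                  config$sketch_n, derive_seed(config$seed, 22L))]
  sketch <- c(sk_a, sk_b)
  logl <- pipeline_log(logl, "sketch", "%d + %d cells", length(sk_a),
                       length(sk_b))

  # --- correlation, pruning, panel, tree, walk, projection ----------------
  norm_sketch <- normalized[, sketch, drop = FALSE]
  corr <- correlate_cells(norm_sketch, atlas)
  pruned <- prune_rare_types(corr, config$min_type_frac)
  logl <- pipeline_log(logl, "prune", "%d/%d types retained, %d ambiguous",
                       ncol(pruned$corr), ncol(corr),
                       sum(pruned$labels$label == "ambiguous"))
  panel <- pairwise_marker_panel(norm_sketch, pruned$labels,
                                 top_k = config$top_k)
  tree <- build_cluster_tree(norm_sketch, panel, n_pcs = config$n_pcs,
                             k_neighbors = config$snn_k)
  walked <- consensus_walk(tree, pruned$corr, patience = config$patience,
                           trim = config$trim)
  logl <- pipeline_log(logl, "walk", "converged after %d iterations",
                       attr(walked, "iterations"))
  labels <- project_labels(walked, normalized, panel,
                           k_neighbors = config$k_neighbors,
                           n_pcs = config$n_pcs)

  # --- balancing, DE, GSEA, scoring, KS -----------------------------------
  sets <- read_gmt(config$gmt_path)
  types <- config$target_types %||%
    sort(Reduce(intersect, split(labels$label, condition[labels$barcode])))
  types <- setdiff(types, "ambiguous")
  if (length(types) == 0L) stop("no type present in both conditions")
  balanced <- balance_conditions(labels, condition, types,
                                 derive_seed(config$seed, 31L))
  de_all <- list(); gsea_rows <- list(); score_rows <- list()
  ks_rows <- list()
  for (tt in types) {
    bc <- balanced[labels$label[match(balanced, labels$barcode)] == tt]
    g1 <- bc[condition[bc] == cn[1]]
    g2 <- bc[condition[bc] == cn[2]]
    if (length(g1) < 3L || length(g2) < 3L) next
    de <- wilcoxon_de(normalized, g1, g2, min_frac = config$de_min_frac)
    if (nrow(de) == 0L) next
    de_all[[tt]] <- cbind(cell_type = tt, de)
    ranked <- rank_by_log2fc(de)
    for (sname in names(sets)) {
      gs <- sets[[sname]]
      if (length(intersect(gs$genes, names(ranked))) == 0L ||
          all(names(ranked) %in% gs$genes)) next
      gr <- gsea_preranked(ranked, gs, n_perm = config$n_perm,
                           seed = derive_seed(config$seed, 41L))
      gsea_rows[[paste(tt, sname)]] <- data.frame(
        cell_type = tt, gene_set = sname, es = gr$es,
        p_value = gr$p_value, n_leading_edge = length(gr$leading_edge),
        leading_edge = paste(gr$leading_edge, collapse = ","),
        stringsAsFactors = FALSE)
      sc <- score_cells(normalized[, bc, drop = FALSE], gr$leading_edge)
      score_rows[[paste(tt, sname)]] <- data.frame(
        barcode = names(sc), cell_type = tt, gene_set = sname,
        condition = unname(condition[names(sc)]), score = unname(sc),
        stringsAsFactors = FALSE)
      ks <- ks_compare(sc[condition[names(sc)] == cn[1]],
                       sc[condition[names(sc)] == cn[2]])
      ks_rows[[paste(tt, sname)]] <- data.frame(
        cell_type = tt, gene_set = sname, D = ks$D, p_value = ks$p_value,
        stringsAsFactors = FALSE)
    }
  }
  logl <- pipeline_log(logl, "compare", "%d type x gene-set KS comparisons",
                       length(ks_rows))

  # --- outputs ------------------------------------------------------------
  out <- function(name) file.path(config$out_dir, name)
  lab_out <- labels
  lab_out$condition <- unname(condition[lab_out$barcode])
  write_labels_tsv(lab_out, out("labels.tsv"))
  wt <- function(x, name) utils::write.table(
    do.call(rbind, c(x, list(make.row.names = FALSE))), out(name),
    sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(de_all)) wt(de_all, "de.tsv")
  if (length(gsea_rows)) wt(gsea_rows, "gsea.tsv")
  if (length(score_rows)) wt(score_rows, "scores.tsv")
  if (length(ks_rows)) wt(ks_rows, "ks.tsv")
  jsonlite::write_json(
    list(condition_a = unclass(qa$report), condition_b = unclass(qb$report)),
    out("qc_report.json"), auto_unbox = TRUE, null = "null")
  cfg_json <- unclass(config)
  cfg_json$qc <- unclass(cfg_json$qc)
  jsonlite::write_json(cfg_json, out("config.json"),
                       auto_unbox = TRUE, null = "null")
  writeLines(logl, out("log.txt"))
  invisible(config$out_dir)
}
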