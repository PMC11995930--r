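#' Configuration for the synthetic single-cell data generator
#'
#' The generator emulates the statistical structure the annotation pipeline
#' assumes: discrete cell types drawn from reference profiles, library-size
#' variation, per-entry dropout, doublets, and a dedicated block of
#' mitochondrial genes (named with the `mt-` prefix so QC can find them).
#'
#' @param n_types number of cell types.
#' @param n_genes total number of genes, including the mitochondrial block.
#' @param n_cells_per_type cells simulated per type; scalar or length
#'   `n_types` vector.
#' @param markers_per_type size of the disjoint marker-gene block given to
#'   each type.
#' @param mean_profile_scale scale of the log-normal baseline expression
#'   shared across types.
#' @param type_separation log2 fold-change applied to a type's marker block;
#'   larger values make types easier to tell apart (0 makes all profiles
#'   identical).
#' @param library_size_lognormal `c(meanlog, sdlog)` of the per-cell total
#'   UMI draw.
#' @param dropout_rate probability that any gene/cell entry is zeroed after
#'   sampling.
#' @param doublet_rate probability that a cell is a doublet (its profile is
#'   the average of two distinct type profiles; the first type is kept as the
#'   true label and the truth table flags it).
#' @param mito_gene_count number of reserved `mt-` genes.
#' @param mito_fraction_beta `c(a, b)` shape parameters of the per-cell
#'   mitochondrial UMI fraction.
#' @param seed integer seed; mandatory. All draws flow from it.
#'
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_types = 4L,
                             n_genes = 500L,
                             n_cells_per_type = 250L,
                             markers_per_type = 10L,
                             mean_profile_scale = 5,
                             type_separation = 4,
                             library_size_lognormal = c(log(2500), 0.3),
                             dropout_rate = 0.1,
                             doublet_rate = 0.02,
                             mito_gene_count = 13L,
                             mito_fraction_beta = c(2, 398),
                             seed) {
  if (missing(seed) || is.null(seed))
    stop("a 'seed' is mandatory in generator_config()")
  cfg <- list(n_types = as.integer(n_types),
              n_genes = as.integer(n_genes),
              n_cells_per_type = as.integer(n_cells_per_type),
              markers_per_type = as.integer(markers_per_type),
              mean_profile_scale = mean_profile_scale,
              type_separation = type_separation,
              library_size_lognormal = as.numeric(library_size_lognormal),
              dropout_rate = dropout_rate,
              doublet_rate = doublet_rate,
              mito_gene_count = as.integer(mito_gene_count),
              mito_fraction_beta = as.numeric(mito_fraction_beta),
              seed = as.integer(seed))
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  stopifnot(length(cfg$library_size_lognormal) == 2L,
            length(cfg$mito_fraction_beta) == 2L)
  if (cfg$n_types < 1L) stop("n_types must be >= 1")
  if (cfg$n_genes < 2L) stop("n_genes must be >= 2")
  if (any(cfg$n_cells_per_type < 1L)) stop("n_cells_per_type must be positive")
  if (!(length(cfg$n_cells_per_type) %in% c(1L, cfg$n_types)))
    stop("n_cells_per_type must be scalar or one value per type")
  for (f in c("dropout_rate", "doublet_rate")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop(sprintf("%s must be a fraction in [0, 1]", f))
  }
  if (cfg$mean_profile_scale <= 0) stop("mean_profile_scale must be positive")
  if (cfg$type_separation < 0) stop("type_separation must be nonnegative")
  if (cfg$mito_gene_count < 0) stop("mito_gene_count must be >= 0")
  if (cfg$n_genes < cfg$mito_gene_count + cfg$n_types * cfg$markers_per_type)
    stop("n_genes too small for the marker blocks plus mitochondrial genes")
  if (any(cfg$mito_fraction_beta <= 0)) stop("mito_fraction_beta must be > 0")
  invisible(cfg)
}

#' Generate a synthetic reference atlas
#'
#' Builds one profile per type: a log-normal baseline shared across types,
#' with a disjoint marker block per type scaled up by
#' `2^type_separation`. Mitochondrial genes (`mt-` prefix) sit at the end of
#' the gene space with baseline expression.
#'
#' @param config a [generator_config()].
#' @return A [reference_atlas()] with `config$n_types` entries.
#' @export
make_reference_atlas <- function(config) {
  if (!inherits(config, "generator_config"))
    stop("'config' must be a generator_config")
  n_mt <- config$mito_gene_count
  n_reg <- config$n_genes - n_mt
  gene_ids <- c(sprintf("gene-%04d", seq_len(n_reg)),
                if (n_mt > 0L) sprintf("mt-%d", seq_len(n_mt)))
  withr::with_seed(derive_seed(config$seed, 1L), {
    baseline <- rlnorm(config$n_genes,
                       meanlog = log(config$mean_profile_scale), sdlog = 1)
    profiles <- matrix(baseline, nrow = config$n_genes,
                       ncol = config$n_types)
    for (t in seq_len(config$n_types)) {
      block <- (t - 1L) * config$markers_per_type +
        seq_len(config$markers_per_type)
      profiles[block, t] <- profiles[block, t] * 2^config$type_separation
    }
  })
  reference_atlas(profiles,
                  type_name = sprintf("type-%02d", seq_len(config$n_types)),
                  source = "synthetic", gene_ids = gene_ids)
}

#' Simulate UMI counts for cells drawn from an atlas
#'
#' Each cell is assigned a type (doublets average two distinct type profiles
#' but keep the first type as true label), draws a total library size from
#' the configured log-normal, and its counts come from a single multinomial
#' over all genes in which the mitochondrial block receives a per-cell
#' Beta-distributed share of the mass. Dropout then zeroes each entry
#' independently. With `dropout_rate = 0` every cell's column sum equals its
#' drawn library size exactly.
#'
#' @param atlas a [reference_atlas()] whose gene space matches the config.
#' @param config a [generator_config()].
#' @return A list with `counts` (sparse integer genes x cells matrix) and
#'   `truth`, a data.frame with columns `barcode`, `true_label`, `is_doublet`,
#'   `condition` (NA here), `library_size`; the generating config is attached
#'   as `attr(truth, "params")`.
#' @export
simulate_cells <- function(atlas, config) {
  if (!inherits(atlas, "reference_atlas")) stop("'atlas' must be a reference_atlas")
  if (length(atlas) == 0L) stop("atlas is empty")
  if (length(atlas$gene_ids) != config$n_genes)
    stop("atlas gene space does not match config$n_genes")
  n_per <- rep_len(config$n_cells_per_type, config$n_types)
  n_cells <- sum(n_per)
  types <- atlas$type_name
  true_label <- rep(types, times = n_per)
  mt_idx <- mito_gene_index(atlas$gene_ids)

  withr::with_seed(derive_seed(config$seed, 2L), {
    is_doublet <- runif(n_cells) < config$doublet_rate &
      config$n_types > 1L
    lib <- pmax(1, round(rlnorm(n_cells,
                                config$library_size_lognormal[1],
                                config$library_size_lognormal[2])))
    mito_frac <- rbeta(n_cells, config$mito_fraction_beta[1],
                       config$mito_fraction_beta[2])
    partner <- integer(n_cells)
    type_of <- match(true_label, types)
    for (i in which(is_doublet)) {
      partner[i] <- sample(setdiff(seq_along(types), type_of[i]), 1L)
    }
    counts <- matrix(0L, nrow = config$n_genes, ncol = n_cells)
    for (i in seq_len(n_cells)) {
      prof <- atlas$profiles[, type_of[i]]
      if (is_doublet[i])
        prof <- (prof + atlas$profiles[, partner[i]]) / 2
      p <- prof
      if (length(mt_idx) > 0L) {
        p_mt <- prof[mt_idx]
        p_rest <- prof[-mt_idx]
        p[mt_idx] <- mito_frac[i] * p_mt / sum(p_mt)
        p[-mt_idx] <- (1 - mito_frac[i]) * p_rest / sum(p_rest)
      } else {
        p <- p / sum(p)
      }
      counts[, i] <- rmultinom(1L, size = lib[i], prob = p)
    }
    if (config$dropout_rate > 0) {
      keep <- matrix(runif(length(counts)) >= config$dropout_rate,
                     nrow = nrow(counts))
      counts <- counts * keep
    }
  })

  barcodes <- sprintf("cell-%05d", seq_len(n_cells))
  dimnames(counts) <- list(atlas$gene_ids, barcodes)
  truth <- data.frame(barcode = barcodes,
                      true_label = true_label,
                      is_doublet = is_doublet,
                      condition = NA_character_,
                      library_size = as.integer(lib),
                      stringsAsFactors = FALSE)
  attr(truth, "params") <- config
  list(counts = as(Matrix(counts, sparse = TRUE), "CsparseMatrix"),
       truth = truth)
}

#' Simulate a two-condition dataset with a signature-gene shift
#'
#' Condition A is drawn from the atlas as-is; condition B from a copy of the
#' atlas in which the given signature genes' profile means are multiplied by
#' `2^shift_log2fc` before sampling. With `shift_log2fc = 0` the two
#' conditions are exchangeable draws from the same distribution.
#'
#' @param atlas a [reference_atlas()].
#' @param config a [generator_config()]; each condition gets its own seed
#'   derived from `config$seed`.
#' @param signature_genes character vector of genes to shift; must all be in
#'   the atlas gene space.
#' @param shift_log2fc log2 fold-change applied in condition B.
#' @return A list `counts_a`, `counts_b`, `truth_a`, `truth_b`; barcodes are
#'   suffixed `-A` / `-B` and the truth tables carry the condition.
#' @export
simulate_condition_pair <- function(atlas, config, signature_genes,
                                    shift_log2fc) {
  missing_genes <- setdiff(signature_genes, atlas$gene_ids)
  if (length(missing_genes) > 0L)
    stop("unknown signature gene(s): ", paste(missing_genes, collapse = ", "))
  atlas_b <- atlas
  idx <- match(signature_genes, atlas$gene_ids)
  atlas_b$profiles[idx, ] <- atlas_b$profiles[idx, ] * 2^shift_log2fc

  cfg_a <- config; cfg_a$seed <- derive_seed(config$seed, 11L)
  cfg_b <- config; cfg_b$seed <- derive_seed(config$seed, 12L)
  class(cfg_a) <- class(cfg_b) <- "generator_config"
  a <- simulate_cells(atlas, cfg_a)
  b <- simulate_cells(atlas_b, cfg_b)
  relabel <- function(sim, cond) {
    bc <- paste0(sim$truth$barcode, "-", cond)
    colnames(sim$counts) <- bc
    sim$truth$barcode <- bc
    sim$truth$condition <- cond
    sim
  }
  a <- relabel(a, "A"); b <- relabel(b, "B")
  list(counts_a = a$counts, counts_b = b$counts,
       truth_a = a$truth, truth_b = b$truth)
}
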