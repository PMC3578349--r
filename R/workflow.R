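#' Build and validate a run configuration
#'
#' The configuration binds the analytic stages into the two supported
#' workflows: `"within"` (preprocess -> PCA -> enrichment within one species)
#' and `"between"` (preprocess -> cross-species comparison -> report). Unknown
#' keys are rejected before any computation. A configuration can come from a
#' YAML file ([read_run_config()]); explicit arguments override file values.
#'
#' @param workflow `"within"` or `"between"`.
#' @param simulation A [sim_config()] (the workflows run on simulated inputs
#'   when no file paths are given) or NULL.
#' @param paths Named list of input file paths (expression/annotation TSVs,
#'   markers, homology, correspondence) or NULL to simulate.
#' @param filter_quantile Low-signal filter quantile, default 0.25.
#' @param anchor_genes Anchor gene IDs for component orientation; NULL uses the
#'   oligodendrocyte marker set of the inputs.
#' @param directions Named map of cell type to `"+"`/`"-"` for enrichment.
#' @param n_top Genes per extracted pattern set, default 25.
#' @param n_shuffles Gene-label shuffles for the permutation null, default 20.
#' @param rho_threshold Threshold for the excess-count comparison, default 0.3.
#' @param seed Integer seed for every stochastic stage.
#' @param out_dir Output directory, or NULL to keep results in memory only.
#' @return Validated list of class `run_config`.
#' @export
run_config <- function(workflow = c("within", "between"),
                       simulation = NULL,
                       paths = NULL,
                       filter_quantile = 0.25,
                       anchor_genes = NULL,
                       directions = c(neuron = "-", oligodendrocyte = "+"),
                       n_top = 25L,
                       n_shuffles = 20L,
                       rho_threshold = 0.30,
                       seed = 1L,
                       out_dir = NULL) {
  workflow <- match.arg(workflow)
  if (is.null(simulation) && is.null(paths)) {
    simulation <- sim_config(seed = seed)
  }
  if (!is.null(simulation) && !inherits(simulation, "sim_config")) {
    simulation <- do.call(sim_config, simulation)
  }
  stopifnot(filter_quantile > 0, filter_quantile < 1, n_shuffles >= 1)
  structure(list(workflow = workflow, simulation = simulation, paths = paths,
                 filter_quantile = filter_quantile,
                 anchor_genes = anchor_genes, directions = directions,
                 n_top = as.integer(n_top),
                 n_shuffles = as.integer(n_shuffles),
                 rho_threshold = rho_threshold, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected with their names.
#'
#' @param path YAML file.
#' @param ... Overrides applied after the file is read (highest precedence).
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  allowed <- setdiff(names(formals(run_config)), "...")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  overrides <- list(...)
  raw[names(overrides)] <- overrides
  do.call(run_config, raw)
}

#' Run a configured workflow
#'
#' Dispatches to [run_within_workflow()] or [run_between_workflow()]; every
#' intermediate is persisted under `out_dir` when one is set.
#'
#' @param config A `run_config`.
#' @return The workflow result list (including `report`).
#' @export
run_workflow <- function(config) {
  stopifnot(inherits(config, "run_config"))
  switch(config$workflow,
         within = run_within_workflow(config),
         between = run_between_workflow(config))
}

load_single_dataset <- function(config) {
  if (!is.null(config$paths)) {
    list(expression = read_expression_tsv(config$paths$expression),
         annotations = read_table_tsv(config$paths$annotations),
         markers = read_markers_tsv(config$paths$markers),
         truth = NULL)
  } else {
    simulate_expression(config$simulation)
  }
}

#' Within-species workflow: preprocessing, PCA patterns, marker enrichment
#'
#' Averages replicates, excludes white-matter samples, filters low-signal
#' genes, standardizes genes, runs PCA oriented so the oligodendrocyte anchor
#' set scores positive on the first component, extracts the top pattern sets,
#' the averaged-pattern anti-correlation, per-region marker ratios, the
#' per-division loading summary, and per-cell-type AUC enrichment.
#'
#' @param config A `run_config` with `workflow = "within"`.
#' @return List with the stage outputs (`pca`, `enrichment`, `patterns`,
#'   `report`, ...); intermediates written under `config$out_dir` when set.
#' @export
run_within_workflow <- function(config) {
  ds <- load_single_dataset(config)
  dims <- list(input = dim(ds$expression))

  avg <- average_replicates(ds$expression, ds$annotations)
  mat <- exclude_samples(avg$matrix, avg$annotations)
  region_ann <- avg$annotations[avg$annotations$sample_id %in% colnames(mat), ,
                                drop = FALSE]
  dims$regions <- dim(mat)

  complete <- !apply(mat, 1, anyNA)
  mat_complete <- mat[complete, , drop = FALSE]
  dims$complete_genes <- nrow(mat_complete)

  filt <- filter_low_signal(mat_complete, config$filter_quantile)
  scaled <- zscore_genes(filt$matrix)
  dims$filtered <- dim(filt$matrix)

  pca <- run_pca(scaled)
  anchor <- config$anchor_genes %||% ds$markers$oligodendrocyte
  pca <- orient_components(pca, anchor)

  sets <- top_pattern_sets(pca, min(config$n_top, nrow(scaled)),
                           raw_matrix = filt$matrix)
  scores <- stats::setNames(pca$gene_scores[, 1], rownames(pca$gene_scores))
  enr <- enrich_all(scores, ds$markers, config$directions)

  prof_o <- averaged_pattern(scaled,
                             intersect(ds$markers$oligodendrocyte,
                                       rownames(scaled)),
                             id = "oligodendrocyte")
  prof_n <- averaged_pattern(scaled,
                             intersect(ds$markers$neuron, rownames(scaled)),
                             id = "neuron")
  anti <- pattern_anticorrelation(prof_n, prof_o)
  ratio <- suppressWarnings(
    marker_ratio_by_region(filt$matrix,
                           intersect(ds$markers$oligodendrocyte,
                                     rownames(filt$matrix)),
                           intersect(ds$markers$neuron,
                                     rownames(filt$matrix))))
  div_sum <- division_loading_summary(pca, region_ann)

  report <- run_report(list(
    dimensions = dims,
    filter_report = unclass(filt$report),
    variance_fraction = utils::head(pca$variance_fraction, 3),
    enrichment = enr,
    anticorrelation = anti,
    division_summary = div_sum
  ), config = strip_config(config), seed = config$seed)

  out <- list(dataset = ds, matrix = filt$matrix, scaled = scaled, pca = pca,
              pattern_sets = sets, enrichment = enr, anticorrelation = anti,
              marker_ratio = ratio, division_summary = div_sum,
              filter_report = filt$report, report = report)
  persist_within(out, config)
  out
}

#' Between-species workflow: matched matrices and conservation statistics
#'
#' Aggregates each species to common parent structures, matches homologous
#' genes, jointly quantile-normalizes, applies the joint expression filter,
#' and computes per-gene and per-region Spearman correlations with BH
#' q-values, the gene-label permutation null, and the threshold-excess
#' comparison.
#'
#' @param config A `run_config` with `workflow = "between"`.
#' @return List with stage outputs (`matched`, `gene_cor`, `region_cor`,
#'   `null`, `excess`, `report`, ...).
#' @export
run_between_workflow <- function(config) {
  if (!is.null(config$paths)) {
    a <- list(expression = read_expression_tsv(config$paths$expression_a),
              annotations = read_table_tsv(config$paths$annotations_a))
    b <- list(expression = read_expression_tsv(config$paths$expression_b),
              annotations = read_table_tsv(config$paths$annotations_b))
    homology <- read_table_tsv(config$paths$homology)
    correspondence <- read_table_tsv(config$paths$correspondence)
    discordant <- character()
  } else {
    pair <- simulate_species_pair(config$simulation)
    a <- pair$a
    b <- pair$b
    homology <- pair$homology
    correspondence <- pair$correspondence
    discordant <- pair$discordant_genes
  }
  dims <- list(input_a = dim(a$expression), input_b = dim(b$expression))

  avg_a <- average_replicates(a$expression, a$annotations)
  avg_b <- average_replicates(b$expression, b$annotations)
  par_a <- aggregate_to_parents(avg_a$matrix, avg_a$annotations,
                                correspondence[correspondence$species == "a", ])
  par_b <- aggregate_to_parents(avg_b$matrix, avg_b$annotations,
                                correspondence[correspondence$species == "b", ])
  matched <- match_matrices(par_a, par_b, homology)
  dims$matched <- dim(matched$a)

  normed <- quantile_normalize_joint(matched$a, matched$b)
  filt <- joint_expression_filter(normed$a, normed$b, config$filter_quantile)
  dims$filtered <- dim(filt$a)
  pairs <- unique(matched$pairs[matched$pairs$group %in% rownames(filt$a),
                                c("species_a_gene", "species_b_gene", "group")])
  names(pairs) <- c("gene_a", "gene_b", "group")
  # one-to-one over simulated data; on many-to-many maps the first pair of a
  # group labels the averaged row
  pairs <- pairs[match(rownames(filt$a), pairs$group), , drop = FALSE]

  gene_cor <- gene_correlations(filt$a, filt$b, pairs = pairs)
  region_cor <- region_correlations(filt$a, filt$b)
  null <- permutation_null(filt$a, filt$b, n_shuffles = config$n_shuffles,
                           seed = config$seed)
  excess <- threshold_excess(gene_cor$rho, null,
                             threshold = config$rho_threshold)

  report <- run_report(list(
    dimensions = dims,
    cross_species = list(
      n_genes = nrow(gene_cor),
      n_regions = ncol(filt$a),
      gene_rho_mean = mean(gene_cor$rho, na.rm = TRUE),
      region_rho_mean = attr(region_cor, "mean_rho"),
      region_rho_sd = attr(region_cor, "sd_rho"),
      n_q_below_0.05 = sum(gene_cor$q < 0.05, na.rm = TRUE)
    ),
    null_comparison = c(list(n_shuffles = null$n_shuffles,
                             null_rho_mean = mean(null$rho, na.rm = TRUE)),
                        excess)
  ), config = strip_config(config), seed = config$seed)

  out <- list(matched = matched, normalized = normed, filtered = filt,
              pairs = pairs, gene_cor = gene_cor, region_cor = region_cor,
              null = null, excess = excess, discordant_genes = discordant,
              report = report)
  persist_between(out, config)
  out
}

# configuration as hashed into reports: drop non-semantic fields
strip_config <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  if (!is.null(cfg$simulation)) cfg$simulation <- unclass(cfg$simulation)
  cfg
}

persist_within <- function(out, config) {
  dir <- config$out_dir
  if (is.null(dir)) return(invisible(NULL))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_tsv(out$scaled, file.path(dir, "scaled_matrix.tsv"))
  gene_tab <- data.frame(gene = rownames(out$pca$gene_scores),
                         out$pca$gene_scores[, seq_len(min(3,
                           ncol(out$pca$gene_scores))), drop = FALSE],
                         check.names = FALSE)
  write_table_tsv(gene_tab, file.path(dir, "gene_scores.tsv"))
  load_tab <- data.frame(region = rownames(out$pca$region_loadings),
                         out$pca$region_loadings[, seq_len(min(3,
                           ncol(out$pca$region_loadings))), drop = FALSE],
                         check.names = FALSE)
  write_table_tsv(load_tab, file.path(dir, "region_loadings.tsv"))
  write_table_tsv(out$enrichment, file.path(dir, "enrichment.tsv"))
  write_table_tsv(out$division_summary, file.path(dir, "division_summary.tsv"))
  write_report(out$report, file.path(dir, "report.json"))
  invisible(dir)
}

persist_between <- function(out, config) {
  dir <- config$out_dir
  if (is.null(dir)) return(invisible(NULL))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_tsv(out$filtered$a, file.path(dir, "matched_a.tsv"))
  write_expression_tsv(out$filtered$b, file.path(dir, "matched_b.tsv"))
  write_table_tsv(out$gene_cor, file.path(dir, "gene_correlations.tsv"))
  write_table_tsv(out$region_cor, file.path(dir, "region_correlations.tsv"))
  jsonlite::write_json(out$excess, file.path(dir, "null_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  write_report(out$report, file.path(dir, "report.json"))
  invisible(dir)
}
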