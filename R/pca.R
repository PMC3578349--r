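#' Principal components of a standardized gene x region matrix
#'
#' Genes are the observations and regions the variables, so each gene receives
#' a score on every component ("x" of the decomposition) and each region a
#' loading ("rotation"). Computed via [stats::prcomp()] with column centring
#' and no further scaling; all `min(n_genes, n_regions)` components are
#' retained so variance fractions sum to 1.
#'
#' @param scaled_matrix Gene x region matrix, standardized per gene, with no
#'   missing values.
#' @return An object of class `pca_result`: `gene_scores` (genes x components),
#'   `region_loadings` (regions x components), `variance_fraction`,
#'   `orientation` (per-component sign multiplier applied so far), `anchor`
#'   (anchor genes used to orient, if any), and `center` (per-region column
#'   means, for reconstruction).
#' @export
run_pca <- function(scaled_matrix) {
  n_miss <- sum(is.na(scaled_matrix))
  if (n_miss > 0) {
    stop("PCA input contains ", n_miss, " missing value(s); ",
         "drop or complete those genes first")
  }
  p <- stats::prcomp(scaled_matrix, center = TRUE, scale. = FALSE)
  vf <- p$sdev^2 / sum(p$sdev^2)
  structure(list(
    gene_scores = p$x,
    region_loadings = p$rotation,
    variance_fraction = vf,
    orientation = rep(1, length(vf)),
    anchor = NULL,
    center = p$center
  ), class = "pca_result")
}

#' Orient a component by an anchor gene set
#'
#' Enforces the sign convention that a chosen anchor set (classically the
#' oligodendrocyte marker MOBP) has a positive mean score on the component: if
#' the mean score of the anchor genes present is negative, the component's gene
#' scores and region loadings are both multiplied by -1. Idempotent.
#'
#' @param result A `pca_result`.
#' @param anchor_genes Character vector of gene IDs; at least one must be
#'   present among the scored genes.
#' @param component Component index to orient (default 1).
#' @return The (possibly flipped) `pca_result` with `orientation` and `anchor`
#'   updated.
#' @export
orient_components <- function(result, anchor_genes, component = 1L) {
  stopifnot(inherits(result, "pca_result"))
  present <- intersect(anchor_genes, rownames(result$gene_scores))
  if (length(present) == 0) {
    stop("none of the anchor genes are present in the PCA gene scores")
  }
  m <- mean(result$gene_scores[present, component])
  if (m < 0) {
    result$gene_scores[, component] <- -result$gene_scores[, component]
    result$region_loadings[, component] <- -result$region_loadings[, component]
    result$orientation[component] <- -result$orientation[component]
  }
  result$anchor <- present
  result
}

#' Extract the oligodendrocyte- and neuron-enriched gene sets
#'
#' The n most-positive genes on the oriented first component form the
#' oligodendrocyte-enriched set and the n most-negative the neuron-enriched
#' set; ties in score are broken lexicographically by gene ID. When the
#' pre-standardization matrix is supplied, each table also reports the gene's
#' mean and SD expression.
#'
#' @param result An oriented `pca_result`.
#' @param n Genes per set.
#' @param raw_matrix Optional gene x region matrix on the original expression
#'   scale used for the mean/SD columns.
#' @param component Component index, default 1.
#' @return List with data.frames `oligodendrocyte` and `neuron` (columns gene,
#'   score, and optionally mean, sd), each of n rows.
#' @export
top_pattern_sets <- function(result, n, raw_matrix = NULL, component = 1L) {
  stopifnot(inherits(result, "pca_result"))
  scores <- result$gene_scores[, component]
  if (n > length(scores)) stop("n exceeds the number of scored genes")
  genes <- rownames(result$gene_scores)
  take <- function(decreasing) {
    ord <- order(if (decreasing) -scores else scores, genes)
    sel <- ord[seq_len(n)]
    df <- data.frame(gene = genes[sel], score = scores[sel],
                     stringsAsFactors = FALSE)
    if (!is.null(raw_matrix)) {
      rows <- raw_matrix[df$gene, , drop = FALSE]
      df$mean <- rowMeans(rows, na.rm = TRUE)
      df$sd <- apply(rows, 1, stats::sd, na.rm = TRUE)
    }
    rownames(df) <- NULL
    df
  }
  list(oligodendrocyte = take(TRUE), neuron = take(FALSE))
}

#' Average the regional expression of a gene set
#'
#' Per-region unweighted mean over the set genes present in the matrix
#' (non-missing values); genes absent from the matrix are dropped and counted.
#'
#' @param matrix Gene x region matrix.
#' @param gene_set Character vector of gene IDs; at least one must be present.
#' @param id Optional label for the profile.
#' @return A list of class `pattern_profile`: `values` (named per-region
#'   means), `gene_set_id`, `n_genes` (genes averaged), `n_missing` (genes of
#'   the set absent from the matrix).
#' @export
averaged_pattern <- function(matrix, gene_set, id = NULL) {
  present <- intersect(gene_set, rownames(matrix))
  if (length(present) == 0) {
    stop("no gene of the set is present in the matrix; missing: ",
         paste(utils::head(gene_set, 10), collapse = ", "))
  }
  vals <- colMeans(matrix[present, , drop = FALSE], na.rm = TRUE)
  structure(list(values = vals, gene_set_id = id %||% "gene_set",
                 n_genes = length(present),
                 n_missing = length(gene_set) - length(present)),
            class = "pattern_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Spearman anti-correlation between two pattern profiles
#'
#' @param a,b `pattern_profile`s over the same regions (>= 3).
#' @return List with `rho`, `p` (two-sided, t-approximation), `n_used`.
#' @export
pattern_anticorrelation <- function(a, b) {
  stopifnot(inherits(a, "pattern_profile"), inherits(b, "pattern_profile"))
  if (!identical(names(a$values), names(b$values))) {
    stop("profiles cover different region sets")
  }
  if (length(a$values) < 3) stop("need at least 3 regions")
  res <- spearman(a$values, b$values, min_overlap = 3)
  res[c("rho", "p", "n_used")]
}

#' Per-region oligodendrocyte/neuron marker expression ratio
#'
#' The ratio of the averaged oligodendrocyte-set pattern to the averaged
#' neuron-set pattern in each region; regions whose neuron-set mean is zero or
#' negative get NA with a warning.
#'
#' @param matrix Gene x region matrix (original expression scale).
#' @param oligo_set,neuron_set Gene-ID vectors, each with at least one gene in
#'   the matrix.
#' @return Named numeric vector of per-region ratios.
#' @export
marker_ratio_by_region <- function(matrix, oligo_set, neuron_set) {
  o <- averaged_pattern(matrix, oligo_set, "oligodendrocyte")$values
  n <- averaged_pattern(matrix, neuron_set, "neuron")$values
  bad <- !is.na(n) & n <= 0
  ratio <- o / n
  if (any(bad)) {
    ratio[bad] <- NA_real_
    warning("ratio undefined (non-positive neuron mean) in region(s): ",
            paste(names(n)[bad], collapse = ", "))
  }
  ratio
}

#' Summarise first-component region loadings by brain division
#'
#' @param result A `pca_result` whose region loadings are named by region.
#' @param annotations Data.frame with one row per region (`sample_id` matching
#'   the loading names) and a `division` column.
#' @param component Component index, default 1.
#' @return Data.frame keyed by division with `mean`, `sd` (NA for single-region
#'   divisions) and `n`.
#' @export
division_loading_summary <- function(result, annotations, component = 1L) {
  stopifnot(inherits(result, "pca_result"))
  if (is.null(annotations) || nrow(annotations) == 0) {
    stop("empty annotation table")
  }
  regions <- rownames(result$region_loadings)
  div <- annotations$division[match(regions, annotations$sample_id)]
  if (anyNA(div)) {
    stop("regions lacking a division annotation: ",
         paste(utils::head(regions[is.na(div)], 5), collapse = ", "))
  }
  loads <- result$region_loadings[, component]
  agg <- do.call(rbind, lapply(split(loads, div), function(x) {
    data.frame(mean = mean(x),
               sd = if (length(x) > 1) stats::sd(x) else NA_real_,
               n = length(x))
  }))
  data.frame(division = rownames(agg), agg, row.names = NULL,
             stringsAsFactors = FALSE)
}
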