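#' Hierarchical clustering of brain regions
#'
#' Agglomerative clustering of the region columns with Euclidean distances and
#' Ward's minimum variance criterion (`hclust` method `"ward.D2"`, so merge
#' heights are on the distance scale and non-decreasing). Deterministic given
#' the input column order; equal-distance merges follow `hclust`'s
#' lowest-index convention.
#'
#' @param matrix Gene x region matrix without missing values.
#' @return An [stats::hclust] object over the region columns.
#' @export
cluster_regions <- function(matrix) {
  n_miss <- sum(is.na(matrix))
  if (n_miss > 0) stop("matrix contains ", n_miss, " missing value(s)")
  stats::hclust(stats::dist(t(matrix), method = "euclidean"),
                method = "ward.D2")
}

#' Serialize a dendrogram as Newick
#'
#' @param hc An [stats::hclust] object.
#' @param path Optional file path; when NULL the Newick string is returned.
#' @return The Newick string (invisibly when written to file).
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Correlate per-gene scores with an external covariate
#'
#' Spearman correlation over the gene intersection between a score vector
#' (for example oriented first-component gene scores) and an external per-gene
#' covariate such as a white-matter/gray-matter transcript ratio.
#'
#' @param scores Named numeric vector of per-gene scores.
#' @param covariate Named numeric vector (or two-column data.frame gene, value)
#'   of external per-gene values.
#' @param min_overlap Minimum shared genes, default 5.
#' @return List: `rho`, `p`, `n_genes`.
#' @export
covariate_correlation <- function(scores, covariate, min_overlap = 5L) {
  if (is.data.frame(covariate)) {
    covariate <- stats::setNames(covariate[[2]], covariate[[1]])
  }
  shared <- intersect(names(scores), names(covariate))
  if (length(shared) == 0) stop("no shared genes between scores and covariate")
  if (length(shared) < min_overlap) {
    stop("fewer than ", min_overlap, " shared genes")
  }
  r <- spearman(scores[shared], covariate[shared], min_overlap = min_overlap)
  list(rho = r$rho, p = r$p, n_genes = r$n_used)
}

#' Overlap of an external gene list with negative cross-species correlations
#'
#' Over the genes shared between the correlation records and an external list
#' of putatively discordant genes, counts how many are negatively correlated
#' and how many meet the stated threshold.
#'
#' @param records Data.frame from [gene_correlations()] (needs gene_a and rho).
#' @param gene_list Character vector of external gene IDs (species-A IDs).
#' @param threshold Threshold on rho, default -0.30 (counted as rho <=
#'   threshold).
#' @return List: `n_negative` (rho < 0), `n_below_threshold` (rho <=
#'   threshold), `n_shared`.
#' @export
external_list_overlap <- function(records, gene_list, threshold = -0.30) {
  hit <- records[records$gene_a %in% gene_list & !is.na(records$rho), ,
                 drop = FALSE]
  list(n_negative = sum(hit$rho < 0),
       n_below_threshold = sum(hit$rho <= threshold),
       n_shared = nrow(hit))
}

#' Consolidated run report
#'
#' Assembles the persisted outputs of a workflow run into one JSON-ready
#' structure: stage dimensions, filter reports, variance fractions, enrichment
#' results, pattern anti-correlation, per-division loading summary,
#' cross-species summaries, the null comparison, and the seed/configuration
#' fingerprint. Sections whose stage output is missing are marked absent, not
#' fabricated.
#'
#' @param stages Named list of stage outputs (any of `dimensions`,
#'   `filter_report`, `variance_fraction`, `enrichment`, `anticorrelation`,
#'   `division_summary`, `cross_species`, `null_comparison`).
#' @param config The run configuration list (hashed into the report).
#' @param seed The run seed.
#' @return List of class `run_report`, serializable with
#'   [jsonlite::write_json()].
#' @export
run_report <- function(stages, config = list(), seed = NA_integer_) {
  section <- function(name) {
    if (is.null(stages[[name]])) list(absent = TRUE) else stages[[name]]
  }
  rep <- list(
    generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config_hash = config_hash(jsonlite::toJSON(config, auto_unbox = TRUE,
                                               digits = NA)),
    dimensions = section("dimensions"),
    filter_report = section("filter_report"),
    variance_fraction = section("variance_fraction"),
    enrichment = section("enrichment"),
    anticorrelation = section("anticorrelation"),
    division_summary = section("division_summary"),
    cross_species = section("cross_species"),
    null_comparison = section("null_comparison")
  )
  structure(rep, class = c("run_report", "list"))
}

# deterministic polynomial rolling hash over the UTF-8 bytes (8 hex digits);
# only used as a configuration fingerprint, not for cryptographic purposes
config_hash <- function(x) {
  bytes <- as.integer(charToRaw(as.character(x)))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write a run report as JSON
#'
#' @param report A `run_report`.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
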