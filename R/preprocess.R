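#' Collapse probe-level rows to gene level
#'
#' Multiple probes mapping to the same gene are combined by the arithmetic
#' mean, computed per sample over non-missing values. Probes without a gene
#' assignment are dropped.
#'
#' @param matrix Probe x sample matrix (probe IDs as rownames).
#' @param probe_to_gene Named character vector or two-column data.frame
#'   (probe_id, gene_id) mapping each probe to at most one gene.
#' @return Gene x sample matrix with unique gene rownames.
#' @export
collapse_probes <- function(matrix, probe_to_gene) {
  if (is.data.frame(probe_to_gene)) {
    probe_to_gene <- stats::setNames(probe_to_gene[[2]], probe_to_gene[[1]])
  }
  if (length(probe_to_gene) == 0) stop("empty probe-to-gene mapping")
  if (anyDuplicated(names(probe_to_gene))) {
    stop("a probe has more than one gene assignment")
  }
  keep <- rownames(matrix) %in% names(probe_to_gene)
  m <- matrix[keep, , drop = FALSE]
  genes <- unname(probe_to_gene[rownames(m)])
  out <- rowsum_mean(m, genes)
  out[sort(rownames(out)), , drop = FALSE]
}

# group rows by `groups` and take per-column means over non-missing values
rowsum_mean <- function(m, groups) {
  present <- !is.na(m)
  m0 <- m
  m0[!present] <- 0
  sums <- rowsum(m0, groups)
  counts <- rowsum(present + 0, groups)
  out <- sums / counts
  out[counts == 0] <- NA_real_
  out
}

#' Average replicate samples sharing a structure name
#'
#' Columns annotated with the same `structure_name` are averaged (per gene,
#' over non-missing values); left- and right-hemisphere samples stay separate
#' whenever their structure names differ. Returns one column per distinct
#' structure name, in order of first appearance, together with region-level
#' annotations.
#'
#' @param matrix Gene x sample matrix.
#' @param annotations Per-sample data.frame covering every column, with at
#'   least `sample_id` and `structure_name` (optionally `parent_structure`,
#'   `division`, `hemisphere`, `is_white_matter`).
#' @return List with `matrix` (gene x structure) and `annotations` (one row per
#'   structure; `sample_id` set to the structure name).
#' @export
average_replicates <- function(matrix, annotations) {
  ann <- annotations[match(colnames(matrix), annotations$sample_id), ,
                     drop = FALSE]
  if (anyNA(ann$sample_id)) {
    stop("annotations do not cover samples: ",
         paste(setdiff(colnames(matrix), annotations$sample_id),
               collapse = ", "))
  }
  structs <- unique(ann$structure_name)
  for (col in intersect(c("parent_structure", "division", "is_white_matter"),
                        names(ann))) {
    n_lab <- tapply(ann[[col]], ann$structure_name,
                    function(x) length(unique(x)))
    if (any(n_lab > 1)) {
      stop("conflicting '", col, "' labels within structure name(s): ",
           paste(names(n_lab)[n_lab > 1], collapse = ", "))
    }
  }
  out <- t(rowsum_mean(t(matrix), ann$structure_name))
  out <- out[, structs, drop = FALSE]
  first <- ann[!duplicated(ann$structure_name), , drop = FALSE]
  first <- first[match(structs, first$structure_name), , drop = FALSE]
  first$sample_id <- first$structure_name
  if ("hemisphere" %in% names(first)) {
    multi <- tapply(ann$hemisphere, ann$structure_name,
                    function(x) length(unique(x))) > 1
    first$hemisphere[multi[first$structure_name]] <- NA_character_
  }
  rownames(first) <- NULL
  list(matrix = out, annotations = first)
}

#' Drop flagged samples (white-matter exclusion)
#'
#' Removes every column whose annotation satisfies the predicate (by default
#' the `is_white_matter` flag); remaining columns keep their order and values.
#'
#' @param matrix Gene x sample matrix.
#' @param annotations Per-sample annotation data.frame.
#' @param predicate Name of a logical annotation column, default
#'   `"is_white_matter"`.
#' @return The matrix without the flagged columns.
#' @export
exclude_samples <- function(matrix, annotations,
                            predicate = "is_white_matter") {
  ann <- annotations[match(colnames(matrix), annotations$sample_id), ,
                     drop = FALSE]
  flag <- isTRUE_vec(ann[[predicate]])
  out <- matrix[, !flag, drop = FALSE]
  if (ncol(out) == 0) stop("all samples excluded by '", predicate, "'")
  out
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Filter low-signal genes
#'
#' Removes regionally uninformative genes: per-gene mean and standard deviation
#' are computed across samples (non-missing values, n-1 SD); the thresholds are
#' the given quantile (linear interpolation of order statistics, R type 7) of
#' the per-gene mean distribution and of the per-gene SD distribution, both
#' computed on the full pre-filter gene set. A gene is removed if its mean is
#' strictly below the mean threshold OR its SD is strictly below the SD
#' threshold; ties at a threshold are kept. Genes with fewer than 3 non-missing
#' samples are removed beforehand.
#'
#' @param matrix Gene x sample matrix with >= 2 samples.
#' @param quantile Quantile in (0, 1), default 0.25.
#' @return List with `matrix` (retained genes) and `report` (class
#'   `filter_report`: quantile, mean_threshold, sd_threshold, n_retained,
#'   n_removed, n_low_coverage).
#' @export
filter_low_signal <- function(matrix, quantile = 0.25) {
  if (!is.numeric(quantile) || length(quantile) != 1 ||
      quantile <= 0 || quantile >= 1) {
    stop("quantile must be in (0, 1)")
  }
  n_input <- nrow(matrix)
  n_obs <- rowSums(!is.na(matrix))
  low_cov <- n_obs < 3
  m <- matrix[!low_cov, , drop = FALSE]
  means <- rowMeans(m, na.rm = TRUE)
  sds <- apply(m, 1, stats::sd, na.rm = TRUE)
  mean_thr <- stats::quantile(means, quantile, type = 7, names = FALSE)
  sd_thr <- stats::quantile(sds, quantile, type = 7, names = FALSE)
  drop <- means < mean_thr | sds < sd_thr
  out <- m[!drop, , drop = FALSE]
  report <- structure(list(
    quantile = quantile,
    mean_threshold = mean_thr,
    sd_threshold = sd_thr,
    n_retained = nrow(out),
    n_removed = n_input - nrow(out),
    n_low_coverage = sum(low_cov)
  ), class = "filter_report")
  list(matrix = out, report = report)
}

#' Standardize each gene across samples
#'
#' Mean-centres and scales every gene row to unit standard deviation (n-1
#' denominator) over its non-missing entries. Idempotent; errors on any
#' constant gene, naming it.
#'
#' @param matrix Gene x sample matrix.
#' @return Matrix of the same shape with per-row mean 0 and SD 1.
#' @export
zscore_genes <- function(matrix) {
  means <- rowMeans(matrix, na.rm = TRUE)
  sds <- apply(matrix, 1, stats::sd, na.rm = TRUE)
  bad <- is.na(sds) | sds == 0
  if (any(bad)) {
    stop("zero-SD gene(s): ",
         paste(utils::head(rownames(matrix)[bad], 5), collapse = ", "))
  }
  (matrix - means) / sds
}
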