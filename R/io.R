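#' Read and write the pipeline's TSV dialects
#'
#' Expression matrices are stored genes-as-rows with a `gene_id` first column
#' and one column per sample; missing values are written as "NA". Annotation,
#' marker, homology and region-correspondence tables are plain TSVs with a
#' header row. Ragged rows are a hard parse error (the line is named in the
#' message raised by the reader).
#'
#' @param path File path.
#' @name io_tsv
NULL

#' @rdname io_tsv
#' @param matrix Numeric matrix with gene IDs as rownames and sample IDs as
#'   colnames.
#' @export
write_expression_tsv <- function(matrix, path) {
  df <- data.frame(gene_id = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname io_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          fill = FALSE)
  if (!"gene_id" %in% names(df)) stop("expression TSV lacks a gene_id column")
  if (anyDuplicated(df$gene_id)) stop("duplicate gene IDs in ", path)
  m <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$gene_id
  m
}

#' @rdname io_tsv
#' @param table A data.frame.
#' @export
write_table_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname io_tsv
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    fill = FALSE)
}

#' @rdname io_tsv
#' @param markers Named list of gene-ID character vectors (one per cell type).
#' @export
write_markers_tsv <- function(markers, path) {
  df <- data.frame(gene_id = unlist(markers, use.names = FALSE),
                   cell_type = rep(names(markers), lengths(markers)),
                   stringsAsFactors = FALSE)
  write_table_tsv(df, path)
}

#' @rdname io_tsv
#' @export
read_markers_tsv <- function(path) {
  df <- read_table_tsv(path)
  stopifnot(all(c("gene_id", "cell_type") %in% names(df)))
  split(df$gene_id, df$cell_type)
}

#' Write a simulated dataset to a directory
#'
#' Persists the expression matrix, sample annotations and marker catalogue of a
#' [simulate_expression()] result using the package's TSV dialects.
#'
#' @param dataset A `labeled_dataset`.
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix.
#' @return The directory, invisibly.
#' @export
write_dataset <- function(dataset, dir, prefix = "dataset") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_tsv(dataset$expression,
                       file.path(dir, paste0(prefix, "_expression.tsv")))
  write_table_tsv(dataset$annotations,
                  file.path(dir, paste0(prefix, "_annotations.tsv")))
  write_markers_tsv(dataset$markers,
                    file.path(dir, paste0(prefix, "_markers.tsv")))
  invisible(dir)
}
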