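#' Aggregate regions to common parent structures
#'
#' First averages hemispheres: columns sharing a structure name but differing
#' in hemisphere are averaged. Then columns are grouped by the parent-structure
#' label of the correspondence table and averaged (per gene, over non-missing
#' values), yielding one column per parent in order of first appearance.
#'
#' @param matrix Gene x region matrix (columns are structure names, or sample
#'   IDs resolvable through `annotations`).
#' @param annotations Per-column annotation data.frame (sample_id,
#'   structure_name, hemisphere, ...); may be NULL when columns are already
#'   structure names and single-hemisphere.
#' @param correspondence Data.frame with columns `region` and `parent` for this
#'   species (a `species` column, if present, must already be filtered).
#' @return Gene x parent matrix.
#' @export
aggregate_to_parents <- function(matrix, annotations = NULL, correspondence) {
  stopifnot(all(c("region", "parent") %in% names(correspondence)))
  if (!is.null(annotations)) {
    ann <- annotations[match(colnames(matrix), annotations$sample_id), ,
                       drop = FALSE]
    if (!anyNA(ann$structure_name)) {
      # hemisphere averaging: same structure name, possibly two hemispheres
      matrix <- t(rowsum_mean(t(matrix), ann$structure_name))
      matrix <- matrix[, unique(ann$structure_name), drop = FALSE]
    }
  }
  parent <- correspondence$parent[match(colnames(matrix),
                                        correspondence$region)]
  if (anyNA(parent)) {
    stop("regions without a parent assignment: ",
         paste(colnames(matrix)[is.na(parent)], collapse = ", "))
  }
  out <- t(rowsum_mean(t(matrix), parent))
  out[, unique(parent), drop = FALSE]
}

#' Match two species' matrices over homologous genes and shared parents
#'
#' Retains only homologous genes present in both matrices and parent regions
#' shared by both, and puts rows and columns of both outputs in identical
#' order. Many-to-many homology is resolved by averaging expression within
#' each homology group (connected component of the gene-pair graph) per
#' species, one output row per group.
#'
#' @param matA,matB Gene x parent matrices for species A and B.
#' @param homology Data.frame with columns `species_a_gene`, `species_b_gene`.
#' @param correspondence Optional correspondence table (unused when both
#'   matrices are already keyed by parent; kept for interface symmetry).
#' @return List of class `matched_matrices`: `a`, `b` (row/column aligned) and
#'   `pairs` (data.frame gene_a, gene_b, group — one row per retained pair).
#' @export
match_matrices <- function(matA, matB, homology, correspondence = NULL) {
  stopifnot(all(c("species_a_gene", "species_b_gene") %in% names(homology)))
  hom <- unique(homology[, c("species_a_gene", "species_b_gene")])
  hom <- hom[hom$species_a_gene %in% rownames(matA) &
               hom$species_b_gene %in% rownames(matB), , drop = FALSE]
  if (nrow(hom) == 0) stop("no homologous gene is present in both matrices")
  parents <- intersect(colnames(matA), colnames(matB))
  if (length(parents) == 0) stop("no shared parent structures")
  hom$group <- homology_groups(hom$species_a_gene, hom$species_b_gene)
  # a gene listed in several pairs of one group must count once per species
  ua <- unique(hom[, c("species_a_gene", "group")])
  ub <- unique(hom[, c("species_b_gene", "group")])
  a_rows <- rowsum_mean(matA[ua$species_a_gene, parents, drop = FALSE],
                        ua$group)
  b_rows <- rowsum_mean(matB[ub$species_b_gene, parents, drop = FALSE],
                        ub$group)
  groups <- sort(unique(hom$group))
  structure(list(a = a_rows[groups, , drop = FALSE],
                 b = b_rows[groups, , drop = FALSE],
                 pairs = hom[order(hom$group), , drop = FALSE]),
            class = "matched_matrices")
}

# connected components of the bipartite homology graph, labelled by the
# lexicographically smallest species-A gene in the component
homology_groups <- function(a, b) {
  nodes <- c(paste0("A|", a), paste0("B|", b))
  uniq <- unique(nodes)
  parent <- stats::setNames(seq_along(uniq), uniq)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(a)) {
    i <- find(match(paste0("A|", a[k]), uniq))
    j <- find(match(paste0("B|", b[k]), uniq))
    if (i != j) parent[j] <- i
  }
  root <- vapply(seq_along(a), function(k) {
    find(match(paste0("A|", a[k]), uniq))
  }, integer(1))
  # name each component by its smallest A-side gene
  comp_name <- tapply(a, root, function(x) min(x))
  unname(comp_name[as.character(root)])
}

#' Joint quantile normalization of two matched matrices
#'
#' Replaces each column of each matrix rank-wise by a common reference
#' distribution: the mean, position by position, of every column's sorted
#' values pooled over both matrices. Columns containing missing values
#' contribute and receive values through linear interpolation of the reference
#' at proportional quantile positions `(rank - 1) / (m - 1)` among their `m`
#' non-missing entries; tied entries share the midrank value. After
#' normalization any two columns with the same number of non-missing entries
#' hold identical sorted values, and the operation is idempotent on complete
#' data.
#'
#' @param matA,matB Matched matrices with equal gene sets (same row count).
#' @param method `"joint"` (pooled reference over both matrices, the default)
#'   or `"separate"` (each matrix normalized against its own reference).
#' @return List with normalized `a` and `b`.
#' @export
quantile_normalize_joint <- function(matA, matB, method = c("joint",
                                                            "separate")) {
  method <- match.arg(method)
  stopifnot(nrow(matA) == nrow(matB))
  if (method == "separate") {
    return(list(a = qn_matrix(matA), b = qn_matrix(matB)))
  }
  pooled <- cbind(matA, matB)
  normed <- qn_matrix(pooled)
  list(a = normed[, seq_len(ncol(matA)), drop = FALSE],
       b = normed[, ncol(matA) + seq_len(ncol(matB)), drop = FALSE])
}

qn_matrix <- function(m) {
  n <- nrow(m)
  grid <- if (n == 1) 0 else (seq_len(n) - 1) / (n - 1)
  cols <- lapply(seq_len(ncol(m)), function(j) m[, j])
  n_obs <- vapply(cols, function(x) sum(!is.na(x)), integer(1))
  if (any(n_obs == 0)) {
    stop("all-missing column(s): ",
         paste(colnames(m)[n_obs == 0], collapse = ", "))
  }
  ref_contrib <- vapply(cols, function(x) {
    v <- sort(x[!is.na(x)])
    mm <- length(v)
    if (mm == 1) return(rep(v, n))
    if (mm == n) return(v)
    stats::approx(x = (seq_len(mm) - 1) / (mm - 1), y = v, xout = grid)$y
  }, numeric(n))
  ref <- rowMeans(ref_contrib)
  out <- m
  for (j in seq_len(ncol(m))) {
    x <- cols[[j]]
    ok <- !is.na(x)
    mm <- sum(ok)
    if (mm == 1) {
      out[ok, j] <- mean(ref)
      next
    }
    q <- (rank(x[ok]) - 1) / (mm - 1)  # midranks -> proportional quantiles
    out[ok, j] <- stats::approx(x = grid, y = ref, xout = q)$y
  }
  out
}

#' Joint low-expression filter across two species
#'
#' Per species, the per-gene mean expression and its quantile threshold (type 7
#' quantile of the per-gene means) are computed; a gene is removed only when
#' its mean is strictly below the threshold in BOTH species.
#'
#' @param matA,matB Matched matrices (equal row sets).
#' @param quantile Quantile in (0, 1), default 0.25.
#' @return List with filtered `a` and `b` (and `kept`, logical per input row).
#' @export
joint_expression_filter <- function(matA, matB, quantile = 0.25) {
  if (!is.numeric(quantile) || length(quantile) != 1 ||
      quantile <= 0 || quantile >= 1) {
    stop("quantile must be in (0, 1)")
  }
  stopifnot(nrow(matA) == nrow(matB))
  mA <- rowMeans(matA, na.rm = TRUE)
  mB <- rowMeans(matB, na.rm = TRUE)
  thrA <- stats::quantile(mA, quantile, type = 7, names = FALSE)
  thrB <- stats::quantile(mB, quantile, type = 7, names = FALSE)
  drop <- (mA < thrA) & (mB < thrB)
  list(a = matA[!drop, , drop = FALSE], b = matB[!drop, , drop = FALSE],
       kept = !drop)
}

#' Pairwise-complete Spearman correlation
#'
#' Positions missing in either vector are dropped; ranks use midranks for
#' ties; rho is the Pearson correlation of the ranks and the two-sided p-value
#' comes from the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on
#' `n - 2` degrees of freedom. Fewer than `min_overlap` complete pairs (or a
#' constant vector) yields a flagged, non-computable result rather than an
#' error.
#'
#' @param x,y Numeric vectors of equal length.
#' @param min_overlap Minimum complete pairs, default 5.
#' @return List: `rho`, `p`, `n_used`, `computable`.
#' @export
spearman <- function(x, y, min_overlap = 5L) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < min_overlap) {
    return(list(rho = NA_real_, p = NA_real_, n_used = n, computable = FALSE))
  }
  rx <- rank(x[ok])
  ry <- rank(y[ok])
  sx <- stats::sd(rx)
  sy <- stats::sd(ry)
  if (sx == 0 || sy == 0) {
    return(list(rho = NA_real_, p = NA_real_, n_used = n, computable = FALSE))
  }
  rho <- stats::cov(rx, ry) / (sx * sy)
  rho <- max(-1, min(1, rho))
  if (abs(rho) == 1) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p = p, n_used = n, computable = TRUE)
}

#' Per-gene cross-species correlations with BH q-values
#'
#' One Spearman correlation per matched gene pair across the shared parent
#' regions, with Benjamini-Hochberg q-values over all computable p-values.
#'
#' @param matA,matB Matched (normalized, filtered) matrices, rows aligned.
#' @param pairs Optional data.frame (gene_a, gene_b) labelling the rows;
#'   defaults to the shared rownames.
#' @param min_overlap Passed to [spearman()].
#' @return Data.frame: gene_a, gene_b, rho, p, q, n_regions_used, computable.
#' @export
gene_correlations <- function(matA, matB, pairs = NULL, min_overlap = 5L) {
  stopifnot(nrow(matA) == nrow(matB), ncol(matA) == ncol(matB))
  if (is.null(pairs)) {
    pairs <- data.frame(gene_a = rownames(matA),
                        gene_b = rownames(matB) %||% rownames(matA),
                        stringsAsFactors = FALSE)
  }
  res <- lapply(seq_len(nrow(matA)), function(i) {
    spearman(matA[i, ], matB[i, ], min_overlap = min_overlap)
  })
  out <- data.frame(
    gene_a = pairs$gene_a, gene_b = pairs$gene_b,
    rho = vapply(res, `[[`, numeric(1), "rho"),
    p = vapply(res, `[[`, numeric(1), "p"),
    q = NA_real_,
    n_regions_used = vapply(res, `[[`, numeric(1), "n_used"),
    computable = vapply(res, `[[`, logical(1), "computable"),
    stringsAsFactors = FALSE
  )
  out$q[out$computable] <- stats::p.adjust(out$p[out$computable],
                                           method = "BH")
  out
}

#' Per-region cross-species correlations
#'
#' Spearman correlation between the two species' expression vectors of each
#' matched parent region, across the shared genes.
#'
#' @inheritParams gene_correlations
#' @return Data.frame: parent, rho, p, n_used, computable, with attributes
#'   `mean_rho` and `sd_rho` over computable regions.
#' @export
region_correlations <- function(matA, matB, min_overlap = 5L) {
  stopifnot(ncol(matA) == ncol(matB))
  res <- lapply(seq_len(ncol(matA)), function(j) {
    spearman(matA[, j], matB[, j], min_overlap = min_overlap)
  })
  out <- data.frame(
    parent = colnames(matA),
    rho = vapply(res, `[[`, numeric(1), "rho"),
    p = vapply(res, `[[`, numeric(1), "p"),
    n_used = vapply(res, `[[`, numeric(1), "n_used"),
    computable = vapply(res, `[[`, logical(1), "computable"),
    stringsAsFactors = FALSE
  )
  attr(out, "mean_rho") <- mean(out$rho[out$computable])
  attr(out, "sd_rho") <- stats::sd(out$rho[out$computable])
  out
}

#' Gene-label permutation null for conservation statistics
#'
#' Repeatedly permutes species-A gene labels uniformly at random (shuffling
#' without replacement; the identity permutation is not excluded) and
#' recomputes the per-gene Spearman rho vector for each shuffle.
#'
#' @param matA,matB Matched matrices, rows aligned.
#' @param n_shuffles Number of label shuffles, default 20.
#' @param seed Integer seed.
#' @param min_overlap Passed to [spearman()].
#' @return Object of class `null_summary`: `n_shuffles`, `rho` (genes x
#'   shuffles matrix of null correlations), `seed`.
#' @export
permutation_null <- function(matA, matB, n_shuffles = 20L, seed = 1L,
                             min_overlap = 5L) {
  if (n_shuffles < 1) stop("n_shuffles must be at least 1")
  stopifnot(nrow(matA) == nrow(matB))
  local_rng(seed)
  n <- nrow(matA)
  rho <- matrix(NA_real_, nrow = n, ncol = n_shuffles)
  for (s in seq_len(n_shuffles)) {
    perm <- sample.int(n)
    for (i in seq_len(n)) {
      rho[i, s] <- spearman(matA[perm[i], ], matB[i, ],
                            min_overlap = min_overlap)$rho
    }
  }
  structure(list(n_shuffles = as.integer(n_shuffles), rho = rho,
                 seed = as.integer(seed)),
            class = "null_summary")
}

#' Excess of strong correlations over the permutation null
#'
#' Counts observed genes above `threshold` and below `-threshold` and subtracts
#' the mean corresponding counts across the null shuffles, alongside summary
#' statistics of the observed distribution.
#'
#' @param observed Numeric vector of observed per-gene rho (NAs ignored).
#' @param null A `null_summary`.
#' @param threshold Correlation threshold, default 0.30.
#' @return List: `excess_above` (observed minus mean-null count above
#'   threshold), `excess_below` (same below `-threshold`; negative means fewer
#'   than random), `observed_above`, `observed_below`, `null_mean_above`,
#'   `null_mean_below`, `observed_mean`, `observed_min`, `observed_max`.
#' @export
threshold_excess <- function(observed, null, threshold = 0.30) {
  stopifnot(inherits(null, "null_summary"))
  above <- sum(observed > threshold, na.rm = TRUE)
  below <- sum(observed < -threshold, na.rm = TRUE)
  null_above <- mean(colSums(null$rho > threshold, na.rm = TRUE))
  null_below <- mean(colSums(null$rho < -threshold, na.rm = TRUE))
  list(
    excess_above = above - null_above,
    excess_below = below - null_below,
    observed_above = above,
    observed_below = below,
    null_mean_above = null_above,
    null_mean_below = null_below,
    observed_mean = mean(observed, na.rm = TRUE),
    observed_min = suppressWarnings(min(observed, na.rm = TRUE)),
    observed_max = suppressWarnings(max(observed, na.rm = TRUE))
  )
}
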