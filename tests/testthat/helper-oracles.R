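# Independent oracles used across the suite. Deliberately brute-force and
# written without reference to the package internals.

# AUC by exhaustive pair counting: P(pos > neg) + 0.5 P(tie).
oracle_auc <- function(scores, positive_names) {
  pos <- scores[names(scores) %in% positive_names]
  neg <- scores[!names(scores) %in% positive_names]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Spearman rho by explicit midranks then the Pearson sum formula, with
# pairwise-complete deletion.
oracle_spearman <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) return(NA_real_)
  midrank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    r
  }
  rx <- midrank(x); ry <- midrank(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  if (!is.finite(den) || den == 0) return(NA_real_)
  num / den
}

# Benjamini-Hochberg step-up, textbook form.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(n)
  q[o] <- q_sorted
  q
}

# PCA oracle: eigen-decomposition of the covariance of the column-centred
# matrix (rows = observations).
oracle_pca <- function(m) {
  mc <- scale(m, center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(mc), symmetric = TRUE)
  k <- min(nrow(m), ncol(m))
  list(loadings = ev$vectors[, seq_len(k), drop = FALSE],
       scores = mc %*% ev$vectors[, seq_len(k), drop = FALSE],
       variance_fraction = ev$values[seq_len(k)] / sum(pmax(ev$values, 0)))
}

# Tiny matrix constructor with gene/sample names.
named_matrix <- function(values, nrow, genes = NULL, samples = NULL) {
  m <- matrix(values, nrow = nrow, byrow = TRUE)
  rownames(m) <- genes %||% paste0("g", seq_len(nrow(m)))
  colnames(m) <- samples %||% paste0("s", seq_len(ncol(m)))
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Annotation table builder.
make_annotations <- function(sample_id,
                             structure_name = sample_id,
                             parent_structure = structure_name,
                             division = "telencephalon",
                             hemisphere = NA_character_,
                             is_white_matter = FALSE) {
  data.frame(sample_id = sample_id, structure_name = structure_name,
             parent_structure = parent_structure, division = division,
             hemisphere = hemisphere, is_white_matter = is_white_matter,
             stringsAsFactors = FALSE)
}
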