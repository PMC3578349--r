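test_that("rank-1 matrix puts all variance on the first component", {
  m <- named_matrix(c(1, -1,
                      -1, 1), nrow = 2)
  res <- run_pca(m)
  expect_equal(res$variance_fraction[1], 1, tolerance = 1e-12)
})

test_that("PCA matches the eigen-decomposition oracle up to sign", {
  set.seed(101)
  for (i in 1:10) {
    n <- sample(5:20, 1)
    p <- sample(3:10, 1)
    m <- matrix(rnorm(n * p), nrow = n,
                dimnames = list(paste0("g", 1:n), paste0("r", 1:p)))
    m <- zscore_genes(m)
    res <- run_pca(m)
    ora <- oracle_pca(m)
    k <- length(res$variance_fraction)
    expect_equal(res$variance_fraction, ora$variance_fraction[seq_len(k)],
                 tolerance = 1e-8)
    for (j in seq_len(k)) {
      if (ora$variance_fraction[j] < 1e-10) next  # null-space axes free
      s <- sign(sum(res$region_loadings[, j] * ora$loadings[, j]))
      expect_equal(unname(res$region_loadings[, j]),
                   s * ora$loadings[, j], tolerance = 1e-6)
      expect_equal(unname(res$gene_scores[, j]),
                   s * unname(ora$scores[, j]), tolerance = 1e-6)
    }
    # variance accounting and orthogonality
    expect_equal(sum(res$variance_fraction), 1, tolerance = 1e-9)
    gram <- crossprod(res$region_loadings)
    expect_lt(max(abs(gram - diag(ncol(gram)))), 1e-8)
    # reconstruction from all components reproduces the input
    rec <- res$gene_scores %*% t(res$region_loadings)
    rec <- sweep(rec, 2, res$center, "+")
    expect_lt(max(abs(rec - m)), 1e-8)
  }
})

test_that("missing values are rejected with their count", {
  m <- named_matrix(c(1, NA, 2, 0, 1, NA), nrow = 2)
  expect_error(run_pca(m), "2 missing")
})

test_that("orientation follows the mean anchor score and is idempotent", {
  m <- zscore_genes(named_matrix(c(1, 2, 3,
                                   3, 2, 1,
                                   1, 3, 2,
                                   2, 1, 3), nrow = 4))
  res <- run_pca(m)
  g <- rownames(res$gene_scores)
  # pick an anchor currently negative on PC1
  neg_gene <- g[which.min(res$gene_scores[, 1])]
  flipped <- orient_components(res, neg_gene)
  expect_gt(flipped$gene_scores[neg_gene, 1], 0)
  expect_equal(flipped$orientation[1], -1)
  expect_equal(flipped$gene_scores[, 1], -res$gene_scores[, 1])
  expect_equal(flipped$region_loadings[, 1], -res$region_loadings[, 1])
  # idempotent
  again <- orient_components(flipped, neg_gene)
  expect_equal(again$gene_scores, flipped$gene_scores)
  # positive anchor: identity
  pos_gene <- g[which.max(res$gene_scores[, 1])]
  same <- orient_components(res, pos_gene)
  expect_equal(same$gene_scores, res$gene_scores)
  expect_equal(same$orientation[1], 1)
  # mean-of-anchors rule: anchors {+1-ish, -3-ish} with negative mean flip
  sc <- res$gene_scores[, 1]
  two <- c(g[which.max(sc)], g[which.min(sc)])
  mean_sign <- sign(mean(sc[two]))
  oriented <- orient_components(res, two)
  expect_equal(oriented$orientation[1], ifelse(mean_sign < 0, -1, 1))
  expect_error(orient_components(res, "absent_gene"), "anchor")
})

test_that("top pattern sets take score extremes with lexicographic ties", {
  res <- structure(list(
    gene_scores = matrix(c(3, -1, 2, -4), ncol = 1,
                         dimnames = list(c("a", "b", "c", "d"), "PC1")),
    region_loadings = matrix(0, 1, 1), variance_fraction = 1,
    orientation = 1, anchor = NULL, center = 0), class = "pca_result")
  s1 <- top_pattern_sets(res, 1)
  expect_equal(s1$oligodendrocyte$gene, "a")
  expect_equal(s1$neuron$gene, "d")
  s2 <- top_pattern_sets(res, 2)
  expect_equal(s2$oligodendrocyte$gene, c("a", "c"))
  expect_equal(s2$neuron$gene, c("d", "b"))
  expect_error(top_pattern_sets(res, 5), "exceeds")

  # ties broken by gene ID
  res$gene_scores[, 1] <- c(2, 2, -2, -2)
  st <- top_pattern_sets(res, 1)
  expect_equal(st$oligodendrocyte$gene, "a")
  expect_equal(st$neuron$gene, "c")
})

test_that("averaged patterns are per-region means over present genes", {
  m <- named_matrix(c(1, 3,
                      3, 1,
                      5, 5), nrow = 3)
  p <- averaged_pattern(m, c("g1", "g2"))
  expect_equal(unname(p$values), c(2, 2))
  expect_equal(p$n_genes, 2)
  # singleton set: the gene's own row
  p1 <- averaged_pattern(m, "g3")
  expect_equal(unname(p1$values), c(5, 5))
  # absent gene masked and counted
  p2 <- averaged_pattern(m, c("g1", "g2", "missing"))
  expect_equal(unname(p2$values), c(2, 2))
  expect_equal(p2$n_missing, 1)
  expect_error(averaged_pattern(m, c("x", "y")), "missing")
})

test_that("pattern anti-correlation uses the Spearman kernel", {
  a <- averaged_pattern(named_matrix(c(1, 2, 3), 1), "g1")
  b <- averaged_pattern(named_matrix(c(3, 2, 1), 1), "g1")
  expect_equal(pattern_anticorrelation(a, b)$rho, -1)
  expect_equal(pattern_anticorrelation(a, a)$rho, 1)
  short_a <- averaged_pattern(named_matrix(c(1, 2), 1), "g1")
  expect_error(pattern_anticorrelation(short_a, short_a), "3 regions")
})

test_that("marker ratio is the quotient of averaged patterns, guarded", {
  m <- named_matrix(c(4, 8,
                      2, 2), nrow = 2)
  r <- marker_ratio_by_region(m, "g1", "g2")
  expect_equal(unname(r), c(2, 4))
  expect_equal(unname(marker_ratio_by_region(m, "g2", "g2")), c(1, 1))
  m2 <- named_matrix(c(4, 8,
                       0, 2), nrow = 2)
  expect_warning(r2 <- marker_ratio_by_region(m2, "g1", "g2"), "undefined")
  expect_true(is.na(r2[1]))
  expect_equal(unname(r2[2]), 4)
})

test_that("division summary reports mean, n-1 SD and counts", {
  res <- structure(list(
    gene_scores = matrix(0, 1, 1),
    region_loadings = matrix(c(0.1, 0.3, 0.5), ncol = 1,
                             dimnames = list(c("r1", "r2", "r3"), "PC1")),
    variance_fraction = 1, orientation = 1, anchor = NULL, center = 0),
    class = "pca_result")
  ann <- make_annotations(c("r1", "r2", "r3"),
                          division = c("D", "D", "E"))
  out <- division_loading_summary(res, ann)
  d <- out[out$division == "D", ]
  expect_equal(d$mean, 0.2)
  expect_equal(d$sd, sd(c(0.1, 0.3)))
  expect_equal(d$n, 2)
  expect_true(is.na(out$sd[out$division == "E"]))  # single region
  expect_error(division_loading_summary(res, ann[0, ]), "empty")
  ann_bad <- make_annotations(c("r1", "r2"), division = "D")
  expect_error(division_loading_summary(res, ann_bad), "division")
})

test_that("planted gradient is recovered in loadings and pattern profiles", {
  cfg <- sim_config(n_genes = 500, n_regions = 40, n_markers_per_type = 40,
                    gradient_strength = 0.9, noise_sd = 0.05, seed = 77,
                    n_replicates_per_region = 1)
  ds <- simulate_expression(cfg)
  avg <- average_replicates(ds$expression, ds$annotations)
  filt <- filter_low_signal(avg$matrix, 0.25)
  scaled <- zscore_genes(filt$matrix)
  pca <- orient_components(run_pca(scaled), ds$markers$oligodendrocyte)
  # loadings track the planted oligodendrocyte proportion
  oligo_prop <- ds$truth$composition[colnames(scaled), "oligodendrocyte"]
  rho <- spearman(pca$region_loadings[, 1], oligo_prop)$rho
  expect_gte(abs(rho), 0.8)
  # averaged marker patterns anti-correlate
  pn <- averaged_pattern(scaled, intersect(ds$markers$neuron,
                                           rownames(scaled)))
  po <- averaged_pattern(scaled, intersect(ds$markers$oligodendrocyte,
                                           rownames(scaled)))
  expect_lte(pattern_anticorrelation(pn, po)$rho, -0.5)
  # marker ratio rises along the planted axis
  ratio <- marker_ratio_by_region(filt$matrix,
                                  intersect(ds$markers$oligodendrocyte,
                                            rownames(filt$matrix)),
                                  intersect(ds$markers$neuron,
                                            rownames(filt$matrix)))
  axis <- seq_along(ratio)
  expect_gt(spearman(ratio, axis)$rho, 0.8)
})
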