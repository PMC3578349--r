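test_that("parent aggregation averages hemispheres first, then parents", {
  # CA1..CA4 columns [1,2,3,4] under one parent -> 2.5
  m <- named_matrix(c(1, 2, 3, 4), nrow = 1,
                    samples = paste0("CA", 1:4))
  co <- data.frame(region = paste0("CA", 1:4), parent = "Ammon's horn",
                   stringsAsFactors = FALSE)
  out <- aggregate_to_parents(m, NULL, co)
  expect_equal(unname(out[1, ]), 2.5)

  # left/right CA1 [2,4] averaged to 3, then parent of CA1 alone
  m2 <- named_matrix(c(2, 4), nrow = 1, samples = c("sL", "sR"))
  ann <- make_annotations(c("sL", "sR"), structure_name = c("CA1", "CA1"),
                          hemisphere = c("left", "right"))
  co2 <- data.frame(region = "CA1", parent = "Ammon's horn")
  out2 <- aggregate_to_parents(m2, ann, co2)
  expect_equal(unname(out2[1, ]), 3)

  # parent with a single region: identity
  m3 <- named_matrix(c(7, 9), nrow = 1, samples = c("r1", "r2"))
  co3 <- data.frame(region = c("r1", "r2"), parent = c("p1", "p2"))
  out3 <- aggregate_to_parents(m3, NULL, co3)
  expect_equal(unname(out3[1, ]), c(7, 9))

  co_bad <- data.frame(region = "r1", parent = "p1")
  expect_error(aggregate_to_parents(m3, NULL, co_bad), "r2")
})

test_that("matrix matching aligns homologs over shared parents", {
  a <- named_matrix(1:15, nrow = 5, genes = paste0("h", 1:5),
                    samples = c("p1", "p2", "p3"))
  b <- named_matrix(1:9, nrow = 3, genes = paste0("m", 1:3),
                    samples = c("p2", "p3", "p4"))
  hom <- data.frame(species_a_gene = c("h1", "h2", "h3", "h5"),
                    species_b_gene = c("m1", "m2", "m3", "m9"),
                    stringsAsFactors = FALSE)
  out <- match_matrices(a, b, hom)
  expect_equal(dim(out$a), c(3, 2))
  expect_equal(dim(out$b), c(3, 2))
  expect_equal(colnames(out$a), colnames(out$b))
  expect_equal(rownames(out$a), rownames(out$b))
  expect_equal(out$a["h1", "p2"], a["h1", "p2"])
  expect_equal(out$b["h1", "p2"], b["m1", "p2"])

  hom_disjoint <- data.frame(species_a_gene = "hx", species_b_gene = "mx")
  expect_error(match_matrices(a, b, hom_disjoint), "no homologous")
  b_far <- b
  colnames(b_far) <- c("q1", "q2", "q3")
  expect_error(match_matrices(a, b_far, hom), "parent")
})

test_that("many-to-many homology groups are averaged per species", {
  a <- named_matrix(c(1, 2,
                      3, 4,
                      10, 10), nrow = 3, genes = c("h1", "h2", "h3"),
                    samples = c("p1", "p2"))
  b <- named_matrix(c(5, 6,
                      7, 8,
                      0, 0), nrow = 3, genes = c("m1", "m2", "m3"),
                    samples = c("p1", "p2"))
  # h1 and h2 both pair with m1; h2 also pairs with m2: one connected group
  hom <- data.frame(species_a_gene = c("h1", "h2", "h2", "h3"),
                    species_b_gene = c("m1", "m1", "m2", "m3"),
                    stringsAsFactors = FALSE)
  out <- match_matrices(a, b, hom)
  expect_equal(nrow(out$a), 2)
  expect_equal(unname(out$a["h1", ]), c(2, 3))   # mean of h1, h2
  expect_equal(unname(out$b["h1", ]), c(6, 7))   # mean of m1, m2
  expect_equal(unname(out$a["h3", ]), c(10, 10))
})

test_that("joint quantile normalization reproduces the sorted-means reference", {
  a <- named_matrix(c(1, 2, 3), nrow = 3, samples = "cA")
  b <- named_matrix(c(4, 5, 6), nrow = 3, samples = "cB")
  out <- quantile_normalize_joint(a, b)
  expect_equal(unname(out$a[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out$b[, 1]), c(2.5, 3.5, 4.5))
  # identical columns everywhere: output equals input
  same <- named_matrix(rep(c(2, 1, 5), 2), nrow = 3,
                       samples = c("c1", "c2"))
  expect_equal(quantile_normalize_joint(same, same)$a, same)
  # idempotence
  twice <- quantile_normalize_joint(out$a, out$b)
  expect_equal(twice$a, out$a, tolerance = 1e-12)
})

test_that("quantile normalization equals limma on complete data", {
  skip_if_not_installed("limma")
  set.seed(8)
  a <- matrix(rlnorm(60), nrow = 20,
              dimnames = list(paste0("g", 1:20), paste0("a", 1:3)))
  b <- matrix(rlnorm(40), nrow = 20,
              dimnames = list(paste0("g", 1:20), paste0("b", 1:2)))
  ours <- quantile_normalize_joint(a, b)
  ref <- limma::normalizeQuantiles(cbind(a, b))
  expect_equal(unname(cbind(ours$a, ours$b)), unname(ref), tolerance = 1e-10)
})

test_that("normalized columns share sorted values and ranks are preserved", {
  set.seed(14)
  for (i in 1:6) {
    n <- 40
    a <- matrix(rlnorm(n * 3), nrow = n,
                dimnames = list(paste0("g", 1:n), paste0("a", 1:3)))
    b <- matrix(rlnorm(n * 4), nrow = n,
                dimnames = list(paste0("g", 1:n), paste0("b", 1:4)))
    if (i > 3) {  # plant missing values in some columns
      a[sample(length(a), 12)] <- NA
      b[sample(length(b), 10)] <- NA
    }
    out <- quantile_normalize_joint(a, b)
    pooled_in <- cbind(a, b)
    pooled <- cbind(out$a, out$b)
    counts <- colSums(!is.na(pooled))
    for (j in seq_len(ncol(pooled))) {
      expect_equal(sum(is.na(pooled[, j])), sum(is.na(pooled_in[, j])))
      ok <- !is.na(pooled[, j])
      expect_equal(rank(pooled[ok, j]), rank(pooled_in[ok, j]))
      # equal non-missing counts imply identical sorted values
      twin <- setdiff(which(counts == counts[j]), j)
      for (k in twin) {
        expect_equal(sort(pooled[, j]), sort(pooled[, k]),
                     ignore_attr = TRUE, tolerance = 1e-12)
      }
    }
  }
  expect_error(quantile_normalize_joint(matrix(NA_real_, 2, 1),
                                        matrix(1:2, 2, 1)), "all-missing")
})

test_that("joint filter removes only genes weak in both species", {
  a <- named_matrix(c(10, 10,
                      1, 1,
                      1, 1,
                      10, 10), nrow = 4, samples = c("p1", "p2"))
  b <- named_matrix(c(10, 10,
                      10, 10,
                      1, 1,
                      1, 1), nrow = 4, samples = c("p1", "p2"))
  out <- joint_expression_filter(a, b, 0.5)
  # only g3 is below the median threshold in both
  expect_false("g3" %in% rownames(out$a))
  expect_setequal(rownames(out$a), c("g1", "g2", "g4"))
  expect_equal(rownames(out$a), rownames(out$b))
  expect_error(joint_expression_filter(a, b, 0), "quantile")

  # hand-computed 25th percentiles on an 8-gene case
  means_a <- c(1, 2, 3, 4, 5, 6, 7, 8)
  means_b <- c(8, 1, 6, 5, 2, 3, 4, 7)
  a8 <- named_matrix(rep(means_a, each = 2), nrow = 8,
                     samples = c("p1", "p2"))
  b8 <- named_matrix(rep(means_b, each = 2), nrow = 8,
                     samples = c("p1", "p2"))
  thr_a <- quantile(means_a, 0.25)
  thr_b <- quantile(means_b, 0.25)
  expected <- !(means_a < thr_a & means_b < thr_b)
  out8 <- joint_expression_filter(a8, b8, 0.25)
  expect_setequal(rownames(out8$a), rownames(a8)[expected])
})

test_that("spearman matches the rank-then-Pearson oracle exhaustively", {
  expect_equal(spearman(1:3, 1:3, min_overlap = 3)$rho, 1)
  expect_equal(spearman(1:3, 3:1, min_overlap = 3)$rho, -1)
  # worked missing-data case: pairs (1,2),(2,1),(4,4) -> rho = 0.5
  r <- spearman(c(1, 2, NA, 4), c(2, 1, 5, 4), min_overlap = 3)
  expect_equal(r$rho, 0.5)
  expect_equal(r$n_used, 3)

  # exhaustive small vectors with ties and missing patterns
  vals <- list(c(1, 2, 3, 4, 5), c(1, 1, 2, 2, 3), c(2, 1, 2, 1, 3))
  miss <- list(rep(FALSE, 5), c(TRUE, rep(FALSE, 4)),
               c(FALSE, TRUE, FALSE, TRUE, FALSE))
  set.seed(3)
  for (x0 in vals) for (y0 in vals) for (mx in miss) for (my in miss) {
    x <- x0; y <- rev(y0)
    x[mx] <- NA; y[my] <- NA
    ours <- spearman(x, y, min_overlap = 3)
    expected <- oracle_spearman(x, y)
    if (!ours$computable) {
      expect_true(is.na(expected) || sum(!is.na(x) & !is.na(y)) < 3)
    } else {
      expect_equal(ours$rho, expected, tolerance = 1e-12)
      # p agrees with the t-distribution transform of rho
      expect_gte(ours$p, 0)
      expect_lte(ours$p, 1)
    }
  }
  # random longer vectors against cor(..., method = "spearman")
  for (i in 1:30) {
    n <- sample(6:40, 1)
    x <- sample(1:8, n, replace = TRUE)
    y <- sample(1:8, n, replace = TRUE)
    x[sample(n, 2)] <- NA
    ours <- spearman(x, y)
    if (ours$computable) {
      expect_equal(ours$rho,
                   cor(x, y, method = "spearman",
                       use = "pairwise.complete.obs"),
                   tolerance = 1e-12)
    }
  }
  # insufficient overlap is flagged, not an error
  short <- spearman(c(1, 2, NA, NA, NA), c(1, 2, 3, 4, 5))
  expect_false(short$computable)
  expect_equal(short$n_used, 2)
})

test_that("spearman p-values follow the t-approximation", {
  set.seed(44)
  x <- rnorm(30)
  y <- x + rnorm(30, sd = 2)
  r <- spearman(x, y)
  tval <- r$rho * sqrt((r$n_used - 2) / (1 - r$rho^2))
  expect_equal(r$p, 2 * pt(-abs(tval), r$n_used - 2), tolerance = 1e-12)
  # perfect monotone association: p = 0 by convention
  expect_equal(spearman(1:10, (1:10)^3)$p, 0)
})

test_that("BH q-values equal the step-up oracle", {
  expect_equal(
    gene_correlations(named_matrix(0, 1), named_matrix(0, 1))$q,
    NA_real_)  # degenerate guard: single constant gene is non-computable
  # worked example
  p <- c(0.002, 0.01, 0.03, 0.04)
  expect_equal(oracle_bh(p), c(0.008, 0.02, 0.04, 0.04))
  expect_equal(p.adjust(p, "BH"), oracle_bh(p))
  set.seed(10)
  for (i in 1:200) {
    p <- runif(sample(3:50, 1))
    expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("gene correlations recover conserved and discordant patterns", {
  # two conserved noise-free genes -> rho 1; one reversed gene -> rho < 0
  a <- named_matrix(c(1, 2, 3, 4, 5, 6,
                      2, 4, 6, 8, 10, 12,
                      1, 2, 3, 4, 5, 6), nrow = 3,
                    samples = paste0("p", 1:6))
  b <- a
  b[3, ] <- rev(b[3, ])
  out <- gene_correlations(a, b)
  expect_equal(out$rho[1:2], c(1, 1))
  expect_lt(out$rho[3], 0)
  expect_equal(out$q[order(out$p)],
               oracle_bh(sort(out$p)), tolerance = 1e-12)
})

test_that("region correlations isolate a randomized column", {
  set.seed(20)
  a <- matrix(rnorm(300), nrow = 50,
              dimnames = list(paste0("g", 1:50), paste0("p", 1:6)))
  b <- a + matrix(rnorm(300, sd = 0.05), nrow = 50)
  b[, "p4"] <- sample(b[, "p4"])
  out <- region_correlations(a, b)
  expect_true(all(out$rho[out$parent != "p4"] > 0.9))
  expect_lt(abs(out$rho[out$parent == "p4"]), 0.5)
  expect_true(is.finite(attr(out, "mean_rho")))
  expect_true(is.finite(attr(out, "sd_rho")))
  # identical matrices: all rho 1
  out2 <- region_correlations(a, a)
  expect_true(all(out2$rho == 1))
})

test_that("permutation null is seeded, sized and centred", {
  set.seed(71)
  a <- matrix(rnorm(240), nrow = 30,
              dimnames = list(paste0("g", 1:30), paste0("p", 1:8)))
  b <- matrix(rnorm(240), nrow = 30,
              dimnames = list(paste0("g", 1:30), paste0("p", 1:8)))
  null1 <- permutation_null(a, b, n_shuffles = 6, seed = 5)
  null2 <- permutation_null(a, b, n_shuffles = 6, seed = 5)
  expect_identical(null1, null2)
  expect_equal(dim(null1$rho), c(30, 6))
  expect_error(permutation_null(a, b, n_shuffles = 0, seed = 1), "n_shuffles")
  # independent noise: grand mean within 3 SE of 0
  null_big <- permutation_null(a, b, n_shuffles = 40, seed = 6)
  se <- sd(null_big$rho) / sqrt(nrow(a))  # genes as independent units
  expect_lt(abs(mean(null_big$rho)), 3 * se)
})

test_that("threshold excess counts observed versus mean null", {
  null <- structure(list(n_shuffles = 2L,
                         rho = cbind(c(0.1, -0.1, 0), c(0.2, -0.5, 0.4)),
                         seed = 1L), class = "null_summary")
  out <- threshold_excess(c(0.5, 0.5), null, threshold = 0.30)
  expect_equal(out$excess_above, 2 - 0.5)  # null above: mean(0, 1)
  expect_equal(out$excess_below, 0 - 0.5)  # null below: mean(0, 1)
  expect_equal(out$observed_mean, 0.5)
  out0 <- threshold_excess(c(0, 0, 0), null)
  expect_equal(out0$excess_above, -0.5)
  expect_equal(out0$observed_min, 0)
  expect_equal(out0$observed_max, 0)
})
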