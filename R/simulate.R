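#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic brain-expression
#' generator. The generator plants a cell-type composition gradient across an
#' ordered set of brain regions: the neuron fraction decreases and the
#' oligodendrocyte fraction increases along the region axis, emulating the
#' glia-to-neuron ratio gradient that dominates regional bulk transcriptomes.
#'
#' @param n_genes Number of genes.
#' @param n_regions Number of brain regions (ordered along the planted axis).
#' @param n_markers_per_type Number of marker genes planted per cell type.
#' @param cell_types Ordered cell-type names; must contain "neuron" and
#'   "oligodendrocyte" (the gradient pair). Additional types (default
#'   "astrocyte") receive the compositional remainder and are flat along the
#'   axis.
#' @param gradient_strength Weight in \[0, 1\] of the deterministic composition
#'   trend; 0 gives pure compositional noise, 1 a noise-free monotone gradient.
#' @param noise_sd Standard deviation of additive Gaussian measurement noise,
#'   in expression units (>= 0). Negative draws are truncated at 0.
#' @param fold_enrichment Minimum mean fold enrichment of a marker gene in its
#'   own cell type relative to every other type (>= 1; default 10, the usual
#'   stringent marker criterion).
#' @param n_replicates_per_region Samples sharing each structure name.
#' @param gene_signal_sd Standard deviation (expression units, >= 0) of a
#'   conserved gene-specific regional signature added to the mixture profile.
#'   Real regional transcriptomes are dominated by gene-specific patterns (the
#'   composition axis explains only a minority of variance), and in a species
#'   pair this signature is what cross-species conservation of non-marker
#'   genes rests on; set it to 0 for a pure cell-type-mixture model.
#' @param missing_rate Probability in \[0, 1) that an expression entry is set
#'   to NA (completely at random, emulating ISH-style missing values).
#' @param discordant_fraction Probability in \[0, 1) that a gene's regional
#'   profile is rank-reversed in species B of a simulated species pair.
#' @param seed Integer seed; identical configs give bit-identical datasets.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 2000L,
                       n_regions = 100L,
                       n_markers_per_type = 100L,
                       cell_types = c("neuron", "oligodendrocyte", "astrocyte"),
                       gradient_strength = 0.9,
                       noise_sd = 0.2,
                       fold_enrichment = 10,
                       gene_signal_sd = 0.15,
                       n_replicates_per_region = 2L,
                       missing_rate = 0,
                       discordant_fraction = 0,
                       seed = 1L) {
  stopifnot(length(cell_types) >= 2, !anyDuplicated(cell_types))
  if (!all(c("neuron", "oligodendrocyte") %in% cell_types)) {
    stop("cell_types must include 'neuron' and 'oligodendrocyte'")
  }
  check_scalar_range(gradient_strength, "gradient_strength", 0, 1)
  check_scalar_range(noise_sd, "noise_sd", 0, Inf)
  check_scalar_range(fold_enrichment, "fold_enrichment", 1, Inf)
  check_scalar_range(gene_signal_sd, "gene_signal_sd", 0, Inf)
  check_scalar_range(missing_rate, "missing_rate", 0, 1, right_open = TRUE)
  check_scalar_range(discordant_fraction, "discordant_fraction", 0, 1,
                     right_open = TRUE)
  n_genes <- as.integer(n_genes)
  n_regions <- as.integer(n_regions)
  n_markers_per_type <- as.integer(n_markers_per_type)
  n_replicates_per_region <- as.integer(n_replicates_per_region)
  stopifnot(n_genes >= 1, n_regions >= 2, n_markers_per_type >= 0,
            n_replicates_per_region >= 1)
  if (n_markers_per_type * length(cell_types) > n_genes) {
    stop("n_markers_per_type x number of cell types exceeds n_genes")
  }
  structure(list(
    n_genes = n_genes, n_regions = n_regions,
    n_markers_per_type = n_markers_per_type, cell_types = cell_types,
    gradient_strength = gradient_strength, noise_sd = noise_sd,
    fold_enrichment = fold_enrichment, gene_signal_sd = gene_signal_sd,
    n_replicates_per_region = n_replicates_per_region,
    missing_rate = missing_rate, discordant_fraction = discordant_fraction,
    seed = as.integer(seed)
  ), class = "sim_config")
}

check_scalar_range <- function(x, name, lo, hi, right_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) ||
      x < lo || (if (right_open) x >= hi else x > hi)) {
    stop(sprintf("%s must be a finite number in [%s, %s%s", name, lo, hi,
                 if (right_open) ")" else "]"))
  }
  invisible(x)
}

# Deterministic composition trends. The neuron and oligodendrocyte trends sum
# to a constant, named non-gradient types (astrocyte, ...) are held exactly
# constant, and an unnamed residual cell fraction ("other": microglia,
# endothelium, ...) absorbs compositional closure, so the windows below keep
# every fraction positive even at full noise.
.trend_neuron <- function(t) 0.50 - 0.20 * t
.trend_oligo <- function(t) 0.12 + 0.20 * t
.flat_share <- 0.10

#' Simulate per-region cell-type proportions
#'
#' Plants a monotone composition axis: the neuron fraction decreases and the
#' oligodendrocyte fraction increases linearly with region index, mixed with
#' uniform noise weighted by `1 - gradient_strength`. Named non-gradient cell
#' types (astrocyte, ...) are held exactly constant — flat-planted — and an
#' unnamed residual `other` fraction (microglia, endothelium, ...) absorbs
#' compositional closure, so rows sum to exactly 1 while, at
#' `gradient_strength = 0`, the neuron and oligodendrocyte fractions are
#' independent draws (their correlation is centred on zero). With exactly two
#' cell types the oligodendrocyte fraction is the neuron complement.
#'
#' @param n_regions Number of regions (>= 2).
#' @param gradient_strength Trend weight in \[0, 1\].
#' @param seed Integer seed.
#' @param cell_types Cell-type names, containing "neuron" and
#'   "oligodendrocyte".
#' @return A data.frame with one row per region (`region` column) and one
#'   proportion column per cell type; rows sum to 1 within 1e-12.
#' @export
simulate_composition <- function(n_regions, gradient_strength, seed = 1L,
                                 cell_types = c("neuron", "oligodendrocyte",
                                                "astrocyte")) {
  stopifnot(n_regions >= 2)
  check_scalar_range(gradient_strength, "gradient_strength", 0, 1)
  if (!all(c("neuron", "oligodendrocyte") %in% cell_types)) {
    stop("cell_types must include 'neuron' and 'oligodendrocyte'")
  }
  rng <- local_rng(seed)
  tt <- seq(0, 1, length.out = n_regions)
  g <- gradient_strength
  k <- length(cell_types)
  if (k == 2) {
    # two-type brain: oligodendrocyte fraction is the complement
    neuron <- g * .trend_neuron(tt) + (1 - g) * stats::runif(n_regions, 0.30, 0.50)
    comp <- cbind(neuron = neuron, oligodendrocyte = 1 - neuron)
    comp <- comp[, cell_types, drop = FALSE]
  } else {
    neuron <- g * .trend_neuron(tt) + (1 - g) * stats::runif(n_regions, 0.30, 0.50)
    oligo <- g * .trend_oligo(tt) + (1 - g) * stats::runif(n_regions, 0.12, 0.32)
    flat <- matrix(min(.flat_share, 0.15 / (k - 2)),
                   nrow = n_regions, ncol = k - 2,
                   dimnames = list(NULL,
                                   setdiff(cell_types,
                                           c("neuron", "oligodendrocyte"))))
    comp <- cbind(neuron = neuron, oligodendrocyte = oligo, flat)
    comp <- comp[, cell_types, drop = FALSE]
    comp <- cbind(comp, other = 1 - rowSums(comp))
  }
  stopifnot(all(comp >= 0))
  out <- data.frame(region = region_names(n_regions), comp,
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- out$region
  out
}

region_names <- function(n, prefix = "region") {
  sprintf("%s_%0*d", prefix, max(2L, nchar(n)), seq_len(n))
}

# One pseudo-random stream per dataset, seeded from the config.
local_rng <- function(seed) {
  set.seed(as.integer(seed))
  invisible(seed)
}

#' Simulate a labelled single-species expression dataset
#'
#' Expression of gene g in a sample of region r is the composition mixture
#' `sum_c p(r, c) * mu(g, c)` plus Gaussian noise truncated at zero. Marker
#' genes of a cell type have their mean profile `mu` elevated at least
#' `fold_enrichment`-fold over every other type; non-marker genes draw
#' independent type means. Replicate samples share a structure name; a
#' `missing_rate` fraction of entries is set NA completely at random.
#'
#' @param config A [sim_config()].
#' @return A list of class `labeled_dataset` with elements `expression`
#'   (genes x samples matrix), `annotations` (per-sample data.frame with
#'   sample_id, structure_name, parent_structure, division, hemisphere,
#'   is_white_matter), `markers` (named list of gene-ID vectors per cell type,
#'   with attribute `fold_enrichment`), and `truth` (list: `composition`,
#'   `mu` genes x cell-types matrix, `marker_table`).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  rng <- local_rng(config$seed)
  truth <- simulate_profiles(config)
  ds <- realize_dataset(config, truth, species_prefix = "")
  ds
}

# Draw the latent per-gene cell-type means and the composition table.
simulate_profiles <- function(config) {
  comp <- simulate_composition(config$n_regions, config$gradient_strength,
                               seed = config$seed + 1L,
                               cell_types = config$cell_types)
  mu_types <- setdiff(colnames(comp), "region")  # includes "other" when k >= 3
  k <- length(mu_types)
  genes <- sprintf("g%0*d", max(4L, nchar(config$n_genes)),
                   seq_len(config$n_genes))
  # Non-marker genes: a per-gene baseline with a modest (+/-10%) cell-type
  # contrast; their regional identity comes from the gene-specific signature,
  # not from the composition axis. Markers overwrite their own rows below.
  base_level <- stats::runif(config$n_genes, 0.5, 1.5)
  mu <- base_level * matrix(stats::runif(config$n_genes * k, 0.9, 1.1),
                            nrow = config$n_genes,
                            dimnames = list(genes, mu_types))
  markers <- stats::setNames(vector("list", length(config$cell_types)),
                             config$cell_types)
  idx <- 0L
  for (ct in config$cell_types) {
    if (config$n_markers_per_type == 0L) { markers[[ct]] <- character(); next }
    sel <- idx + seq_len(config$n_markers_per_type)
    idx <- idx + config$n_markers_per_type
    base <- stats::runif(length(sel), 0.5, 1.5)
    enr <- config$fold_enrichment *
      stats::runif(length(sel), 1.0, 1.5)
    mu[sel, ] <- base            # low in every other type (incl. "other")
    mu[cbind(sel, match(ct, mu_types))] <- base * enr
    markers[[ct]] <- genes[sel]
  }
  attr(markers, "fold_enrichment") <- config$fold_enrichment
  marker_table <- data.frame(
    gene_id = unlist(markers, use.names = FALSE),
    cell_type = rep(names(markers), lengths(markers)),
    stringsAsFactors = FALSE
  )
  signal <- matrix(stats::rnorm(config$n_genes * config$n_regions,
                                0, config$gene_signal_sd),
                   nrow = config$n_genes,
                   dimnames = list(genes, rownames(comp)))
  list(composition = comp, mu = mu, markers = markers,
       marker_table = marker_table, signal = signal)
}

# Noiseless regional mean profiles (mixture + conserved gene-specific
# signature): genes x regions.
mixture_profiles <- function(truth, composition = NULL) {
  comp <- composition %||% truth$composition
  p <- as.matrix(comp[, colnames(truth$mu), drop = FALSE])
  prof <- truth$mu %*% t(p)
  colnames(prof) <- rownames(comp)
  prof + truth$signal
}

# Expand regional profiles into replicate samples with noise and missingness.
realize_dataset <- function(config, truth, species_prefix = "",
                            profiles = NULL) {
  if (is.null(profiles)) profiles <- mixture_profiles(truth)
  n_rep <- config$n_replicates_per_region
  regions <- colnames(profiles)
  if (nzchar(species_prefix)) {
    regions <- paste0(species_prefix, regions)
    colnames(profiles) <- regions
  }
  expr <- profiles[, rep(seq_along(regions), each = n_rep), drop = FALSE]
  sample_ids <- paste0(rep(regions, each = n_rep), "_rep",
                       rep(seq_len(n_rep), times = length(regions)))
  colnames(expr) <- sample_ids
  if (config$noise_sd > 0) {
    expr <- expr + matrix(stats::rnorm(length(expr), 0, config$noise_sd),
                          nrow = nrow(expr))
  }
  expr[expr < 0] <- 0            # expression energies are non-negative
  if (config$missing_rate > 0) {
    expr[stats::runif(length(expr)) < config$missing_rate] <- NA_real_
  }
  n_regions <- length(regions)
  divisions <- c("telencephalon", "diencephalon", "mesencephalon",
                 "metencephalon", "myelencephalon")
  div_of_region <- divisions[pmin(
    ceiling(seq_len(n_regions) / ceiling(n_regions / length(divisions))),
    length(divisions))]
  annotations <- data.frame(
    sample_id = sample_ids,
    structure_name = rep(regions, each = n_rep),
    parent_structure = rep(sprintf("parent_%0*d", max(2L, nchar(n_regions)),
                                   seq_len(n_regions)), each = n_rep),
    division = rep(div_of_region, each = n_rep),
    hemisphere = NA_character_,
    is_white_matter = FALSE,
    stringsAsFactors = FALSE
  )
  structure(list(expression = expr, annotations = annotations,
                 markers = truth$markers, truth = truth),
            class = "labeled_dataset")
}

#' Simulate a matched pair of species datasets
#'
#' Both species share the per-gene cell-type mean profiles and the regional
#' composition trend; the compositional noise around the trend, the
#' measurement noise, replicates, and missing entries are drawn independently
#' per species (so a zero-gradient pair is genuinely null across species). A `discordant_fraction` of genes has its regional profile
#' rank-reversed in species B only (a permutation of the profile values, so the
#' gene's marginal distribution is preserved while its regional pattern is
#' anti-ordered). The homology map is one-to-one over shared genes, and the
#' region correspondence links region i of A with region i of B through a
#' common parent label.
#'
#' @param config A [sim_config()]; `discordant_fraction` must be < 1.
#' @return A list of class `species_pair`: `a`, `b` (labelled datasets),
#'   `homology` (data.frame species_a_gene, species_b_gene), `correspondence`
#'   (data.frame species, region, parent), and `discordant_genes` (species-A
#'   gene IDs whose pattern was reversed in B).
#' @export
simulate_species_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  rng <- local_rng(config$seed)
  truth <- simulate_profiles(config)
  prof <- mixture_profiles(truth)
  # species B shares the composition trend and the per-gene cell-type means,
  # but draws its own composition noise (independent between species)
  comp_b <- simulate_composition(config$n_regions, config$gradient_strength,
                                 seed = config$seed + 2L,
                                 cell_types = config$cell_types)
  truth$composition_b <- comp_b
  prof_b0 <- mixture_profiles(truth, composition = comp_b)

  ds_a <- realize_dataset(config, truth, species_prefix = "hs_",
                          profiles = prof)

  # Discordance is planted in non-marker genes: reversing a marker's profile
  # in one species would falsify that species' marker catalogue (its neuron
  # markers would no longer track its neuron proportions), breaking the
  # within-species contracts the catalogue is meant to satisfy in both species.
  n_disc <- round(config$discordant_fraction * config$n_genes)
  genes_all <- rownames(truth$mu)
  eligible <- which(!genes_all %in% unlist(truth$markers))
  if (n_disc > length(eligible)) {
    stop("discordant_fraction too large for the number of non-marker genes")
  }
  disc_idx <- if (n_disc > 0) sort(sample(eligible, n_disc)) else integer()
  prof_b <- prof_b0
  for (i in disc_idx) {
    v <- prof_b[i, ]
    # rank-reversing permutation: highest value moves to the lowest-ranked
    # region and vice versa; ties resolved by first occurrence
    prof_b[i, ] <- sort(v, decreasing = TRUE)[rank(v, ties.method = "first")]
  }
  truth_b <- truth
  truth_b$mu <- truth$mu  # shared latent means
  ds_b <- realize_dataset(config, truth_b, species_prefix = "mm_",
                          profiles = prof_b)
  genes <- rownames(truth$mu)
  ds_b$expression <- ds_b$expression[genes, , drop = FALSE]
  rownames(ds_b$expression) <- paste0("mm_", genes)
  ds_b$markers <- lapply(truth$markers, function(g) paste0("mm_", g))
  attr(ds_b$markers, "fold_enrichment") <- config$fold_enrichment

  homology <- data.frame(species_a_gene = genes,
                         species_b_gene = paste0("mm_", genes),
                         stringsAsFactors = FALSE)
  n_regions <- config$n_regions
  parents <- sprintf("parent_%0*d", max(2L, nchar(n_regions)),
                     seq_len(n_regions))
  correspondence <- rbind(
    data.frame(species = "a", region = region_names(n_regions, "hs_region"),
               parent = parents, stringsAsFactors = FALSE),
    data.frame(species = "b", region = region_names(n_regions, "mm_region"),
               parent = parents, stringsAsFactors = FALSE)
  )
  structure(list(a = ds_a, b = ds_b, homology = homology,
                 correspondence = correspondence,
                 discordant_genes = genes[sort(disc_idx)]),
            class = "species_pair")
}
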