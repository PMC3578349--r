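#!/usr/bin/env Rscript
# Generate the study datasets: one single-species regional expression matrix
# with a planted cell-type composition gradient, and one matched species pair
# with 10% discordant genes. Everything downstream reads from results/data/.

suppressPackageStartupMessages(library(brainpatterns))

seed <- 1L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg_single <- sim_config(n_genes = 2000, n_regions = 100,
                         n_markers_per_type = 100, gradient_strength = 0.9,
                         noise_sd = 0.2, missing_rate = 0.01, seed = seed)
ds <- simulate_expression(cfg_single)
write_dataset(ds, out, prefix = "single")
message(sprintf("single-species dataset: %d genes x %d samples (%d regions)",
                nrow(ds$expression), ncol(ds$expression),
                cfg_single$n_regions))

cfg_pair <- sim_config(n_genes = 2000, n_regions = 58,
                       n_markers_per_type = 100, gradient_strength = 0.9,
                       noise_sd = 0.05, missing_rate = 0.02,
                       discordant_fraction = 0.1, seed = seed)
pair <- simulate_species_pair(cfg_pair)
write_dataset(pair$a, out, prefix = "species_a")
write_dataset(pair$b, out, prefix = "species_b")
write_table_tsv(pair$homology, file.path(out, "homology.tsv"))
write_table_tsv(pair$correspondence, file.path(out, "correspondence.tsv"))
write_table_tsv(data.frame(gene_id = pair$discordant_genes),
                file.path(out, "discordant_truth.tsv"))
message(sprintf("species pair: %d homologous genes, %d matched regions, %d discordant",
                nrow(pair$homology), cfg_pair$n_regions,
                length(pair$discordant_genes)))
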