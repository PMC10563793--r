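#!/usr/bin/env Rscript

# Step 1: generate the study's synthetic genome.
#
# Builds a genome with planted duplicate-class structure -- ohnolog families
# laid out on paired macrosynteny segments, SSD families with young
# duplication nodes, retroduplicated pairs, singletons -- together with three
# replicate ohnolog data sets, a per-gene feature table and a TPM expression
# matrix. All downstream steps read the tables written here.

suppressMessages(library(duplicability))

out <- "results/tables"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- simulation_config(seed = 20260925, n_chromosomes = 8,
                         genes_per_chromosome = 90,
                         n_ohnolog_families = 50, n_ssd_families = 50,
                         n_retro_pairs = 4, n_prevertebrate_pairs = 3)
sim <- simulate_genome(cfg)
write_genome_tables(sim, out)

reps <- simulate_ohnolog_replicates(sim)
for (k in 1:3)
  write_tsv_table(reps[[k]], file.path(out, sprintf("ohnologs_%d.tsv", k)))
write_tsv_table(sim$truth$pair_truth, file.path(out, "pair_truth.tsv"))

ft <- simulate_feature_table(sim)
write_tsv_table(ft$features, file.path(out, "features.tsv"))
write_expression_matrix(ft$expression, file.path(out, "expression.tsv"))

cat(sprintf("Simulated %d genes on %d chromosomes: %d planted ohnologs, %d SSD genes,\n",
            nrow(sim$genes), cfg$n_chromosomes,
            sum(sim$truth$gene_truth$true_class == "WGD"),
            sum(sim$truth$gene_truth$true_class == "SSD")))
cat(sprintf("%d retro-excluded genes, %d singletons; %d paralog pairs over %d segments.\n",
            sum(sim$truth$gene_truth$true_class == "RETRO_EXCLUDED"),
            sum(sim$truth$gene_truth$true_class == "SINGLETON"),
            nrow(sim$pairs), nrow(sim$segments)))
cat("Tables written under", out, "\n")
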