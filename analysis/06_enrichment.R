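#!/usr/bin/env Rscript

# Step 6: functional-term enrichment and cross-class overlap.
#
# Builds a synthetic flat annotation map in which some terms preferentially
# sample ohnologs (development/regulation-like), some sample SSD genes
# (immunity-like) and some sample singletons (core-cellular-like), then runs
# the two-sided hypergeometric + BH enrichment of each consensus class
# against the whole-gene background and summarises concordant/opposed
# overlaps between classes.

suppressMessages(library(duplicability))

tab <- "results/tables"
labels <- read_tsv_table(file.path(tab, "consensus_labels.tsv"))
universe <- labels$gene_id
cls <- setNames(labels$label, labels$gene_id)

set.seed(20260925)
biased_term <- function(id, favoured, n_genes = 60, bias = 0.7) {
  fav <- universe[cls == favoured]
  n_fav <- round(n_genes * bias)
  data.frame(term_id = id,
             gene_id = c(sample(fav, min(n_fav, length(fav))),
                         sample(setdiff(universe, fav),
                                n_genes - min(n_fav, length(fav)))))
}
ann <- rbind(
  do.call(rbind, lapply(1:6, function(i)
    biased_term(sprintf("wgd_like_%d", i), "WGD"))),
  do.call(rbind, lapply(1:6, function(i)
    biased_term(sprintf("ssd_like_%d", i), "SSD"))),
  do.call(rbind, lapply(1:6, function(i)
    biased_term(sprintf("core_like_%d", i), "SINGLETON", bias = 0.9))),
  simulate_annotations(universe, n_terms = 12, term_size = 60,
                       seed = 20260925))
write_tsv_table(ann, file.path(tab, "annotations.tsv"))

records <- lapply(c(WGD = "WGD", SSD = "SSD", SINGLETON = "SINGLETON"),
                  function(cl)
                    term_enrichment(universe[cls == cl], ann, universe))
for (cl in names(records))
  write_tsv_table(records[[cl]],
                  file.path(tab, sprintf("enrichment_%s.tsv", cl)))

ov <- overlap_summary(records)
write_tsv_table(ov$fractions, file.path(tab, "overlap_fractions.tsv"))
write_tsv_table(ov$intersections_directional,
                file.path(tab, "overlap_intersections.tsv"))

cat("Significant terms per class:\n")
print(ov$n_significant)
cat("\nDirected concordance/opposition fractions:\n")
print(ov$fractions, row.names = FALSE, digits = 3)
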