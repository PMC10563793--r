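#!/usr/bin/env Rscript

# Step 3: derived features.
#
# Computes tissue specificity (tau) and maximal expression from the TPM
# matrix, assigns duplicate ages from the oldest duplication node per
# vertebrate gene family, and summarises per-tissue expression by duplicate
# class (1 TPM floor). Appends the derived columns to the feature table.

suppressMessages(library(duplicability))

tab <- "results/tables"
features <- read_tsv_table(file.path(tab, "features.tsv"))
expr <- read_expression_matrix(file.path(tab, "expression.tsv"))
genes <- read_tsv_table(file.path(tab, "genes.tsv"))
pairs <- read_tsv_table(file.path(tab, "pairs.tsv"))
labels <- read_tsv_table(file.path(tab, "consensus_labels.tsv"))

tau <- tissue_specificity(expr)
features$tau <- tau[match(features$gene_id, rownames(expr))]
features$max_expression <- apply(expr, 1, max)[match(features$gene_id,
                                                     rownames(expr))]

ages <- assign_duplicate_age(genes, pairs)
features$age_from_pairs <- unname(ages[features$gene_id])

write_tsv_table(features, file.path(tab, "features_derived.tsv"))

lab <- labels[, c("gene_id", "label")]
by_class <- split(features$tau, lab$label[match(features$gene_id,
                                                lab$gene_id)])
cat("Median tau by consensus class:\n")
print(vapply(by_class, median, numeric(1), na.rm = TRUE))

tissue_summ <- per_tissue_expression_summary(expr, lab)
write_tsv_table(tissue_summ, file.path(tab, "per_tissue_expression.tsv"))
cat(sprintf("WGD median exceeds SSD median in %d of %d tissues (>= 1 TPM).\n",
            sum(tissue_summ$wgd_gt_ssd), nrow(tissue_summ)))
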