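#!/usr/bin/env Rscript

# Step 4: group comparisons and age/type regressions.
#
# Mann-Whitney comparisons of every feature between WGD, SSD and singleton
# genes (Bonferroni over all tests in the run), then, for duplicates only,
# OLS models feature ~ age + type with transformation selection (none / log /
# Box-Cox by Jarque-Bera on residuals) and the Delta-AIC >= 2 interaction
# rule.

suppressMessages(library(duplicability))

tab <- "results/tables"
features <- read_tsv_table(file.path(tab, "features_derived.tsv"))
labels <- read_tsv_table(file.path(tab, "consensus_labels.tsv"))

tests <- pairwise_feature_tests(
  features[, setdiff(names(features), c("age_from_pairs"))], labels)
write_tsv_table(tests, file.path(tab, "pairwise_tests.tsv"))
sig <- tests[tests$p_adjusted < 0.05, ]
cat(sprintf("%d of %d pairwise comparisons significant after Bonferroni.\n",
            nrow(sig), nrow(tests)))
wgd_ssd <- sig[sig$class_a == "WGD" & sig$class_b == "SSD", ]
cat("WGD vs SSD, significant features and the class with the higher median:\n")
print(wgd_ssd[, c("feature", "direction", "p_adjusted")], row.names = FALSE)

lab <- labels$label[match(features$gene_id, labels$gene_id)]
dup <- lab %in% c("WGD", "SSD") & !is.na(features$age)
feature_cols <- setdiff(names(features),
                        c("gene_id", "age", "age_from_pairs"))
fits <- list()
for (f in feature_cols) {
  fit <- tryCatch(
    suppressWarnings(fit_feature_age_model(features[[f]][dup],
                                           features$age[dup], lab[dup],
                                           feature = f)),
    error = function(e) NULL)
  if (is.null(fit)) next
  type_row <- fit$coefficients[grepl("^types", fit$coefficients$term), ][1, ]
  fits[[f]] <- data.frame(
    feature = f, transformation = fit$transformation,
    interaction = fit$interaction_included,
    type_estimate = type_row$estimate, type_p = type_row$p)
}
reg <- do.call(rbind, fits)
write_tsv_table(reg, file.path(tab, "age_type_models.tsv"))
cat(sprintf("\n%d features keep a significant type effect when age is in the model.\n",
            sum(reg$type_p < 0.05)))
print(reg, row.names = FALSE, digits = 3)
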