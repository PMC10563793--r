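test_that("identical seed and config give byte-identical tables", {
  cfg <- simulation_config(seed = 5)
  s1 <- simulate_genome(cfg)
  s2 <- simulate_genome(cfg)
  expect_identical(s1$genes, s2$genes)
  expect_identical(s1$pairs, s2$pairs)
  expect_identical(s1$segments, s2$segments)
  expect_identical(s1$truth, s2$truth)
  expect_identical(simulate_feature_table(s1), simulate_feature_table(s2))
  expect_identical(simulate_ohnolog_replicates(s1),
                   simulate_ohnolog_replicates(s2))
})

test_that("planted structure satisfies the classification rules", {
  cfg <- simulation_config(seed = 9)
  sim <- simulate_genome(cfg)
  gt <- sim$truth$gene_truth
  pt <- sim$truth$pair_truth

  # every gene has exactly one true class; every pair references real genes
  expect_equal(nrow(gt), nrow(sim$genes))
  expect_true(all(c(pt$gene_a, pt$gene_b) %in% sim$genes$gene_id))

  # retro pairs satisfy the intron rule; other genes never lack introns
  retro <- pt[pt$true_type == "RETRO", ]
  for (i in seq_len(nrow(retro))) {
    ic <- sim$genes$intron_count[match(c(retro$gene_a[i], retro$gene_b[i]),
                                       sim$genes$gene_id)]
    expect_equal(min(ic), 0)
    expect_gte(max(ic), 3)
  }
  non_retro <- setdiff(gt$gene_id, c(retro$gene_a, retro$gene_b))
  expect_true(all(sim$genes$intron_count[match(non_retro,
                                               sim$genes$gene_id)] >= 1))

  # SSD nodes strictly inside the vertebrate lineage
  ssd <- pt[pt$true_type == "SSD", ]
  ages <- default_node_ages()
  expect_true(all(ages[ssd$duplication_node] < ages["Vertebrata"]))

  # singleton genes appear in no vertebrate-lineage pair
  vert_genes <- unique(c(pt$gene_a[pt$true_type %in% c("WGD", "SSD", "RETRO")],
                         pt$gene_b[pt$true_type %in% c("WGD", "SSD",
                                                       "RETRO")]))
  singles <- gt$gene_id[gt$true_class == "SINGLETON"]
  expect_length(intersect(singles, vert_genes), 0)
})

test_that("without ohnolog families segments exist but carry no valid chain", {
  cfg <- simulation_config(seed = 2, n_ohnolog_families = 0)
  sim <- simulate_genome(cfg)
  expect_gt(nrow(sim$segments), 0)
  expect_equal(nrow(call_ohnolog_pairs(sim$pairs, sim$genes)), 0)
})

test_that("infeasible layouts raise a sizing error naming the constraint", {
  cfg <- simulation_config(seed = 1, n_chromosomes = 2,
                           genes_per_chromosome = 8,
                           n_ohnolog_families = 12)
  expect_error(simulate_genome(cfg), "capacity")
  expect_error(simulation_config(n_ohnolog_families = 2), "at least three")
  expect_error(simulation_config(dataset_noise = 1.5), "dataset_noise")
  expect_error(simulation_config(n_ssd_families = -1), "non-negative")
})

test_that("replicate ohnolog sets degrade with dataset noise as binomials", {
  cfg0 <- simulation_config(seed = 4, dataset_noise = 0)
  sim0 <- simulate_genome(cfg0)
  reps0 <- simulate_ohnolog_replicates(sim0)
  expect_identical(pair_keys(reps0[[1]]), pair_keys(reps0[[2]]))
  expect_identical(pair_keys(reps0[[1]]), pair_keys(reps0[[3]]))
  truth_wgd <- sim0$truth$pair_truth[sim0$truth$pair_truth$true_type == "WGD", ]
  expect_setequal(pair_keys(reps0[[1]]), pair_keys(truth_wgd))

  # at noise 0.1 with 99 planted pairs, ~90% retained per replicate
  cfg <- simulation_config(seed = 4, n_chromosomes = 10,
                           genes_per_chromosome = 80,
                           n_ohnolog_families = 99, n_ssd_families = 0,
                           n_retro_pairs = 0, dataset_noise = 0.1)
  sim <- simulate_genome(cfg)
  reps <- simulate_ohnolog_replicates(sim)
  retained <- vapply(reps, nrow, integer(1))
  # 4 sd binomial band around 99 * 0.9
  expect_true(all(abs(retained - 89.1) < 4 * sqrt(99 * 0.9 * 0.1) + 1))

  # noise 1 with an empty addition pool gives empty sets
  cfg1 <- simulation_config(seed = 4, n_ssd_families = 0, n_retro_pairs = 0,
                            dataset_noise = 1)
  reps1 <- simulate_ohnolog_replicates(simulate_genome(cfg1))
  expect_true(all(vapply(reps1, nrow, integer(1)) == 0))
})

test_that("per-class feature means are calibrated to the configured shifts", {
  # age confounding off so the class means are exactly base + shift * sd
  specs <- list(
    f_norm = list(dist = "norm", base = 10, sd = 2,
                  shift = c(WGD = 1, SSD = -1, SINGLETON = 0), age_beta = 0),
    f_lnorm = list(dist = "lnorm", base = 1, sd = 0.4,
                   shift = c(WGD = 0.5, SSD = 0, SINGLETON = 0),
                   age_beta = 0))
  cfg <- simulation_config(seed = 8, n_chromosomes = 10,
                           genes_per_chromosome = 100,
                           n_ohnolog_families = 120, n_ssd_families = 120,
                           feature_specs = specs,
                           age_confound_strength = 0)
  sim <- simulate_genome(cfg)
  ft <- simulate_feature_table(sim)
  cls <- sim$truth$gene_truth$true_class
  for (cl in c("WGD", "SSD")) {
    x <- ft$features$f_norm[cls == cl]
    target <- 10 + specs$f_norm$shift[cl] * 2
    expect_lt(abs(mean(x) - target), 3 * 2 / sqrt(length(x)))
    xl <- log(ft$features$f_lnorm[cls == cl])
    targetl <- 1 + specs$f_lnorm$shift[cl] * 0.4
    expect_lt(abs(mean(xl) - targetl), 3 * 0.4 / sqrt(length(xl)))
  }
  # unknown distribution family is a config error
  bad <- specs
  bad$f_norm$dist <- "cauchy"
  expect_error(simulation_config(feature_specs = bad), "cauchy")
})

test_that("age confounding injects the requested correlation and can be
           switched off", {
  # zero class shifts isolate the injected coupling: at strength 0 the only
  # remaining age correlation is sampling noise
  specs0 <- lapply(default_feature_specs(), function(sp) {
    sp$shift[] <- 0
    sp
  })
  cfg0 <- simulation_config(seed = 3, n_chromosomes = 10,
                            genes_per_chromosome = 110,
                            n_ohnolog_families = 150, n_ssd_families = 150,
                            feature_specs = specs0,
                            age_confound_strength = 0)
  ft0 <- simulate_feature_table(simulate_genome(cfg0))
  dup <- !is.na(ft0$features$age)
  # sampling-error bound: |r| < 0.1 for all features at n ~ 600
  for (f in names(specs0)) {
    r <- cor(ft0$features[[f]][dup], ft0$features$age[dup])
    expect_lt(abs(r), 0.1)
  }
  cfg1 <- simulation_config(seed = 3, n_chromosomes = 10,
                            genes_per_chromosome = 110,
                            n_ohnolog_families = 150, n_ssd_families = 150,
                            age_confound_strength = 1)
  ft1 <- simulate_feature_table(simulate_genome(cfg1))
  dup1 <- !is.na(ft1$features$age)
  expect_gt(cor(ft1$features$age_only_score[dup1], ft1$features$age[dup1]),
            0.9)
})

test_that("genome tables and configs round-trip through TSV and YAML", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(seed = 6, n_ohnolog_families = 6,
                           n_ssd_families = 3)
  sim <- simulate_genome(cfg)
  write_genome_tables(sim, dir)
  genes2 <- read_tsv_table(file.path(dir, "genes.tsv"))
  expect_equal(genes2, sim$genes)
  cfg2 <- read_simulation_config(file.path(dir, "config.yaml"))
  expect_equal(unclass(cfg2)[order(names(cfg2))],
               unclass(cfg)[order(names(cfg))], tolerance = 1e-9)
  sim2 <- simulate_genome(cfg2)
  expect_identical(sim2$genes, sim$genes)
})
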