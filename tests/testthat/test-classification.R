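# Synteny-block ohnolog calling ------------------------------------------

test_that("blocks of three linking pairs within the gap limit are called", {
  # S1 anchors at 0, 3, 9 (gaps 2 and 5); S2 anchors at 0, 1, 2
  genes <- rbind(
    toy_genes(sprintf("a%d", 0:9), "chr1", 0:9, segments = "S1"),
    toy_genes(sprintf("b%d", 0:2), "chr2", 0:2, segments = "S2"))
  pairs <- toy_pairs(c("a0", "a3", "a9"), c("b0", "b1", "b2"))
  called <- call_ohnolog_pairs(pairs, genes)
  expect_setequal(pair_keys(called), pair_keys(pairs))
})

test_that("two linking pairs are never enough, even at gap zero", {
  genes <- rbind(
    toy_genes(c("a0", "a1"), "chr1", 0:1, segments = "S1"),
    toy_genes(c("b0", "b1"), "chr2", 0:1, segments = "S2"))
  pairs <- toy_pairs(c("a0", "a1"), c("b0", "b1"))
  expect_equal(nrow(call_ohnolog_pairs(pairs, genes)), 0)
})

test_that("a nine-gene gap splits four pairs into two sub-minimum runs", {
  # anchors on S1 at 0,1,11,12: gap of 9 genes between positions 1 and 11
  genes <- rbind(
    toy_genes(sprintf("a%d", 0:12), "chr1", 0:12, segments = "S1"),
    toy_genes(sprintf("b%d", 0:3), "chr2", 0:3, segments = "S2"))
  pairs <- toy_pairs(c("a0", "a1", "a11", "a12"), c("b0", "b1", "b2", "b3"))
  expect_equal(nrow(call_ohnolog_pairs(pairs, genes)), 0)
  # verified against exhaustive enumeration on the same toy instance
  expect_equal(nrow(brute_force_ohnologs(pairs, genes)), 0)
})

test_that("ohnolog calling matches the exhaustive-chain oracle and is
           order-independent and monotone in the rule parameters", {
  for (seed in 1:25) {
    inst <- random_synteny_instance(seed)
    called <- call_ohnolog_pairs(inst$pairs, inst$genes)
    oracle <- brute_force_ohnologs(inst$pairs, inst$genes)
    expect_identical(pair_keys(called), pair_keys(oracle),
                     label = paste("instance", seed))

    shuffled <- inst$pairs[sample(nrow(inst$pairs)), , drop = FALSE]
    expect_identical(pair_keys(call_ohnolog_pairs(shuffled, inst$genes)),
                     pair_keys(called))

    looser_gap <- call_ohnolog_pairs(inst$pairs, inst$genes, max_gap = 12)
    smaller_block <- call_ohnolog_pairs(inst$pairs, inst$genes, min_block = 2)
    expect_true(all(pair_keys(called) %in% pair_keys(looser_gap)))
    expect_true(all(pair_keys(called) %in% pair_keys(smaller_block)))
  }
})

test_that("pairs referencing unknown genes raise a referential error", {
  genes <- toy_genes(c("a0", "a1"), "chr1", 0:1, segments = "S1")
  pairs <- toy_pairs("a0", "ghost")
  expect_error(call_ohnolog_pairs(pairs, genes), "ghost")
})

# Microsynteny ------------------------------------------------------------

test_that("microsynteny requires a neighbouring pair within the window on
           both sides", {
  genes <- rbind(toy_genes(sprintf("x%d", 0:10), "chr1", 0:10),
                 toy_genes(sprintf("y%d", 0:10), "chr2", 0:10))
  # tested pair (x5, y5); neighbour at offsets (+2, -3) links the regions
  pairs <- toy_pairs(c("x5", "x7"), c("y5", "y2"))
  expect_true(check_microsynteny(c("x5", "y5"), pairs, genes))
  # offsets (+6, +1): x-side neighbour outside the 5-gene window
  pairs2 <- rbind(toy_pairs("x5", "y5"), toy_pairs("x11", "y6"))
  expect_false(check_microsynteny(c("x5", "y5"), pairs2, genes))
  # no other pairs at all
  expect_false(check_microsynteny(c("x5", "y5"), toy_pairs("x5", "y5"),
                                  genes))
})

# Retroduplication rules --------------------------------------------------

test_that("all four retroduplication rule branches behave as stated", {
  mk <- function(ia, ib) {
    genes <- rbind(toy_genes("p1", "chr1", 0, introns = ia),
                   toy_genes("p2", "chr2", 0, introns = ib),
                   toy_genes(c("q1", "q2"), c("chr1", "chr2"), c(3, 3),
                             introns = 5))
    genes
  }
  no_pairs <- toy_pairs(character(0), character(0))

  # 0 vs >= 3 introns: retro regardless of microsynteny
  genes <- mk(0, 5)
  with_micro <- toy_pairs("q1", "q2")  # neighbours of both members
  expect_true(detect_retroduplication(c("p1", "p2"), genes, no_pairs))
  expect_true(detect_retroduplication(c("p1", "p2"), genes, with_micro))

  # 0 vs < 3: retro only without microsynteny
  genes <- mk(0, 2)
  expect_true(detect_retroduplication(c("p1", "p2"), genes, no_pairs))
  expect_false(detect_retroduplication(c("p1", "p2"), genes, with_micro))

  # no zero-intron member: never retro
  genes <- mk(2, 7)
  expect_false(detect_retroduplication(c("p1", "p2"), genes, no_pairs))

  # both members intronless, no microsynteny: retro
  genes <- mk(0, 0)
  expect_true(detect_retroduplication(c("p1", "p2"), genes, no_pairs))

  # symmetric under member swap
  genes <- mk(0, 5)
  expect_identical(detect_retroduplication(c("p1", "p2"), genes, no_pairs),
                   detect_retroduplication(c("p2", "p1"), genes, no_pairs))
  # missing intron count names the gene
  genes$intron_count[1] <- NA
  expect_error(detect_retroduplication(c("p1", "p2"), genes, no_pairs), "p1")
})

# Pair labelling precedence ----------------------------------------------

test_that("pair labels follow the PRE_VERTEBRATE > WGD > RETRO > SSD
           precedence", {
  genes <- rbind(toy_genes(c("a", "b"), "chr1", 0:1, introns = c(0, 5)),
                 toy_genes(c("c", "d"), "chr2", 0:1, introns = 5),
                 toy_genes(c("e", "f"), "chr3", 0:1, introns = 5))
  pairs <- rbind(toy_pairs("a", "b", "Mammalia"),      # retro introns
                 toy_pairs("c", "d", "Chordata"),      # pre-vertebrate
                 toy_pairs("e", "f", "Vertebrata"))    # in ohnolog set
  ohno <- data.frame(gene_a = c("e", "c"), gene_b = c("f", "d"))
  lab <- label_pairs(pairs, ohno, genes)
  expect_equal(as.character(lab$pair_label), c("RETRO", "PRE_VERTEBRATE",
                                               "WGD"))
  # unknown node is a config error
  expect_error(label_pairs(toy_pairs("a", "b", "Atlantis"), ohno, genes),
               "Atlantis")
})

# Gene labels and consensus -----------------------------------------------

test_that("gene labels partition the universe with stated precedence", {
  genes <- toy_genes(sprintf("g%d", 1:8), "chr1", 0:7)
  lp <- data.frame(
    gene_a = c("g1", "g1", "g3", "g4", "g5", "g6"),
    gene_b = c("g2", "g3", "g4", "g5", "g6", "g7"),
    pair_label = factor(c("WGD", "WGD", "SSD", "SSD", "RETRO",
                          "PRE_VERTEBRATE"),
                        levels = c("WGD", "SSD", "RETRO", "PRE_VERTEBRATE")))
  labs <- assign_gene_labels(lp, genes)
  got <- setNames(labs$label, labs$gene_id)
  expect_equal(unname(got[c("g1", "g2")]), c("WGD", "WGD"))
  expect_equal(unname(got["g3"]), "EXCLUDED")  # WGD + SSD pairs
  expect_equal(labs$exclusion_reason[labs$gene_id == "g3"], "MIXED_TYPE")
  expect_equal(unname(got["g5"]), "EXCLUDED")  # retro wins over SSD
  expect_equal(labs$exclusion_reason[labs$gene_id == "g5"], "RETRO_PAIR")
  expect_equal(unname(got["g7"]), "SINGLETON")
  expect_equal(labs$singleton_subtype[labs$gene_id == "g7"],
               "PRE_VERTEBRATE_ONLY")
  expect_equal(labs$singleton_subtype[labs$gene_id == "g8"], "NO_PARALOGS")
  # exactly one label each
  expect_equal(nrow(labs), 8)
})

test_that("majority vote takes any 2-of-3 label and excludes full splits", {
  mk <- function(labels) data.frame(gene_id = sprintf("g%d",
                                                      seq_along(labels)),
                                    label = labels,
                                    exclusion_reason = NA_character_,
                                    singleton_subtype = NA_character_)
  sets <- list(mk(c("WGD", "SSD", "WGD")),
               mk(c("WGD", "SSD", "SSD")),
               mk(c("SSD", "SSD", "SINGLETON")))
  cons <- majority_vote(sets)
  expect_equal(cons$label, c("WGD", "SSD", "EXCLUDED"))
  expect_equal(cons$exclusion_reason[3], "NO_MAJORITY")
  # mismatched universes are an error
  sets[[2]] <- sets[[2]][-1, ]
  expect_error(majority_vote(sets), "universe")
})

# Round trip and summary --------------------------------------------------

test_that("noise-free synthetic genomes classify back to the planted truth", {
  cfg <- simulation_config(seed = 11)
  sim <- simulate_genome(cfg)
  reps <- simulate_ohnolog_replicates(sim)
  res <- classify_genes(sim$genes, sim$pairs, reps)
  cons <- res$consensus$label[match(sim$truth$gene_truth$gene_id,
                                    res$consensus$gene_id)]
  expect_equal(cons, truth_labels(sim))

  # the synteny route recovers exactly the planted ohnolog pairs
  called <- call_ohnolog_pairs(sim$pairs, sim$genes)
  planted <- sim$truth$pair_truth[sim$truth$pair_truth$true_type == "WGD", ]
  expect_setequal(pair_keys(called), pair_keys(planted))
})

test_that("classification summary partitions pairs and genes", {
  cfg <- simulation_config(seed = 21)
  sim <- simulate_genome(cfg)
  res <- classify_genes(sim$genes, sim$pairs, simulate_ohnolog_replicates(sim))
  summ <- classification_summary(res)
  pc <- summ$pair_counts
  expect_equal(pc$wgd_pairs + pc$non_wgd_pairs, rep(nrow(sim$pairs), 3))
  expect_equal(pc$retro_pairs + pc$prevertebrate_pairs + pc$presumed_ssd_pairs,
               pc$non_wgd_pairs)
  gcounts <- summ$gene_counts
  expect_true(all(rowSums(gcounts[, c("WGD", "SSD", "SINGLETON",
                                      "EXCLUDED")]) == nrow(sim$genes)))
})

test_that("an empty pair table makes every gene a singleton", {
  genes <- toy_genes(sprintf("g%d", 1:5), "chr1", 0:4)
  empty <- toy_pairs(character(0), character(0))
  ohno <- data.frame(gene_a = character(0), gene_b = character(0))
  res <- classify_genes(genes, empty, list(ohno, ohno, ohno))
  expect_true(all(res$consensus$label == "SINGLETON"))
})
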