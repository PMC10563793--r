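#' Simulation configuration for the synthetic genome generator
#'
#' Bundles and validates every knob of the synthetic-data module. The
#' defaults define the study conditions used throughout the package's tests
#' and analysis drivers: ohnolog families planted on paired macrosynteny
#' segments as chains of at least three linking pairs (anchor gaps 0-2
#' genes), SSD families with duplication nodes strictly inside the vertebrate
#' lineage, retroduplicated pairs planted as intronless copies of multi-intron
#' parents, and an age-confounded feature structure in which ohnologs are
#' longer, slower-evolving, more constrained and more broadly expressed.
#'
#' @param seed integer master seed; all outputs are deterministic given it.
#' @param n_chromosomes number of chromosomes.
#' @param genes_per_chromosome capacity of each chromosome in genes.
#' @param n_ohnolog_families number of 2-gene ohnolog families; planted in
#'   synteny blocks of 3-5 linking pairs, so must be 0 or >= 3.
#' @param n_ssd_families number of 2-gene SSD families.
#' @param n_retro_pairs number of planted retroduplicated pairs.
#' @param n_prevertebrate_pairs number of pairs with a pre-vertebrate
#'   duplication node (their genes are true singletons).
#' @param n_singletons number of filler singleton genes, or `NULL` to fill
#'   every chromosome to capacity.
#' @param n_decoy_segments macrosynteny segments containing no linking pairs.
#' @param n_tissues number of expression conditions (tissues/stages).
#' @param node_age_table named vector of node ages in MY.
#' @param age_unit MY per duplicate-age unit (default 50).
#' @param feature_specs per-feature generation spec, see
#'   [default_feature_specs].
#' @param age_confound_strength global multiplier on each feature's age
#'   coupling (`age_beta`); 0 removes all age confounding.
#' @param dataset_noise probability that a planted ohnolog pair is dropped
#'   from (or a planted SSD pair spuriously added to) each replicate ohnolog
#'   set.
#' @param expr_breadth per-class fraction of conditions in which a gene is
#'   expressed.
#' @param expr_level_log per-class mean of log TPM in expressed conditions.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_chromosomes = 4,
                              genes_per_chromosome = 60,
                              n_ohnolog_families = 12,
                              n_ssd_families = 10,
                              n_retro_pairs = 3,
                              n_prevertebrate_pairs = 2,
                              n_singletons = NULL,
                              n_decoy_segments = 2,
                              n_tissues = 12,
                              node_age_table = default_node_ages(),
                              age_unit = 50,
                              feature_specs = default_feature_specs(),
                              age_confound_strength = 1,
                              dataset_noise = 0,
                              expr_breadth = c(WGD = 0.9, SSD = 0.2,
                                               SINGLETON = 0.6),
                              expr_level_log = c(WGD = log(50), SSD = log(15),
                                                 SINGLETON = log(25))) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = n_chromosomes,
              genes_per_chromosome = genes_per_chromosome,
              n_ohnolog_families = n_ohnolog_families,
              n_ssd_families = n_ssd_families,
              n_retro_pairs = n_retro_pairs,
              n_prevertebrate_pairs = n_prevertebrate_pairs,
              n_singletons = n_singletons,
              n_decoy_segments = n_decoy_segments,
              n_tissues = n_tissues,
              node_age_table = node_age_table, age_unit = age_unit,
              feature_specs = feature_specs,
              age_confound_strength = age_confound_strength,
              dataset_noise = dataset_noise,
              expr_breadth = expr_breadth, expr_level_log = expr_level_log)
  counts <- cfg[c("n_chromosomes", "genes_per_chromosome",
                  "n_ohnolog_families", "n_ssd_families", "n_retro_pairs",
                  "n_prevertebrate_pairs", "n_decoy_segments", "n_tissues")]
  if (any(unlist(counts) < 0)) stop2("counts must be non-negative")
  if (cfg$dataset_noise < 0 || cfg$dataset_noise > 1)
    stop2("dataset_noise must be in [0, 1]")
  if (any(node_age_table <= 0)) stop2("node ages must be strictly positive")
  if (n_ohnolog_families > 0 && n_ohnolog_families < 3)
    stop2("ohnolog families are planted in synteny blocks of at least three ",
          "linking pairs; n_ohnolog_families must be 0 or >= 3")
  if (n_ohnolog_families > 0 && n_chromosomes < 2)
    stop2("ohnolog blocks need at least two chromosomes")
  for (nm in names(feature_specs)) {
    sp <- feature_specs[[nm]]
    if (!sp$dist %in% c("norm", "lnorm"))
      stop2("unknown distribution family '", sp$dist, "' for feature ", nm)
    if (any(!is.finite(sp$shift)))
      stop2("per-class shifts must be finite for feature ", nm)
  }
  structure(cfg, class = "simulation_config")
}

#' Default per-feature generation specs
#'
#' Each spec gives a distribution family (`norm` or `lnorm`; the base and
#' per-class shift apply on the log scale for `lnorm`), a baseline, a noise
#' scale, per-class location shifts in units of the noise scale, and an
#' `age_beta` coupling (noise-scale units per standard deviation of duplicate
#' age, multiplied by the config's `age_confound_strength`). Directions mirror
#' the planted biology: ohnologs longer, more domain-rich, slower evolving,
#' more haploinsufficiency-intolerant and more broadly/highly expressed; SSD
#' paralogs the opposite extreme; singletons intermediate. `age_only_score`
#' is a pure age proxy with no class shift of its own, planted to exercise
#' the age-controlled importance protocol.
#'
#' @return Named list of feature specs.
#' @export
default_feature_specs <- function() {
  spec <- function(dist, base, sd, wgd, ssd, singleton = 0, age_beta = 0)
    list(dist = dist, base = base, sd = sd,
         shift = c(WGD = wgd, SSD = ssd, SINGLETON = singleton),
         age_beta = age_beta)
  list(
    genomic_length = spec("lnorm", log(3e4), 0.9,  1.0, -0.6, 0, 1.0),
    cds_length     = spec("lnorm", log(1500), 0.5, 0.8, -0.5, 0, 1.0),
    intron_count   = spec("lnorm", log(8),   0.6,  0.8, -0.5, 0, 0.5),
    domains        = spec("norm", 4, 2,           0.8, -0.5, 0, 0),
    unique_domains = spec("norm", 3, 1.5,         1.2, -0.7, 0, 0),
    dnds           = spec("lnorm", log(0.25), 0.6, -0.9, 0.5, 0, -0.5),
    pli            = spec("norm", 0, 1,           1.0, -0.4, 0, 0),
    missense_z     = spec("norm", 1, 1.2,         0.8, -0.4, 0, 0),
    rvis           = spec("norm", 0, 1,          -0.8,  0.4, 0, 0),
    isoform_count  = spec("norm", 5, 2.5,         0.7, -0.8, 0, 0),
    ppis           = spec("lnorm", log(8), 0.8,   0.4, -0.3, 0, 0),
    age_only_score = spec("norm", 0, 1,           0,    0,   0, 5)
  )
}

#' Simulate a genome with planted duplicate-class structure
#'
#' Generates the gene table, paralog-pair table and macrosynteny-segment
#' table that the classification pipeline consumes, together with the ground
#' truth of the planted structure. Ohnolog families are laid out on paired
#' segments as chains of linking pairs satisfying the block rule (>= 3 pairs,
#' anchor gaps <= 8 genes); retro pairs copy a multi-intron parent to a
#' random location with zero introns; SSD families carry duplication nodes
#' strictly inside the vertebrate lineage; all other genes are singletons
#' (some with pre-vertebrate-only pairs). Non-retro genes always have at
#' least one intron so no planted pair trips the retroduplication rule by
#' accident.
#'
#' @param config a [simulation_config].
#' @return List with `genes`, `pairs`, `segments` data frames, `truth` (list
#'   with `gene_truth`, `pair_truth`, `informative_features`,
#'   `age_only_features`) and the `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)

  node_ages <- config$node_age_table
  root_age <- node_ages[["Vertebrata"]]
  ssd_nodes <- names(node_ages)[node_ages < root_age]
  pre_nodes <- names(node_ages)[node_ages > root_age]
  if (config$n_ssd_families > 0 && length(ssd_nodes) == 0)
    stop2("node-age table has no node younger than the vertebrate root")
  if (config$n_prevertebrate_pairs > 0 && length(pre_nodes) == 0)
    stop2("node-age table has no pre-vertebrate node")

  # --- block sizing: chunks of 3-5 linking pairs
  block_sizes <- integer(0)
  rem <- config$n_ohnolog_families
  while (rem > 0) {
    take <- if (rem <= 5) rem else 3L
    block_sizes <- c(block_sizes, take)
    rem <- rem - take
  }

  gene_counter <- 0L
  new_ids <- function(n) {
    ids <- sprintf("g%04d", gene_counter + seq_len(n))
    gene_counter <<- gene_counter + n
    ids
  }

  # units per chromosome; a unit is a data frame of gene rows kept contiguous
  units <- vector("list", config$n_chromosomes)
  loads <- rep(0L, config$n_chromosomes)
  add_unit <- function(chrom, df) {
    units[[chrom]][[length(units[[chrom]]) + 1L]] <<- df
    loads[chrom] <<- loads[chrom] + nrow(df)
  }
  least_loaded <- function(k) order(loads, stats::runif(length(loads)))[seq_len(k)]

  gene_row <- function(id, introns, segment = NA_character_)
    data.frame(gene_id = id, intron_count = introns, segment_id = segment,
               stringsAsFactors = FALSE)
  draw_introns <- function(n) 1L + stats::rpois(n, 6)

  seg_counter <- 0L
  new_seg <- function() {
    seg_counter <<- seg_counter + 1L
    sprintf("seg%02d", seg_counter)
  }

  pair_rows <- list()
  truth_pairs <- list()
  truth_genes <- list()
  fam_counter <- 0L

  # --- ohnolog blocks
  for (bs in block_sizes) {
    chroms <- least_loaded(2)
    seg_a <- new_seg(); seg_b <- new_seg()
    anchors_a <- new_ids(bs); anchors_b <- new_ids(bs)
    reversed <- stats::runif(1) < 0.3
    order_b <- if (reversed) rev(seq_len(bs)) else seq_len(bs)

    build_segment <- function(anchors, seg_id) {
      rows <- list()
      for (i in seq_along(anchors)) {
        rows[[length(rows) + 1L]] <-
          gene_row(anchors[i], draw_introns(1), seg_id)
        if (i < length(anchors)) {
          n_fill <- sample(0:2, 1)
          if (n_fill > 0) {
            fids <- new_ids(n_fill)
            rows[[length(rows) + 1L]] <-
              gene_row(fids, draw_introns(n_fill), seg_id)
            truth_genes[[length(truth_genes) + 1L]] <<-
              data.frame(gene_id = fids, true_class = "SINGLETON",
                         family_id = NA_character_)
          }
        }
      }
      do.call(rbind, rows)
    }
    add_unit(chroms[1], build_segment(anchors_a, seg_a))
    add_unit(chroms[2], build_segment(anchors_b[order_b], seg_b))

    for (i in seq_len(bs)) {
      fam_counter <- fam_counter + 1L
      fam <- sprintf("fam%03d", fam_counter)
      pair_rows[[length(pair_rows) + 1L]] <-
        data.frame(gene_a = anchors_a[i], gene_b = anchors_b[i],
                   duplication_node = "Vertebrata")
      truth_pairs[[length(truth_pairs) + 1L]] <-
        data.frame(gene_a = anchors_a[i], gene_b = anchors_b[i],
                   duplication_node = "Vertebrata", true_type = "WGD",
                   family_id = fam)
      truth_genes[[length(truth_genes) + 1L]] <-
        data.frame(gene_id = c(anchors_a[i], anchors_b[i]),
                   true_class = "WGD", family_id = fam)
    }
  }

  # --- decoy segments: contiguous singleton runs with segment ids, no pairs
  for (d in seq_len(config$n_decoy_segments)) {
    n <- sample(4:8, 1)
    ids <- new_ids(n)
    add_unit(least_loaded(1), gene_row(ids, draw_introns(n), new_seg()))
    truth_genes[[length(truth_genes) + 1L]] <-
      data.frame(gene_id = ids, true_class = "SINGLETON",
                 family_id = NA_character_)
  }

  scatter_gene <- function(df) add_unit(least_loaded(1), df)

  # --- SSD families
  for (s in seq_len(config$n_ssd_families)) {
    fam_counter <- fam_counter + 1L
    fam <- sprintf("fam%03d", fam_counter)
    ids <- new_ids(2)
    node <- sample(ssd_nodes, 1)
    scatter_gene(gene_row(ids[1], draw_introns(1)))
    scatter_gene(gene_row(ids[2], draw_introns(1)))
    pair_rows[[length(pair_rows) + 1L]] <-
      data.frame(gene_a = ids[1], gene_b = ids[2], duplication_node = node)
    truth_pairs[[length(truth_pairs) + 1L]] <-
      data.frame(gene_a = ids[1], gene_b = ids[2], duplication_node = node,
                 true_type = "SSD", family_id = fam)
    truth_genes[[length(truth_genes) + 1L]] <-
      data.frame(gene_id = ids, true_class = "SSD", family_id = fam)
  }

  # --- retro pairs: multi-intron parent, intronless copy elsewhere
  for (r in seq_len(config$n_retro_pairs)) {
    ids <- new_ids(2)
    node <- sample(ssd_nodes, 1)
    scatter_gene(gene_row(ids[1], sample(3:12, 1)))
    scatter_gene(gene_row(ids[2], 0L))
    pair_rows[[length(pair_rows) + 1L]] <-
      data.frame(gene_a = ids[1], gene_b = ids[2], duplication_node = node)
    truth_pairs[[length(truth_pairs) + 1L]] <-
      data.frame(gene_a = ids[1], gene_b = ids[2], duplication_node = node,
                 true_type = "RETRO", family_id = NA_character_)
    truth_genes[[length(truth_genes) + 1L]] <-
      data.frame(gene_id = ids, true_class = "RETRO_EXCLUDED",
                 family_id = NA_character_)
  }

  # --- pre-vertebrate pairs: genes are true singletons
  for (p in seq_len(config$n_prevertebrate_pairs)) {
    ids <- new_ids(2)
    node <- sample(pre_nodes, 1)
    scatter_gene(gene_row(ids[1], draw_introns(1)))
    scatter_gene(gene_row(ids[2], draw_introns(1)))
    pair_rows[[length(pair_rows) + 1L]] <-
      data.frame(gene_a = ids[1], gene_b = ids[2], duplication_node = node)
    truth_pairs[[length(truth_pairs) + 1L]] <-
      data.frame(gene_a = ids[1], gene_b = ids[2], duplication_node = node,
                 true_type = "PRE_VERTEBRATE", family_id = NA_character_)
    truth_genes[[length(truth_genes) + 1L]] <-
      data.frame(gene_id = ids, true_class = "SINGLETON",
                 family_id = NA_character_)
  }

  if (any(loads > config$genes_per_chromosome))
    stop2("requested families exceed chromosome capacity: chromosome load(s) ",
          paste(loads[loads > config$genes_per_chromosome], collapse = ", "),
          " > genes_per_chromosome = ", config$genes_per_chromosome,
          "; increase genes_per_chromosome or n_chromosomes")

  # --- filler singletons
  if (is.null(config$n_singletons)) {
    fills <- config$genes_per_chromosome - loads
  } else {
    free <- sum(config$genes_per_chromosome - loads)
    if (config$n_singletons > free)
      stop2("requested families exceed chromosome capacity: ",
            config$n_singletons, " singletons requested but only ", free,
            " free gene slots remain")
    fills <- rep(0L, config$n_chromosomes)
    rem <- config$n_singletons
    while (rem > 0) {
      ch <- least_loaded(1)
      fills[ch] <- fills[ch] + 1L
      loads[ch] <- loads[ch] + 1L
      rem <- rem - 1L
    }
    loads <- loads - fills  # add_unit below re-adds
  }
  for (ch in seq_len(config$n_chromosomes)) {
    if (fills[ch] > 0) {
      ids <- new_ids(fills[ch])
      for (id in ids) add_unit(ch, gene_row(id, draw_introns(1)))
      truth_genes[[length(truth_genes) + 1L]] <-
        data.frame(gene_id = ids, true_class = "SINGLETON",
                   family_id = NA_character_)
    }
  }

  # --- shuffle units within chromosomes, flatten, assign order indices
  gene_tabs <- list()
  for (ch in seq_len(config$n_chromosomes)) {
    u <- units[[ch]]
    if (length(u) == 0) next
    u <- u[sample.int(length(u))]
    df <- do.call(rbind, u)
    df$chromosome <- sprintf("chr%d", ch)
    df$order_index <- seq_len(nrow(df)) - 1L
    gene_tabs[[ch]] <- df
  }
  genes <- do.call(rbind, gene_tabs)
  rownames(genes) <- NULL
  genes <- genes[, c("gene_id", "chromosome", "order_index", "intron_count",
                     "segment_id")]

  seg_ids <- unique(stats::na.omit(genes$segment_id))
  segments <- do.call(rbind, lapply(seg_ids, function(s) {
    g <- genes[!is.na(genes$segment_id) & genes$segment_id == s, ]
    data.frame(segment_id = s, chromosome = g$chromosome[1],
               start_index = min(g$order_index), end_index = max(g$order_index),
               n_genes = nrow(g))
  }))
  if (is.null(segments))
    segments <- data.frame(segment_id = character(), chromosome = character(),
                           start_index = integer(), end_index = integer(),
                           n_genes = integer())

  pairs <- if (length(pair_rows) > 0) do.call(rbind, pair_rows) else
    data.frame(gene_a = character(), gene_b = character(),
               duplication_node = character())
  gene_truth <- do.call(rbind, truth_genes)
  gene_truth <- gene_truth[match(genes$gene_id, gene_truth$gene_id), ]
  rownames(gene_truth) <- NULL
  pair_truth <- if (length(truth_pairs) > 0) do.call(rbind, truth_pairs) else
    data.frame(gene_a = character(), gene_b = character(),
               duplication_node = character(), true_type = character(),
               family_id = character())

  fs <- config$feature_specs
  informative <- names(fs)[vapply(fs, function(s) any(s$shift != 0), logical(1))]
  age_only <- names(fs)[vapply(fs, function(s)
    all(s$shift == 0) && s$age_beta != 0, logical(1))]

  list(genes = genes, pairs = pairs, segments = segments,
       truth = list(gene_truth = gene_truth, pair_truth = pair_truth,
                    informative_features = informative,
                    age_only_features = age_only),
       config = config)
}

#' Simulate three replicate ohnolog pair sets
#'
#' Starting from the planted true ohnolog pair set, each replicate
#' independently drops every true ohnolog pair with probability
#' `dataset_noise` and adds every planted SSD pair with the same probability
#' (the three published ohnolog sets differ essentially only in WGD
#' membership, so noise perturbs only that axis). At noise 0 the three
#' replicates are identical to the truth.
#'
#' @param sim output of [simulate_genome] (or a list with `truth` and
#'   `config`).
#' @param n_replicates number of replicate sets (default 3).
#' @return List of `n_replicates` data frames (`gene_a`, `gene_b`).
#' @export
simulate_ohnolog_replicates <- function(sim, n_replicates = 3) {
  config <- sim$config
  noise <- config$dataset_noise
  pt <- sim$truth$pair_truth
  true_wgd <- pt[pt$true_type == "WGD", c("gene_a", "gene_b")]
  pool <- pt[pt$true_type == "SSD", c("gene_a", "gene_b")]

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(derive_seeds(config$seed, 2)[2])

  lapply(seq_len(n_replicates), function(k) {
    keep <- stats::runif(nrow(true_wgd)) >= noise
    add <- stats::runif(nrow(pool)) < noise
    out <- rbind(true_wgd[keep, , drop = FALSE], pool[add, , drop = FALSE])
    rownames(out) <- NULL
    out
  })
}

#' Simulate a per-gene feature table and expression matrix
#'
#' Draws every configured feature per gene from its class-conditional
#' distribution (location shifted by class and, for age-coupled features, by
#' the gene's standardized duplicate age times `age_beta *
#' age_confound_strength`), and generates a TPM expression matrix whose
#' breadth and level differ by class (ohnologs broad and high, SSD paralogs
#' narrow, singletons intermediate) from which tissue specificity and maximal
#' expression are later computed. Duplicate ages are taken from the planted
#' family structure (oldest node age divided by `age_unit`); singletons and
#' retro-excluded genes have missing age.
#'
#' @param sim output of [simulate_genome].
#' @return List with `features` (data frame: `gene_id`, `age`, one column per
#'   configured feature) and `expression` (genes x conditions TPM matrix).
#' @export
simulate_feature_table <- function(sim) {
  config <- sim$config
  gt <- sim$truth$gene_truth
  n <- nrow(gt)

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(derive_seeds(config$seed, 3)[3])

  # true ages from planted families (oldest node per family)
  pt <- sim$truth$pair_truth
  vert <- pt[pt$true_type %in% c("WGD", "SSD"), ]
  fam_age <- if (nrow(vert) > 0)
    tapply(config$node_age_table[vert$duplication_node], vert$family_id, max)
  else numeric(0)
  age <- unname(fam_age[gt$family_id] / config$age_unit)
  age[gt$true_class %in% c("SINGLETON", "RETRO_EXCLUDED")] <- NA

  age_c <- rep(0, n)
  has_age <- !is.na(age)
  if (sum(has_age) > 1 && stats::sd(age[has_age]) > 0)
    age_c[has_age] <- (age[has_age] - mean(age[has_age])) / stats::sd(age[has_age])

  cls <- ifelse(gt$true_class == "RETRO_EXCLUDED", "SINGLETON", gt$true_class)
  features <- data.frame(gene_id = gt$gene_id, age = age)
  for (nm in names(config$feature_specs)) {
    sp <- config$feature_specs[[nm]]
    loc <- sp$base + sp$shift[cls] * sp$sd +
      config$age_confound_strength * sp$age_beta * age_c * sp$sd
    val <- stats::rnorm(n, loc, sp$sd)
    if (sp$dist == "lnorm") val <- exp(val)
    features[[nm]] <- unname(val)
  }

  nt <- config$n_tissues
  expr <- matrix(0, nrow = n, ncol = nt,
                 dimnames = list(gt$gene_id, sprintf("tissue_%02d", seq_len(nt))))
  breadth <- config$expr_breadth[cls]
  lvl <- config$expr_level_log[cls]
  for (i in seq_len(n)) {
    k <- max(1L, stats::rbinom(1, nt, breadth[i]))
    on_t <- sample.int(nt, k)
    expr[i, on_t] <- exp(stats::rnorm(k, lvl[i], 0.6))
    off_t <- setdiff(seq_len(nt), on_t)
    expr[i, off_t] <- stats::runif(length(off_t), 0, 0.5)
  }

  list(features = features, expression = expr)
}
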