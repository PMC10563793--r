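# Builders and independent oracles shared across the test files.

# quick gene-table builder: one chromosome per element of `chroms`,
# order indices 0..(n-1); introns default 5, segments NA
toy_genes <- function(ids, chroms, order, introns = 5,
                      segments = NA_character_) {
  data.frame(gene_id = ids, chromosome = chroms, order_index = order,
             intron_count = introns, segment_id = segments,
             stringsAsFactors = FALSE)
}

toy_pairs <- function(a, b, node = "Vertebrata") {
  data.frame(gene_a = a, gene_b = b,
             duplication_node = rep_len(node, length(a)),
             stringsAsFactors = FALSE)
}

# Exhaustive synteny-block oracle: a pair is an ohnolog pair iff it belongs
# to some subset of >= min_block linking pairs between one segment pair whose
# consecutive anchor gaps (in each segment's own sorted order) are <= max_gap
# intervening genes. Enumerates all subsets by bitmask; independent of the
# clustering algorithm under test.
brute_force_ohnologs <- function(pairs, genes, min_block = 3, max_gap = 8) {
  seg_a <- genes$segment_id[match(pairs$gene_a, genes$gene_id)]
  seg_b <- genes$segment_id[match(pairs$gene_b, genes$gene_id)]
  pos_a <- genes$order_index[match(pairs$gene_a, genes$gene_id)]
  pos_b <- genes$order_index[match(pairs$gene_b, genes$gene_id)]
  linking <- which(!is.na(seg_a) & !is.na(seg_b) & seg_a != seg_b)

  hit <- logical(nrow(pairs))
  key <- function(i) paste(sort(c(seg_a[i], seg_b[i])), collapse = "|")
  for (k in unique(vapply(linking, key, character(1)))) {
    idx <- linking[vapply(linking, key, character(1)) == k]
    n <- length(idx)
    if (n < min_block) next
    stopifnot(n <= 14)  # keep enumeration tractable
    # orient: x on the lexicographically smaller segment
    first_seg <- sort(c(seg_a[idx[1]], seg_b[idx[1]]))[1]
    x <- ifelse(seg_a[idx] == first_seg, pos_a[idx], pos_b[idx])
    y <- ifelse(seg_a[idx] == first_seg, pos_b[idx], pos_a[idx])
    ok_subset <- function(members) {
      xs <- sort(x[members]); ys <- sort(y[members])
      all(diff(xs) <= max_gap + 1) && all(diff(ys) <= max_gap + 1)
    }
    for (mask in seq_len(2^n - 1)) {
      members <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
      if (length(members) >= min_block && ok_subset(members))
        hit[idx[members]] <- TRUE
    }
  }
  pairs[hit, , drop = FALSE]
}

# random small synteny instance for oracle-equivalence checks: <= 5 segments
# of <= 30 genes, pairs biased to form chains with mixed gap sizes
random_synteny_instance <- function(seed) {
  set.seed(seed)
  n_seg <- sample(2:5, 1)
  seg_len <- sample(5:30, n_seg, replace = TRUE)
  seg_chrom <- sample(sprintf("chr%d", 1:3), n_seg, replace = TRUE)

  genes <- list()
  counter <- 0
  for (ch in unique(seg_chrom)) {
    pos <- 0
    for (s in which(seg_chrom == ch)) {
      pos <- pos + sample(0:4, 1)  # filler before segment
      ids <- sprintf("g%03d", counter + seq_len(seg_len[s]))
      counter <- counter + seg_len[s]
      genes[[length(genes) + 1]] <-
        toy_genes(ids, ch, pos + seq_len(seg_len[s]) - 1,
                  segments = sprintf("S%d", s))
      pos <- pos + seg_len[s]
    }
  }
  genes <- do.call(rbind, genes)

  # chains of 2-5 pairs between one segment pair with gaps straddling the rule
  pairs <- list()
  n_chains <- sample(1:2, 1)
  for (cc in seq_len(n_chains)) {
    ss <- sample(n_seg, 2)
    ga <- genes[genes$segment_id == sprintf("S%d", ss[1]), ]
    gb <- genes[genes$segment_id == sprintf("S%d", ss[2]), ]
    k <- sample(2:5, 1)
    pa <- pb <- 1
    for (i in seq_len(k)) {
      if (pa > nrow(ga) || pb > nrow(gb)) break
      pairs[[length(pairs) + 1]] <-
        data.frame(gene_a = ga$gene_id[pa], gene_b = gb$gene_id[pb])
      pa <- pa + 1 + sample(0:12, 1)
      pb <- pb + 1 + sample(0:12, 1)
    }
  }
  # scattered extra pairs
  for (i in seq_len(sample(0:3, 1))) {
    gg <- sample(genes$gene_id, 2)
    pairs[[length(pairs) + 1]] <- data.frame(gene_a = gg[1], gene_b = gg[2])
  }
  pairs <- unique(do.call(rbind, pairs))
  pairs <- pairs[pairs$gene_a != pairs$gene_b, , drop = FALSE]
  list(genes = genes, pairs = pairs)
}

pair_keys <- function(df) {
  if (nrow(df) == 0) return(character(0))
  sort(paste(pmin(df$gene_a, df$gene_b), pmax(df$gene_a, df$gene_b)))
}

# literal evaluation of the tissue-specificity formula, independent of the
# package implementation
tau_oracle <- function(x) {
  xs <- x / max(x)
  total <- 0
  for (i in seq_along(xs)) total <- total + (1 - xs[i])
  total / (length(xs) - 1)
}

# duplicate-class truth with retro-excluded genes mapped to the consensus
# EXCLUDED label used by the classifier
truth_labels <- function(sim) {
  ifelse(sim$truth$gene_truth$true_class == "RETRO_EXCLUDED", "EXCLUDED",
         sim$truth$gene_truth$true_class)
}
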