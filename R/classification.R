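#' @title Duplicate-gene classification from paralog pairs and macrosynteny
#'
#' @description
#' Functions implementing the pair- and gene-level classification pipeline:
#' ohnolog-pair calling from 2R macrosynteny segments, retroduplication
#' filtering with a microsynteny check, per-gene labelling, and majority-rule
#' consensus across three ohnolog data sets.
#'
#' @details
#' The expected inputs are plain data frames. The gene table has columns
#' `gene_id`, `chromosome`, `order_index` (integer rank along the chromosome),
#' `intron_count` and optional `segment_id` (macrosynteny segment membership;
#' `NA` for genes outside any segment). The paralog-pair table has columns
#' `gene_a`, `gene_b`, `duplication_node`.
#'
#' @name classification
NULL

validate_gene_table <- function(genes) {
  check_columns(genes, c("gene_id", "chromosome", "order_index",
                         "intron_count"), "gene table")
  if (anyDuplicated(genes$gene_id))
    stop2("gene table contains duplicated gene_id values")
  bad <- stats::aggregate(order_index ~ chromosome, genes,
                          function(x) anyDuplicated(x) > 0)
  if (any(bad$order_index))
    stop2("order_index values are not unique within chromosome(s): ",
          paste(bad$chromosome[bad$order_index], collapse = ", "))
  invisible(genes)
}

check_pair_refs <- function(pairs, genes) {
  ids <- unique(c(pairs$gene_a, pairs$gene_b))
  missing <- setdiff(ids, genes$gene_id)
  if (length(missing) > 0)
    stop2("pair table references gene id(s) absent from the gene table: ",
          paste(missing, collapse = ", "))
  invisible(pairs)
}

#' Call ohnolog pairs from macrosynteny segments
#'
#' A paralog pair is called as a 2R ohnolog ("WGD") pair when it links two
#' distinct macrosynteny segments and belongs to a block of at least
#' `min_block` linking pairs in which consecutive anchors on each segment are
#' separated by at most `max_gap` intervening genes (genes strictly between
#' the two anchors, counted along the segment's own order).
#'
#' @details
#' Blocks are assembled by iterated one-dimensional splitting: the linking
#' pairs between one segment pair are repeatedly partitioned at anchor gaps
#' exceeding `max_gap` genes on either segment until stable. A stable cluster
#' is itself a chain satisfying the gap rule on both segments, and no chain
#' can span a hole larger than `max_gap` in the anchor set, so membership in a
#' stable cluster of size >= `min_block` is equivalent to membership in some
#' valid chain. Anchor order may be inverted between the two segments
#' (orientation is ignored). The result is independent of input row order.
#'
#' @param pairs data frame of paralog pairs (`gene_a`, `gene_b`).
#' @param genes gene table (see [classification]); `segment_id` must be
#'   present, `NA` for genes outside macrosynteny segments.
#' @param min_block minimum number of linking pairs per block (default 3).
#' @param max_gap maximum number of genes separating consecutive anchors on a
#'   segment (default 8).
#' @return The subset of `pairs` rows called as ohnolog pairs.
#' @export
call_ohnolog_pairs <- function(pairs, genes, min_block = 3, max_gap = 8) {
  validate_gene_table(genes)
  check_columns(genes, "segment_id", "gene table")
  check_columns(pairs, c("gene_a", "gene_b"), "pair table")
  check_pair_refs(pairs, genes)
  if (nrow(pairs) == 0) return(pairs[0, , drop = FALSE])

  seg <- genes$segment_id[match(pairs$gene_a, genes$gene_id)]
  seg_b <- genes$segment_id[match(pairs$gene_b, genes$gene_id)]
  pos <- genes$order_index[match(pairs$gene_a, genes$gene_id)]
  pos_b <- genes$order_index[match(pairs$gene_b, genes$gene_id)]

  linking <- !is.na(seg) & !is.na(seg_b) & seg != seg_b
  if (!any(linking)) return(pairs[0, , drop = FALSE])

  # orient each linking pair by the lexicographically smaller segment id so
  # that one segment consistently supplies x and the other y
  idx <- which(linking)
  sa <- seg[idx]; sb <- seg_b[idx]; xa <- pos[idx]; yb <- pos_b[idx]
  flip <- sa > sb
  tmp <- sa[flip]; sa[flip] <- sb[flip]; sb[flip] <- tmp
  tmp <- xa[flip]; xa[flip] <- yb[flip]; yb[flip] <- tmp

  keep <- logical(length(idx))
  for (key in unique(paste(sa, sb, sep = "\r"))) {
    members <- which(paste(sa, sb, sep = "\r") == key)
    keep[members[chain_cluster_ok(xa[members], yb[members],
                                  min_block, max_gap)]] <- TRUE
  }
  pairs[idx[keep], , drop = FALSE]
}

# Iterated gap-splitting on both coordinates; returns indices of points lying
# in a stable cluster of size >= min_block.
chain_cluster_ok <- function(x, y, min_block, max_gap) {
  clusters <- list(seq_along(x))
  repeat {
    new <- list()
    changed <- FALSE
    for (cl in clusters) {
      parts <- split_on_gaps(cl, x[cl], max_gap)
      parts <- unlist(lapply(parts, function(p) split_on_gaps(p, y[p], max_gap)),
                      recursive = FALSE)
      if (length(parts) > 1) changed <- TRUE
      new <- c(new, parts)
    }
    clusters <- new
    if (!changed) break
  }
  sizes <- lengths(clusters)
  unlist(clusters[sizes >= min_block], use.names = FALSE)
}

# split indices `idx` at positions where sorted coordinate gaps exceed
# max_gap intervening genes (difference > max_gap + 1)
split_on_gaps <- function(idx, coord, max_gap) {
  o <- order(coord)
  idx <- idx[o]; coord <- coord[o]
  if (length(idx) <= 1) return(list(idx))
  brk <- which(diff(coord) > max_gap + 1)
  unname(split(idx, cumsum(c(0, seq_along(idx)[-1] %in% (brk + 1)))))
}

#' Test a paralog pair for conserved microsynteny
#'
#' Returns `TRUE` when at least one *other* paralogous pair links the regions
#' surrounding the two tested genes: one member within `window` genes (either
#' side, same chromosome) of the first gene and its partner within `window`
#' genes of the second. The tested pair itself never counts; a gene near a
#' chromosome end simply has a truncated window.
#'
#' @param pair character vector of two gene ids.
#' @param pairs full paralog-pair table.
#' @param genes gene table.
#' @param window number of genes either side defining "surrounding" (default 5).
#' @return Logical scalar.
#' @export
check_microsynteny <- function(pair, pairs, genes, window = 5) {
  stopifnot(length(pair) == 2)
  validate_gene_table(genes)
  check_pair_refs(data.frame(gene_a = pair[1], gene_b = pair[2]), genes)
  ga <- genes[match(pair[1], genes$gene_id), ]
  gb <- genes[match(pair[2], genes$gene_id), ]

  others <- pairs[pair_key(pairs$gene_a, pairs$gene_b) !=
                    pair_key(pair[1], pair[2]), , drop = FALSE]
  if (nrow(others) == 0) return(FALSE)

  near <- function(ids, anchor) {
    chr <- genes$chromosome[match(ids, genes$gene_id)]
    oi <- genes$order_index[match(ids, genes$gene_id)]
    !is.na(chr) & chr == anchor$chromosome &
      abs(oi - anchor$order_index) <= window
  }
  any((near(others$gene_a, ga) & near(others$gene_b, gb)) |
      (near(others$gene_a, gb) & near(others$gene_b, ga)))
}

#' Detect retroduplication in a paralog pair
#'
#' A pair is flagged as retroduplicated when one member has zero introns and
#' the other has three or more, or when one member has zero introns, the
#' other fewer than three, *and* there is no conserved microsynteny between
#' the duplicates (see [check_microsynteny]). The zero/zero intron case falls
#' under the second clause. Intron gain is never inferred. The result is
#' symmetric in member order.
#'
#' @param pair character vector of two gene ids.
#' @param genes gene table with `intron_count`.
#' @param pairs full paralog-pair table (for the microsynteny check).
#' @param window microsynteny window (default 5).
#' @return Logical scalar.
#' @export
detect_retroduplication <- function(pair, genes, pairs, window = 5) {
  ic <- genes$intron_count[match(pair, genes$gene_id)]
  if (anyNA(ic))
    stop2("intron count missing for gene(s): ",
          paste(pair[is.na(ic)], collapse = ", "))
  lo <- min(ic); hi <- max(ic)
  if (lo > 0) return(FALSE)
  if (hi >= 3) return(TRUE)
  !check_microsynteny(pair, pairs, genes, window = window)
}

#' Label paralog pairs by duplication mechanism
#'
#' Assigns each pair exactly one label with precedence
#' `PRE_VERTEBRATE` (duplication node older than the vertebrate root) >
#' `WGD` (pair present in the supplied ohnolog set) > `RETRO`
#' ([detect_retroduplication], applied only to pairs not already labelled) >
#' `SSD`.
#'
#' @param pairs paralog-pair table with `duplication_node`.
#' @param ohnolog_pairs data frame (`gene_a`, `gene_b`) of called ohnolog
#'   pairs, e.g. from [call_ohnolog_pairs] or a published ohnolog list.
#' @param genes gene table.
#' @param node_ages named vector of node ages in MY; see [default_node_ages].
#' @param vertebrate_root node label marking the base of the vertebrate
#'   lineage (default `"Vertebrata"`); nodes strictly older are
#'   pre-vertebrate.
#' @param window microsynteny window for the retroduplication check.
#' @return `pairs` with an added `pair_label` factor column.
#' @export
label_pairs <- function(pairs, ohnolog_pairs, genes,
                        node_ages = default_node_ages(),
                        vertebrate_root = "Vertebrata", window = 5) {
  check_columns(pairs, c("gene_a", "gene_b", "duplication_node"), "pair table")
  check_pair_refs(pairs, genes)
  unknown <- setdiff(unique(pairs$duplication_node), names(node_ages))
  if (length(unknown) > 0)
    stop2("duplication node(s) not in the node-age table: ",
          paste(unknown, collapse = ", "))
  if (!vertebrate_root %in% names(node_ages))
    stop2("vertebrate_root '", vertebrate_root, "' not in the node-age table")

  root_age <- node_ages[[vertebrate_root]]
  ages <- node_ages[pairs$duplication_node]
  in_ohno <- pair_key(pairs$gene_a, pairs$gene_b) %in%
    pair_key(ohnolog_pairs$gene_a, ohnolog_pairs$gene_b)

  label <- rep("SSD", nrow(pairs))
  label[in_ohno] <- "WGD"
  label[ages > root_age] <- "PRE_VERTEBRATE"
  ssd_idx <- which(label == "SSD")
  for (i in ssd_idx) {
    if (detect_retroduplication(c(pairs$gene_a[i], pairs$gene_b[i]),
                                genes, pairs, window = window))
      label[i] <- "RETRO"
  }
  pairs$pair_label <- factor(label,
                             levels = c("WGD", "SSD", "RETRO", "PRE_VERTEBRATE"))
  pairs
}

#' Assign per-gene duplication labels from labelled pairs
#'
#' A gene is `WGD` when all of its vertebrate-lineage pairs are WGD pairs,
#' `SSD` when all are SSD pairs, and `SINGLETON` when it has no
#' vertebrate-lineage pairs (subtype `PRE_VERTEBRATE_ONLY` when it has only
#' pre-vertebrate pairs, else `NO_PARALOGS`). Genes in any retroduplicated
#' pair are `EXCLUDED` with reason `RETRO_PAIR`; genes with both WGD and SSD
#' pairs are `EXCLUDED` with reason `MIXED_TYPE`. Retro exclusion takes
#' precedence over mixed-type.
#'
#' @param labeled_pairs output of [label_pairs].
#' @param genes gene table; every gene receives exactly one label.
#' @return Data frame `gene_id`, `label`, `exclusion_reason`,
#'   `singleton_subtype`.
#' @export
assign_gene_labels <- function(labeled_pairs, genes) {
  check_columns(labeled_pairs, c("gene_a", "gene_b", "pair_label"),
                "labelled pair table")
  ids <- genes$gene_id
  long <- data.frame(
    gene_id = c(labeled_pairs$gene_a, labeled_pairs$gene_b),
    pair_label = c(as.character(labeled_pairs$pair_label),
                   as.character(labeled_pairs$pair_label))
  )
  has <- function(lab) ids %in% long$gene_id[long$pair_label == lab]
  has_wgd <- has("WGD"); has_ssd <- has("SSD")
  has_retro <- has("RETRO"); has_pre <- has("PRE_VERTEBRATE")

  label <- rep("SINGLETON", length(ids))
  reason <- rep(NA_character_, length(ids))
  subtype <- rep(NA_character_, length(ids))

  vert_any <- has_wgd | has_ssd | has_retro
  label[has_wgd & !has_ssd] <- "WGD"
  label[has_ssd & !has_wgd] <- "SSD"
  mixed <- has_wgd & has_ssd
  label[mixed] <- "EXCLUDED"; reason[mixed] <- "MIXED_TYPE"
  label[has_retro] <- "EXCLUDED"; reason[has_retro] <- "RETRO_PAIR"
  single <- !vert_any
  label[single] <- "SINGLETON"
  subtype[single] <- ifelse(has_pre[single], "PRE_VERTEBRATE_ONLY",
                            "NO_PARALOGS")
  subtype[!single] <- NA_character_

  data.frame(gene_id = ids, label = label, exclusion_reason = reason,
             singleton_subtype = subtype, stringsAsFactors = FALSE)
}

#' Majority-rule consensus across three ohnolog data sets
#'
#' The consensus label is any label held by at least two of the three
#' per-data-set assignments; where all three disagree the gene is `EXCLUDED`
#' with reason `NO_MAJORITY`. For a consensus `EXCLUDED` or `SINGLETON`
#' label, the reason/subtype is the most frequent among the agreeing data
#' sets.
#'
#' @param label_sets list of three data frames from [assign_gene_labels],
#'   covering the same gene universe.
#' @return Consensus data frame in the same shape, plus columns
#'   `label_1..label_3` with the per-data-set labels.
#' @export
majority_vote <- function(label_sets) {
  stopifnot(length(label_sets) == 3)
  ids <- label_sets[[1]]$gene_id
  for (k in 2:3) {
    if (!setequal(label_sets[[k]]$gene_id, ids))
      stop2("label set ", k, " does not cover the same gene universe")
    label_sets[[k]] <- label_sets[[k]][match(ids, label_sets[[k]]$gene_id), ]
  }
  labs <- cbind(label_sets[[1]]$label, label_sets[[2]]$label,
                label_sets[[3]]$label)
  reasons <- cbind(label_sets[[1]]$exclusion_reason,
                   label_sets[[2]]$exclusion_reason,
                   label_sets[[3]]$exclusion_reason)
  subtypes <- cbind(label_sets[[1]]$singleton_subtype,
                    label_sets[[2]]$singleton_subtype,
                    label_sets[[3]]$singleton_subtype)

  n <- length(ids)
  label <- character(n); reason <- rep(NA_character_, n)
  subtype <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    tab <- sort(table(labs[i, ]), decreasing = TRUE)
    if (tab[1] >= 2) {
      label[i] <- names(tab)[1]
      agree <- labs[i, ] == label[i]
      if (label[i] == "EXCLUDED") {
        rtab <- sort(table(reasons[i, agree]), decreasing = TRUE)
        reason[i] <- names(rtab)[1]
      } else if (label[i] == "SINGLETON") {
        stab <- sort(table(subtypes[i, agree]), decreasing = TRUE)
        subtype[i] <- names(stab)[1]
      }
    } else {
      label[i] <- "EXCLUDED"
      reason[i] <- "NO_MAJORITY"
    }
  }
  data.frame(gene_id = ids, label = label, exclusion_reason = reason,
             singleton_subtype = subtype,
             label_1 = labs[, 1], label_2 = labs[, 2], label_3 = labs[, 3],
             stringsAsFactors = FALSE)
}

#' Run the full three-data-set classification pipeline
#'
#' Labels all pairs against each supplied ohnolog set, assigns per-gene
#' labels per data set, and returns the majority-rule consensus together with
#' the per-data-set labelled pairs.
#'
#' @param genes gene table.
#' @param pairs paralog-pair table with `duplication_node`.
#' @param ohnolog_sets list of three ohnolog pair data frames.
#' @inheritParams label_pairs
#' @return List with `consensus` (see [majority_vote]), `gene_labels` (list
#'   of three per-data-set label frames) and `labeled_pairs` (list of three).
#' @export
classify_genes <- function(genes, pairs, ohnolog_sets,
                           node_ages = default_node_ages(),
                           vertebrate_root = "Vertebrata", window = 5) {
  stopifnot(length(ohnolog_sets) == 3)
  labeled <- lapply(ohnolog_sets, function(os)
    label_pairs(pairs, os, genes, node_ages = node_ages,
                vertebrate_root = vertebrate_root, window = window))
  gene_labels <- lapply(labeled, assign_gene_labels, genes = genes)
  list(consensus = majority_vote(gene_labels),
       gene_labels = gene_labels,
       labeled_pairs = labeled)
}

#' Summarise a classification run as per-data-set and consensus counts
#'
#' Produces the count structure of a duplicate-classification-by-data-set
#' table: per data set, the number of WGD pairs, the non-WGD remainder broken
#' down into retroduplicated, pre-vertebrate and presumed-SSD pairs (the
#' three partition the non-WGD pairs), and the per-class gene counts; plus
#' the final consensus gene counts.
#'
#' @param result output of [classify_genes].
#' @return List with data frames `pair_counts` (data set x pair category) and
#'   `gene_counts` (data set x gene class, plus a `consensus` column).
#' @export
classification_summary <- function(result) {
  pc <- do.call(rbind, lapply(seq_along(result$labeled_pairs), function(k) {
    lab <- result$labeled_pairs[[k]]$pair_label
    data.frame(
      data_set = k,
      wgd_pairs = sum(lab == "WGD"),
      non_wgd_pairs = sum(lab != "WGD"),
      retro_pairs = sum(lab == "RETRO"),
      prevertebrate_pairs = sum(lab == "PRE_VERTEBRATE"),
      presumed_ssd_pairs = sum(lab == "SSD")
    )
  }))
  classes <- c("WGD", "SSD", "SINGLETON", "EXCLUDED")
  gc <- do.call(rbind, lapply(seq_along(result$gene_labels), function(k) {
    lab <- result$gene_labels[[k]]$label
    out <- as.data.frame(as.list(vapply(classes, function(cl)
      sum(lab == cl), integer(1))))
    cbind(data.frame(data_set = k), out)
  }))
  cons <- vapply(classes, function(cl)
    sum(result$consensus$label == cl), integer(1))
  gc_cons <- cbind(data.frame(data_set = "consensus"),
                   as.data.frame(as.list(cons)))
  gc$data_set <- as.character(gc$data_set)
  list(pair_counts = pc, gene_counts = rbind(gc, gc_cons))
}
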