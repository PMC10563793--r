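#' Tissue-specificity index tau
#'
#' Computes tau = sum(1 - x_i) / (N - 1), where x_i is each condition's
#' expression scaled by the row maximum and N the number of conditions
#' (tissues and developmental stages treated alike). tau is 0 for a uniformly
#' expressed (housekeeping) gene and 1 for a gene expressed in a single
#' condition. Computed on raw TPM, no transformation.
#'
#' @param x numeric vector of expression values (>= 0) for one gene, or a
#'   genes x conditions matrix (one tau per row).
#' @return Numeric tau in \[0, 1\]; `NA` (with a warning) for an all-zero row.
#' @export
tissue_specificity <- function(x) {
  if (is.matrix(x) || is.data.frame(x)) {
    x <- as.matrix(x)
    return(vapply(seq_len(nrow(x)), function(i) tau_one(x[i, ]), numeric(1)))
  }
  tau_one(x)
}

tau_one <- function(x) {
  if (length(x) < 2)
    stop2("tau requires at least two conditions")
  if (any(x < 0)) stop2("expression values must be non-negative")
  m <- max(x)
  if (m == 0) {
    warning("all-zero expression row: tau undefined", call. = FALSE)
    return(NA_real_)
  }
  sum(1 - x / m) / (length(x) - 1)
}

#' Assign duplicate age per gene from its vertebrate gene family
#'
#' The age of a gene is the age of the oldest duplication node within its
#' vertebrate gene family, where family membership is the transitive closure
#' over vertebrate-lineage paralog pairs (pairs whose duplication node is at
#' or younger than the vertebrate root). The age is expressed in units of
#' `age_unit` MY (default 50) and is identical for all members of a family.
#' WGD genes take their ages by the same method as SSD genes. Genes with no
#' vertebrate-lineage pairs get `NA` by default (or 0 with
#' `singleton_age = 0`) so they never leak into age regressions.
#'
#' @param genes gene table (or any data frame with `gene_id`).
#' @param pairs paralog-pair table with `duplication_node`.
#' @param node_ages named node-age vector in MY.
#' @param vertebrate_root root node of the vertebrate lineage.
#' @param age_unit MY per age unit.
#' @param singleton_age value for genes without vertebrate-lineage pairs
#'   (default `NA`).
#' @return Named numeric vector of ages, one per gene in `genes`.
#' @export
assign_duplicate_age <- function(genes, pairs,
                                 node_ages = default_node_ages(),
                                 vertebrate_root = "Vertebrata",
                                 age_unit = 50, singleton_age = NA_real_) {
  check_columns(pairs, c("gene_a", "gene_b", "duplication_node"), "pair table")
  unknown <- setdiff(unique(pairs$duplication_node), names(node_ages))
  if (length(unknown) > 0)
    stop2("duplication node(s) not in the node-age table: ",
          paste(unknown, collapse = ", "))
  root_age <- node_ages[[vertebrate_root]]
  vert <- pairs[node_ages[pairs$duplication_node] <= root_age, , drop = FALSE]

  ages <- stats::setNames(rep(singleton_age, nrow(genes)), genes$gene_id)
  if (nrow(vert) == 0) return(ages)

  g <- igraph::graph_from_data_frame(vert[, c("gene_a", "gene_b")],
                                     directed = FALSE)
  comp <- igraph::components(g)$membership
  pair_age <- node_ages[vert$duplication_node]
  fam_of_pair <- comp[vert$gene_a]
  fam_age <- tapply(pair_age, fam_of_pair, max) / age_unit
  in_fam <- names(comp)[names(comp) %in% names(ages)]
  ages[in_fam] <- fam_age[as.character(comp[in_fam])]
  ages
}

#' Per-tissue expression summary by duplicate class
#'
#' For each condition, restricts to genes expressed at or above
#' `threshold_tpm` and reports the per-class median, plus an indicator of
#' whether the WGD median exceeds the SSD median in that condition.
#'
#' @param expression genes x conditions TPM matrix with gene-id rownames.
#' @param labels data frame with `gene_id` and `label` (consensus labels).
#' @param threshold_tpm expression floor in TPM (default 1; 0 disables the
#'   filter).
#' @param classes classes to summarise.
#' @return Data frame: `tissue`, one median column per class, `n_<class>`
#'   expressed-gene counts, and `wgd_gt_ssd`.
#' @export
per_tissue_expression_summary <- function(expression, labels,
                                          threshold_tpm = 1,
                                          classes = c("WGD", "SSD",
                                                      "SINGLETON")) {
  check_columns(labels, c("gene_id", "label"), "label table")
  lab <- labels$label[match(rownames(expression), labels$gene_id)]
  out <- list()
  for (j in seq_len(ncol(expression))) {
    row <- list(tissue = colnames(expression)[j])
    for (cl in classes) {
      v <- expression[!is.na(lab) & lab == cl, j]
      v <- v[v >= threshold_tpm]
      if (length(v) == 0)
        warning("no ", cl, " gene expressed in ", colnames(expression)[j],
                call. = FALSE)
      row[[paste0("median_", cl)]] <-
        if (length(v) > 0) stats::median(v) else NA_real_
      row[[paste0("n_", cl)]] <- length(v)
    }
    if (all(c("WGD", "SSD") %in% classes))
      row$wgd_gt_ssd <- isTRUE(row$median_WGD > row$median_SSD)
    out[[j]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' GC content at third codon positions
#'
#' Percentage of G or C bases among third-codon-position bases of a CDS. A
#' trailing partial codon is dropped with a warning; `N` at a third position
#' is excluded from both numerator and denominator.
#'
#' @param cds character vector of CDS sequences over A/C/G/T/N (case
#'   insensitive).
#' @return Numeric vector of percentages; `NA` when no informative third
#'   position remains.
#' @export
gc3_content <- function(cds) {
  vapply(cds, function(s) {
    if (is.na(s) || nchar(s) == 0) stop2("empty CDS sequence")
    s <- toupper(s)
    if (grepl("[^ACGTN]", s)) stop2("CDS contains characters outside ACGTN")
    n <- nchar(s)
    if (n %% 3 != 0) {
      warning("CDS length not a multiple of 3; trailing partial codon dropped",
              call. = FALSE)
      n <- n - n %% 3
    }
    if (n < 3) stop2("CDS shorter than one codon")
    third <- strsplit(s, "")[[1]][seq(3, n, by = 3)]
    third <- third[third != "N"]
    if (length(third) == 0) return(NA_real_)
    100 * mean(third %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Keep one row per gene: the longest transcript
#'
#' Where a feature differs between transcripts of a gene, the convention is
#' to use the value for the longest transcript. Ties are broken by the
#' lexicographically smallest transcript id, so the result is deterministic.
#'
#' @param transcripts data frame with `gene_id`, `transcript_id`,
#'   `transcript_length` and any feature columns.
#' @return One row per gene.
#' @export
select_longest_transcript <- function(transcripts) {
  check_columns(transcripts,
                c("gene_id", "transcript_id", "transcript_length"),
                "transcript table")
  o <- order(transcripts$gene_id, -transcripts$transcript_length,
             transcripts$transcript_id)
  t2 <- transcripts[o, , drop = FALSE]
  out <- t2[!duplicated(t2$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
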