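#' Term enrichment and depletion for a duplicate class
#'
#' Tests every annotation term for enrichment or depletion of a class gene
#' set against the total gene universe with a two-sided hypergeometric test
#' (doubled smaller tail, capped at 1), then controls the false discovery
#' rate across terms within the class with Benjamini-Hochberg. Direction is
#' `enriched` when the observed overlap exceeds its expectation and
#' `depleted` otherwise. This in-house test stands in for external enrichment
#' services; ontology structure is not modelled, annotations are flat sets.
#'
#' @param class_genes character vector of gene ids in the class.
#' @param annotations data frame with `term_id` and `gene_id` (one row per
#'   annotation), or a named list of gene-id vectors.
#' @param universe character vector of all gene ids (the background).
#' @param alpha FDR threshold for the `significant` flag (default 0.05).
#' @return Data frame: `term`, `class_size`, `term_size`, `observed`,
#'   `expected`, `direction`, `p`, `q`, `significant`.
#' @export
term_enrichment <- function(class_genes, annotations, universe,
                            alpha = 0.05) {
  if (length(class_genes) == 0) stop2("class gene set is empty")
  if (!all(class_genes %in% universe))
    stop2("class gene set is not a subset of the universe")
  if (is.data.frame(annotations)) {
    check_columns(annotations, c("term_id", "gene_id"), "annotation table")
    term_sets <- split(annotations$gene_id, annotations$term_id)
  } else {
    term_sets <- annotations
  }
  term_sets <- lapply(term_sets, function(g) unique(g[g %in% universe]))
  term_sets <- term_sets[lengths(term_sets) > 0]

  N <- length(unique(universe))
  k <- length(unique(class_genes))
  rows <- lapply(names(term_sets), function(t) {
    genes_t <- term_sets[[t]]
    m <- length(genes_t)
    x <- sum(class_genes %in% genes_t)
    expected <- k * m / N
    p <- hypergeom_two_sided(x, m, N, k)
    data.frame(term = t, class_size = k, term_size = m, observed = x,
               expected = expected,
               direction = if (x > expected) "enriched" else "depleted",
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q < alpha
  rownames(out) <- NULL
  out
}

# two-sided hypergeometric p as the doubled smaller tail, capped at 1
hypergeom_two_sided <- function(x, m, N, k) {
  lower <- stats::phyper(x, m, N - m, k)
  upper <- stats::phyper(x - 1, m, N - m, k, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

#' Cross-class overlap of significant enrichment/depletion terms
#'
#' For every ordered pair of classes (A, B) reports the fraction of A's
#' significant terms that are also significant in B with the same direction
#' (concordant) and with the opposite direction (opposed); the denominator is
#' always the source class's significant-term count, so the fractions are
#' asymmetric. Also returns UpSet-style intersection sizes over the
#' significant term sets, both counting terms irrespective of direction and
#' counting term-direction pairs.
#'
#' @param records named list of per-class enrichment tables from
#'   [term_enrichment].
#' @return List with `fractions` (data frame: `from`, `to`, `n_from`,
#'   `concordant`, `opposed`), `intersections_terms` and
#'   `intersections_directional` (data frames: `classes`, `size`, counting
#'   exclusive intersections), and `n_significant` per class.
#' @export
overlap_summary <- function(records) {
  stopifnot(!is.null(names(records)), all(nzchar(names(records))))
  sig <- lapply(records, function(r) r[r$significant, c("term", "direction")])
  classes <- names(records)

  fractions <- list()
  for (a in classes) for (b in setdiff(classes, a)) {
    sa <- sig[[a]]; sb <- sig[[b]]
    n_from <- nrow(sa)
    if (n_from == 0) {
      conc <- 0; opp <- 0
    } else {
      dir_b <- sb$direction[match(sa$term, sb$term)]
      conc <- sum(!is.na(dir_b) & dir_b == sa$direction) / n_from
      opp <- sum(!is.na(dir_b) & dir_b != sa$direction) / n_from
    }
    fractions[[length(fractions) + 1L]] <-
      data.frame(from = a, to = b, n_from = n_from,
                 concordant = conc, opposed = opp, stringsAsFactors = FALSE)
  }
  fractions <- do.call(rbind, fractions)

  exclusive_intersections <- function(sets) {
    all_items <- unique(unlist(sets))
    if (length(all_items) == 0)
      return(data.frame(classes = character(), size = integer()))
    member <- vapply(sets, function(s) all_items %in% s,
                     logical(length(all_items)))
    if (is.null(dim(member))) member <- matrix(member, nrow = 1)
    key <- apply(member, 1, function(r) paste(classes[r], collapse = "+"))
    tab <- table(key)
    data.frame(classes = names(tab), size = as.integer(tab),
               stringsAsFactors = FALSE)
  }
  by_term <- lapply(sig, function(s) unique(s$term))
  by_dir <- lapply(sig, function(s) paste(s$term, s$direction, sep = ":"))

  list(fractions = fractions,
       intersections_terms = exclusive_intersections(by_term),
       intersections_directional = exclusive_intersections(by_dir),
       n_significant = vapply(sig, nrow, integer(1)))
}

#' Simulate a flat annotation map for enrichment testing
#'
#' Assigns genes to terms at random (each term draws a random gene set of
#' the requested size from the universe), giving a null annotation map for
#' calibration checks.
#'
#' @param universe gene ids.
#' @param n_terms number of terms.
#' @param term_size number of genes per term (scalar or vector recycled).
#' @param seed integer seed.
#' @return Data frame `term_id`, `gene_id`.
#' @export
simulate_annotations <- function(universe, n_terms = 50, term_size = 100,
                                 seed = 1L) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  term_size <- rep_len(term_size, n_terms)
  do.call(rbind, lapply(seq_len(n_terms), function(i) {
    data.frame(term_id = sprintf("term%03d", i),
               gene_id = sample(universe, min(term_size[i], length(universe))),
               stringsAsFactors = FALSE)
  }))
}
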