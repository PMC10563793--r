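#' Configuration for the duplicate-type classifier protocol
#'
#' Defaults follow the study protocol: 100 iterations of a fresh random
#' 80/20 train/test split, a random forest with balanced class weights and
#' 39 trees (the tuned value; 100 pre-tuning), permutation importance
#' computed on the held-out set with one permutation round per feature per
#' iteration, and a randomized hyperparameter search with 10-fold
#' cross-validation maximizing F1.
#'
#' @param n_iterations number of protocol iterations.
#' @param test_fraction held-out fraction per iteration.
#' @param n_trees number of trees.
#' @param mtry,max_depth,min_node,replace optional forest hyperparameters
#'   (ranger's `mtry`, `max.depth`, `min.node.size`, `replace`); `NULL` keeps
#'   ranger defaults.
#' @param n_permutations permutation rounds per feature per iteration.
#' @param cv_folds folds for hyperparameter tuning.
#' @param n_search candidate draws in the randomized search.
#' @param seed master seed; per-iteration seeds are derived from it.
#' @return List of class `classifier_config`.
#' @export
classifier_config <- function(n_iterations = 100, test_fraction = 0.2,
                              n_trees = 39, mtry = NULL, max_depth = NULL,
                              min_node = NULL, replace = TRUE,
                              n_permutations = 1, cv_folds = 10,
                              n_search = 20, seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stop2("test_fraction must be in (0, 1)")
  if (n_iterations < 1) stop2("n_iterations must be >= 1")
  structure(list(n_iterations = n_iterations, test_fraction = test_fraction,
                 n_trees = n_trees, mtry = mtry, max_depth = max_depth,
                 min_node = min_node, replace = replace,
                 n_permutations = n_permutations, cv_folds = cv_folds,
                 n_search = n_search, seed = as.integer(seed)),
            class = "classifier_config")
}

balanced_class_weights <- function(y) {
  tab <- table(y)
  w <- length(y) / (length(tab) * tab)
  stats::setNames(as.numeric(w), names(tab))
}

fit_class_forest <- function(x, y, config, seed) {
  ranger::ranger(
    x = x, y = y, num.trees = config$n_trees,
    mtry = config$mtry, max.depth = config$max_depth,
    min.node.size = config$min_node, replace = config$replace,
    class.weights = balanced_class_weights(y),
    seed = seed, num.threads = 1
  )
}

check_complete <- function(features, gene_ids = NULL) {
  bad <- !stats::complete.cases(features)
  if (any(bad)) {
    who <- if (!is.null(gene_ids)) gene_ids[bad] else which(bad)
    stop2("features contain missing values for: ",
          paste(utils::head(who, 10), collapse = ", "),
          if (sum(bad) > 10) sprintf(" (and %d more)", sum(bad) - 10) else "")
  }
  invisible(features)
}

prep_feature_frame <- function(features) {
  drop <- intersect(c("gene_id", "age"), names(features))
  ids <- if ("gene_id" %in% names(features)) features$gene_id else NULL
  x <- features[, setdiff(names(features), drop), drop = FALSE]
  if (!all(vapply(x, is.numeric, logical(1))))
    stop2("all feature columns must be numeric")
  list(x = as.data.frame(x), ids = ids)
}

#' Run the repeated train/test permutation-importance protocol
#'
#' Per iteration: a fresh simple-random train/test split, a balanced-weight
#' random-forest fit on the training set, held-out accuracy, and for each
#' feature the drop in held-out accuracy caused by randomly permuting that
#' feature relative to the unpermuted base accuracy. Importances, ranks and
#' confusion counts are aggregated across iterations; the whole protocol is
#' deterministic given the config seed.
#'
#' @param features data frame of numeric features (a `gene_id` column, if
#'   present, is used only for error reporting; an `age` column is dropped).
#'   Must be complete-case.
#' @param labels two-class factor or character vector aligned with
#'   `features`.
#' @param config a [classifier_config].
#' @param mode label recorded in the report (`"raw"` or `"age_controlled"`).
#' @return Object of class `importance_report`: list with `importance` (data
#'   frame: feature, mean/sd importance, mean rank), `accuracy` (mean, sd and
#'   normal-approximation 95% CI over iterations), `accuracies`, `confusion`
#'   (summed counts, true classes in rows), `confusion_precision`
#'   (column-normalized), `confusion_recall` (row-normalized), `mode` and
#'   `n`.
#' @export
run_protocol <- function(features, labels, config = classifier_config(),
                         mode = "raw") {
  pf <- prep_feature_frame(features)
  x <- pf$x
  check_complete(x, pf$ids)
  y <- factor(labels)
  if (nlevels(y) != 2) stop2("labels must contain exactly two classes")
  if (length(y) != nrow(x)) stop2("labels and features are misaligned")

  n <- nrow(x)
  p <- ncol(x)
  n_test <- max(1L, round(n * config$test_fraction))
  seeds <- derive_seeds(config$seed, config$n_iterations)

  imp <- matrix(NA_real_, config$n_iterations, p,
                dimnames = list(NULL, names(x)))
  acc <- numeric(config$n_iterations)
  conf <- matrix(0, 2, 2, dimnames = list(true = levels(y),
                                          predicted = levels(y)))

  for (it in seq_len(config$n_iterations)) {
    set.seed(seeds[it])
    test_idx <- sample.int(n, n_test)
    tr <- setdiff(seq_len(n), test_idx)
    if (nlevels(droplevels(y[tr])) < 2) next  # degenerate split, keep NA
    fit <- fit_class_forest(x[tr, , drop = FALSE], y[tr], config, seeds[it])
    x_test <- x[test_idx, , drop = FALSE]
    y_test <- y[test_idx]
    pred <- stats::predict(fit, data = x_test, num.threads = 1)$predictions
    base_acc <- mean(pred == y_test)
    acc[it] <- base_acc
    conf <- conf + table(factor(y_test, levels(y)), factor(pred, levels(y)))

    for (j in seq_len(p)) {
      drops <- numeric(config$n_permutations)
      for (r in seq_len(config$n_permutations)) {
        xp <- x_test
        xp[[j]] <- xp[[j]][sample.int(n_test)]
        pp <- stats::predict(fit, data = xp, num.threads = 1)$predictions
        drops[r] <- base_acc - mean(pp == y_test)
      }
      imp[it, j] <- mean(drops)
    }
  }

  ok <- !is.na(acc) & apply(imp, 1, function(r) !anyNA(r))
  imp <- imp[ok, , drop = FALSE]
  acc <- acc[ok]
  ranks <- t(apply(-imp, 1, rank, ties.method = "average"))
  if (p == 1) ranks <- matrix(1, nrow(imp), 1)

  importance <- data.frame(
    feature = names(x),
    mean_importance = colMeans(imp),
    sd_importance = apply(imp, 2, stats::sd),
    mean_rank = colMeans(ranks),
    row.names = NULL
  )
  importance <- importance[order(-importance$mean_importance), ]
  rownames(importance) <- NULL

  m <- length(acc)
  se <- stats::sd(acc) / sqrt(m)
  accuracy <- c(mean = mean(acc), sd = stats::sd(acc),
                ci_lower = mean(acc) - 1.96 * se,
                ci_upper = mean(acc) + 1.96 * se)

  structure(list(importance = importance, accuracy = accuracy,
                 accuracies = acc, confusion = conf,
                 confusion_precision = sweep(conf, 2, pmax(colSums(conf), 1),
                                             "/"),
                 confusion_recall = sweep(conf, 1, pmax(rowSums(conf), 1),
                                          "/"),
                 mode = mode, n = n, n_test = n_test,
                 feature_names = names(x), config = config),
            class = "importance_report")
}

#' @export
print.importance_report <- function(x, ...) {
  cat(sprintf(
    "Duplicate-type importance protocol (%s), %d genes, %d iterations\n",
    x$mode, x$n, length(x$accuracies)))
  cat(sprintf("  accuracy %.4f (95%% CI %.4f-%.4f)\n",
              x$accuracy["mean"], x$accuracy["ci_lower"],
              x$accuracy["ci_upper"]))
  print(utils::head(x$importance, 10), row.names = FALSE)
  invisible(x)
}

#' Age-controlled variant of the importance protocol
#'
#' Residualizes every feature on duplicate age ([residualize_on_age]) over
#' the supplied gene set and runs the identical protocol on the residuals.
#'
#' @inheritParams run_protocol
#' @param ages duplicate ages aligned with `features`, no missing values.
#' @return An `importance_report` with mode `"age_controlled"`.
#' @export
run_age_controlled_protocol <- function(features, ages, labels,
                                        config = classifier_config()) {
  pf <- prep_feature_frame(features)
  check_complete(pf$x, pf$ids)
  resid <- residualize_on_age(pf$x, ages)
  run_protocol(resid, labels, config, mode = "age_controlled")
}

macro_f1 <- function(true, pred) {
  lev <- levels(true)
  f1 <- vapply(lev, function(cl) {
    tp <- sum(pred == cl & true == cl)
    prec <- if (sum(pred == cl) > 0) tp / sum(pred == cl) else 0
    rec <- if (sum(true == cl) > 0) tp / sum(true == cl) else 0
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, numeric(1))
  mean(f1)
}

#' Randomized hyperparameter search with cross-validated F1
#'
#' Draws `n_search` candidate configurations from the grid (number of trees,
#' mtry, maximum depth, minimum node size, bootstrap on/off), scores each by
#' macro-F1 under `cv_folds`-fold cross-validation, and returns the config
#' updated with the F1-maximizing candidate. Deterministic given the config
#' seed.
#'
#' @inheritParams run_protocol
#' @param grid named list of candidate values; defaults cover a common
#'   forest grid.
#' @return List with `config` (tuned [classifier_config]), `best_f1` and the
#'   scored `candidates` data frame.
#' @export
tune_hyperparameters <- function(features, labels,
                                 config = classifier_config(),
                                 grid = NULL) {
  pf <- prep_feature_frame(features)
  x <- pf$x
  check_complete(x, pf$ids)
  y <- factor(labels)
  if (nlevels(y) < 2) stop2("labels must contain two classes")
  if (length(y) < config$cv_folds * 2)
    stop2("need at least cv_folds * 2 samples")

  p <- ncol(x)
  if (is.null(grid))
    grid <- list(n_trees = c(25, 39, 50, 100, 200),
                 mtry = unique(pmax(1, round(c(sqrt(p), p / 3, p / 2, p)))),
                 max_depth = c(0, 5, 10, 20),
                 min_node = c(1, 5, 10),
                 replace = c(TRUE, FALSE))

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)

  total <- prod(lengths(grid))
  n_cand <- min(config$n_search, total)
  draw <- function() lapply(grid, function(v) v[sample.int(length(v), 1)])
  cands <- list()
  seen <- character(0)
  while (length(cands) < n_cand) {
    cd <- draw()
    key <- paste(unlist(cd), collapse = "|")
    if (!key %in% seen) {
      seen <- c(seen, key)
      cands[[length(cands) + 1L]] <- cd
    }
  }

  folds <- sample(rep_len(seq_len(config$cv_folds), nrow(x)))
  score_one <- function(cd, cand_seed) {
    cfg <- config
    cfg$n_trees <- cd$n_trees
    cfg$mtry <- cd$mtry
    cfg$max_depth <- if (cd$max_depth == 0) NULL else cd$max_depth
    cfg$min_node <- cd$min_node
    cfg$replace <- cd$replace
    f1s <- vapply(seq_len(config$cv_folds), function(k) {
      tr <- folds != k
      if (nlevels(droplevels(y[tr])) < 2 || !any(!tr)) return(NA_real_)
      fit <- fit_class_forest(x[tr, , drop = FALSE], y[tr], cfg, cand_seed + k)
      pred <- stats::predict(fit, data = x[!tr, , drop = FALSE],
                             num.threads = 1)$predictions
      macro_f1(y[!tr], factor(pred, levels(y)))
    }, numeric(1))
    mean(f1s, na.rm = TRUE)
  }
  cand_seeds <- sample.int(.Machine$integer.max - config$cv_folds, n_cand)
  f1 <- vapply(seq_len(n_cand), function(i) score_one(cands[[i]],
                                                      cand_seeds[i]),
               numeric(1))

  best <- cands[[which.max(f1)]]
  tuned <- config
  tuned$n_trees <- best$n_trees
  tuned$mtry <- best$mtry
  tuned$max_depth <- if (best$max_depth == 0) NULL else best$max_depth
  tuned$min_node <- best$min_node
  tuned$replace <- best$replace

  cand_df <- cbind(do.call(rbind, lapply(cands, as.data.frame)), f1 = f1)
  list(config = tuned, best_f1 = max(f1), candidates = cand_df)
}

#' Feature-dependence matrix
#'
#' For every feature, fits a random-forest regression with that feature as
#' the target and all other features as predictors, and reports the held-out
#' R-squared ("dependence": how well the feature can be predicted from the
#' others) together with each predictor's permutation importance (held-out
#' R-squared drop). All reported values are clipped to \[0, 1\].
#'
#' @inheritParams run_protocol
#' @return Object of class `dependence_matrix`: list with `dependence`
#'   (named vector of R-squared) and `importances` (target x predictor
#'   matrix, diagonal `NA`).
#' @export
dependence_matrix <- function(features, config = classifier_config()) {
  pf <- prep_feature_frame(features)
  x <- pf$x
  check_complete(x, pf$ids)
  p <- ncol(x)
  if (p < 3) stop2("dependence matrix needs at least 3 features")
  n <- nrow(x)
  n_test <- max(2L, round(n * config$test_fraction))
  seeds <- derive_seeds(config$seed, p)

  dep <- stats::setNames(numeric(p), names(x))
  imps <- matrix(NA_real_, p, p, dimnames = list(target = names(x),
                                                 predictor = names(x)))
  r2 <- function(obs, pred) {
    sst <- sum((obs - mean(obs))^2)
    if (sst == 0) return(0)
    1 - sum((obs - pred)^2) / sst
  }
  for (j in seq_len(p)) {
    set.seed(seeds[j])
    test_idx <- sample.int(n, n_test)
    tr <- setdiff(seq_len(n), test_idx)
    xx <- x[, -j, drop = FALSE]
    fit <- ranger::ranger(x = xx[tr, , drop = FALSE], y = x[[j]][tr],
                          num.trees = max(config$n_trees, 100),
                          seed = seeds[j], num.threads = 1)
    obs <- x[[j]][test_idx]
    base <- r2(obs, stats::predict(fit, data = xx[test_idx, , drop = FALSE],
                                   num.threads = 1)$predictions)
    dep[j] <- min(max(base, 0), 1)
    for (k in seq_len(p - 1)) {
      xp <- xx[test_idx, , drop = FALSE]
      xp[[k]] <- xp[[k]][sample.int(n_test)]
      rp <- r2(obs, stats::predict(fit, data = xp,
                                   num.threads = 1)$predictions)
      imps[j, names(xx)[k]] <- min(max(base - rp, 0), 1)
    }
  }
  structure(list(dependence = dep, importances = imps),
            class = "dependence_matrix")
}

#' @export
print.dependence_matrix <- function(x, ...) {
  cat("Feature-dependence matrix (held-out R^2 per feature):\n")
  print(round(sort(x$dependence, decreasing = TRUE), 3))
  invisible(x)
}

#' Correlated-feature isolation re-ranking
#'
#' For each feature in each supplied group of correlated features, reruns the
#' full protocol with all *other* group members dropped, giving an importance
#' estimate free of compensation from correlated features. Reports each
#' feature's previous rank (position in the baseline ranked mean-importance
#' list), its new rank (insertion position of the isolated mean importance
#' into that list), and the baseline vs isolated mean accuracy.
#'
#' @inheritParams run_protocol
#' @param groups named list of disjoint character vectors of feature names.
#' @param baseline optional precomputed baseline `importance_report` (from
#'   [run_protocol] on the full feature set with the same config).
#' @return Data frame: `group`, `feature`, `previous_rank`, `new_rank`,
#'   `previous_importance`, `new_importance`, `previous_accuracy`,
#'   `new_accuracy`.
#' @export
isolation_analysis <- function(features, labels, config = classifier_config(),
                               groups, baseline = NULL) {
  if (anyDuplicated(unlist(groups)))
    stop2("isolation groups must be disjoint")
  pf <- prep_feature_frame(features)
  unknown <- setdiff(unlist(groups), names(pf$x))
  if (length(unknown) > 0)
    stop2("group feature(s) not in the feature table: ",
          paste(unknown, collapse = ", "))
  if (is.null(baseline))
    baseline <- run_protocol(features, labels, config)
  base_imp <- stats::setNames(baseline$importance$mean_importance,
                              baseline$importance$feature)
  base_rank <- stats::setNames(rank(-base_imp, ties.method = "first"),
                               names(base_imp))

  rows <- list()
  for (gname in names(groups)) {
    grp <- groups[[gname]]
    for (f in grp) {
      dropped <- setdiff(grp, f)
      keep <- setdiff(names(pf$x), dropped)
      rep_f <- run_protocol(pf$x[, keep, drop = FALSE], labels, config)
      new_imp <- rep_f$importance$mean_importance[
        rep_f$importance$feature == f]
      new_rank <- 1 + sum(base_imp[setdiff(names(base_imp), f)] > new_imp)
      rows[[length(rows) + 1L]] <- data.frame(
        group = gname, feature = f,
        previous_rank = unname(base_rank[f]), new_rank = new_rank,
        previous_importance = unname(base_imp[f]), new_importance = new_imp,
        previous_accuracy = unname(baseline$accuracy["mean"]),
        new_accuracy = unname(rep_f$accuracy["mean"]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
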