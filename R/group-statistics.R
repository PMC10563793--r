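#' Jarque-Bera normality statistic
#'
#' JB = n/6 * (S^2 + (K - 3)^2 / 4), with skewness S and kurtosis K computed
#' from maximum-likelihood central moments. Used to choose among candidate
#' transformations in [fit_feature_age_model]; larger values mean larger
#' deviation from normality.
#'
#' @param x numeric vector.
#' @return The JB statistic (numeric scalar).
#' @export
jarque_bera <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 4) stop2("Jarque-Bera requires at least 4 observations")
  m <- x - mean(x)
  m2 <- mean(m^2)
  if (m2 == 0) return(0)
  s <- mean(m^3) / m2^1.5
  k <- mean(m^4) / m2^2
  n / 6 * (s^2 + (k - 3)^2 / 4)
}

#' Pairwise Mann-Whitney comparisons of features between duplicate classes
#'
#' For each feature, runs two-tailed Mann-Whitney U tests for every pair of
#' classes (by default WGD-SSD, WGD-singleton, SSD-singleton) and
#' Bonferroni-corrects the p-values over all tests performed in the call.
#'
#' @param features data frame with `gene_id` and feature columns.
#' @param labels data frame with `gene_id` and `label`.
#' @param feature_names features to test (default: all numeric columns except
#'   `gene_id`/`age`).
#' @param classes classes to compare pairwise.
#' @return Data frame: `feature`, `class_a`, `class_b`, `statistic`, `p`,
#'   `p_adjusted`, `median_a`, `median_b`, `direction` (class with the higher
#'   median, or `"equal"`).
#' @export
pairwise_feature_tests <- function(features, labels, feature_names = NULL,
                                   classes = c("WGD", "SSD", "SINGLETON")) {
  check_columns(features, "gene_id", "feature table")
  check_columns(labels, c("gene_id", "label"), "label table")
  if (is.null(feature_names))
    feature_names <- setdiff(names(features)[vapply(features, is.numeric,
                                                    logical(1))], "age")
  lab <- labels$label[match(features$gene_id, labels$gene_id)]
  for (cl in classes)
    if (sum(lab == cl, na.rm = TRUE) < 2)
      stop2("class ", cl, " has fewer than 2 observations")

  combos <- utils::combn(classes, 2)
  rows <- list()
  for (f in feature_names) {
    for (j in seq_len(ncol(combos))) {
      a <- combos[1, j]; b <- combos[2, j]
      xa <- features[[f]][!is.na(lab) & lab == a]
      xb <- features[[f]][!is.na(lab) & lab == b]
      xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
      if (length(unique(c(xa, xb))) <= 1) {
        w <- length(xa) * length(xb) / 2
        p <- 1
      } else {
        ht <- suppressWarnings(
          stats::wilcox.test(xa, xb, alternative = "two.sided", exact = FALSE))
        w <- unname(ht$statistic)
        p <- ht$p.value
        if (is.na(p)) p <- 1
      }
      ma <- stats::median(xa); mb <- stats::median(xb)
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, class_a = a, class_b = b, statistic = w, p = p,
        median_a = ma, median_b = mb,
        direction = if (ma > mb) a else if (mb > ma) b else "equal",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p, method = "bonferroni")
  out[, c("feature", "class_a", "class_b", "statistic", "p", "p_adjusted",
          "median_a", "median_b", "direction")]
}

#' Fit a feature ~ age + type regression with transformation selection
#'
#' Fits ordinary least squares of a (possibly transformed) feature on
#' duplicate age and duplicate type. The transformation is chosen from none,
#' log, and Box-Cox according to which minimizes the Jarque-Bera statistic of
#' the model residuals; log and Box-Cox candidates are skipped with a warning
#' when the feature has non-positive values. An age x type interaction is
#' kept if and only if adding it decreases the AIC by at least `aic_drop`
#' (default 2) units.
#'
#' Candidates are considered in order of complexity (none, log, Box-Cox) and
#' a more complex transformation is chosen only when it improves the JB
#' statistic by more than `jb_preference` (default 2, the conventional
#' two-unit evidence threshold also used for the AIC rule) over every
#' simpler candidate.
#' Under normality JB is approximately chi-squared with 2 df, so differences
#' below ~2 units are noise; without this margin the choice between log and a
#' Box-Cox fit with lambda near 0 would be arbitrary on genuinely log-normal
#' data.
#'
#' @param values numeric feature vector (duplicates only).
#' @param ages duplicate ages in age units, no missing values.
#' @param types factor or character of duplicate types (two levels).
#' @param feature optional feature name carried into the result.
#' @param aic_drop AIC improvement required to keep the interaction.
#' @param jb_preference JB improvement a more complex transformation must
#'   offer over a simpler one to be chosen (default 2).
#' @param normality_on `"residuals"` (default) assesses candidate
#'   transformations on model residuals; `"values"` on the transformed
#'   feature itself.
#' @return Object of class `regression_result`: a list with `feature`,
#'   `transformation`, `lambda` (Box-Cox only), `coefficients` (data frame of
#'   estimates and p-values), `interaction_included`, `aic_without`,
#'   `aic_with`, `jb` (named vector per candidate), `residuals` and the
#'   fitted `model`.
#' @export
fit_feature_age_model <- function(values, ages, types, feature = "feature",
                                  aic_drop = 2, jb_preference = 2,
                                  normality_on = c("residuals", "values")) {
  normality_on <- match.arg(normality_on)
  ok <- !is.na(values) & !is.na(ages) & !is.na(types)
  values <- values[ok]; ages <- ages[ok]
  types <- factor(types[ok])
  if (length(values) < 10) stop2("need at least 10 complete observations")
  if (nlevels(types) < 2) stop2("need two duplicate types")

  candidates <- list(none = function(y) list(y = y, lambda = NA_real_))
  if (all(values > 0)) {
    candidates$log <- function(y) list(y = log(y), lambda = NA_real_)
    candidates$boxcox <- function(y) {
      bc <- MASS::boxcox(y ~ ages + types, lambda = seq(-2, 2, 0.01),
                         plotit = FALSE)
      lambda <- bc$x[which.max(bc$y)]
      yt <- if (abs(lambda) < 1e-8) log(y) else (y^lambda - 1) / lambda
      list(y = yt, lambda = lambda)
    }
  } else {
    warning("non-positive values: log and Box-Cox candidates skipped",
            call. = FALSE)
  }

  jb <- c(); fits <- list(); lambdas <- c()
  for (nm in names(candidates)) {
    tr <- candidates[[nm]](values)
    fit <- stats::lm(tr$y ~ ages + types)
    jb[nm] <- if (normality_on == "residuals") jarque_bera(stats::residuals(fit))
              else jarque_bera(tr$y)
    fits[[nm]] <- fit
    lambdas[nm] <- tr$lambda
  }
  # candidates are ordered by complexity; take the first within
  # jb_preference of the minimum
  best <- names(jb)[which(jb <= min(jb) + jb_preference)[1]]
  base_fit <- fits[[best]]
  y_best <- stats::model.frame(base_fit)[[1]]

  int_fit <- stats::lm(y_best ~ ages * types)
  aic_without <- stats::AIC(base_fit)
  aic_with <- stats::AIC(int_fit)
  use_int <- (aic_without - aic_with) >= aic_drop
  final <- if (use_int) int_fit else base_fit

  cf <- summary(final)$coefficients
  coefs <- data.frame(term = rownames(cf), estimate = cf[, 1],
                      p = cf[, 4], row.names = NULL)

  structure(list(feature = feature, transformation = best,
                 lambda = unname(lambdas[best]),
                 coefficients = coefs, interaction_included = use_int,
                 aic_without = aic_without, aic_with = aic_with,
                 jb = jb, residuals = stats::residuals(final), model = final),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat("Feature ~ age + type regression for '", x$feature, "'\n", sep = "")
  cat("  transformation:", x$transformation,
      if (x$transformation == "boxcox") sprintf("(lambda = %.2f)", x$lambda)
      else "", "\n")
  cat("  interaction:", if (x$interaction_included) "included" else "excluded",
      sprintf("(AIC %.2f without, %.2f with)\n", x$aic_without, x$aic_with))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' Residualize a feature on duplicate age
#'
#' Returns residuals of the ordinary least squares fit feature ~ age over the
#' supplied genes (the combined SSD + WGD set in the age-controlled
#' classifier). The residuals are numerically orthogonal to age and to the
#' intercept.
#'
#' @param x numeric vector, or a data frame / matrix of feature columns.
#' @param ages duplicate ages; must be present for every gene and not
#'   constant.
#' @return Residuals in the same shape as `x`.
#' @export
residualize_on_age <- function(x, ages) {
  if (anyNA(ages)) stop2("ages must be present for all genes supplied")
  if (length(unique(ages)) < 2)
    stop2("age vector is constant: no age variation to remove")
  if (is.data.frame(x) || is.matrix(x)) {
    out <- as.data.frame(x)
    for (j in seq_along(out)) out[[j]] <- residualize_on_age(out[[j]], ages)
    return(out)
  }
  if (anyNA(x)) stop2("feature values must be complete for residualization")
  unname(stats::residuals(stats::lm(x ~ ages)))
}
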