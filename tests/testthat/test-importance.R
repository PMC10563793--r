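# shared small planted dataset for protocol tests
make_planted <- function(seed = 1, n = 240, p_noise = 8) {
  set.seed(seed)
  cls <- rep(c("WGD", "SSD"), each = n / 2)
  f <- data.frame(signal = rnorm(n, ifelse(cls == "WGD", 1.5, 0)))
  for (j in seq_len(p_noise)) f[[paste0("noise", j)]] <- rnorm(n)
  list(features = f, labels = cls)
}

test_that("the protocol is deterministic given the master seed", {
  d <- make_planted()
  cc <- classifier_config(n_iterations = 5, seed = 42)
  r1 <- run_protocol(d$features, d$labels, cc)
  r2 <- run_protocol(d$features, d$labels, cc)
  expect_identical(r1$importance, r2$importance)
  expect_identical(r1$accuracies, r2$accuracies)
  r3 <- run_protocol(d$features, d$labels,
                     classifier_config(n_iterations = 5, seed = 43))
  expect_false(identical(r1$accuracies, r3$accuracies))
})

test_that("a planted informative feature dominates the importance ranking
           and noise features sit near zero", {
  d <- make_planted(seed = 2)
  rep <- run_protocol(d$features, d$labels,
                      classifier_config(n_iterations = 10, seed = 7))
  expect_equal(rep$importance$feature[1], "signal")
  expect_equal(rep$importance$mean_rank[rep$importance$feature == "signal"],
               1, tolerance = 0.2)
  noise_imp <- rep$importance$mean_importance[rep$importance$feature !=
                                                "signal"]
  expect_true(all(abs(noise_imp) < 0.05))
  # per-iteration accuracies are proper proportions; confusion counts cover
  # every test prediction
  expect_true(all(rep$accuracies >= 0 & rep$accuracies <= 1))
  expect_equal(sum(rep$confusion), 10 * rep$n_test)
  expect_equal(unname(colSums(rep$confusion_precision)), c(1, 1))
  expect_equal(unname(rowSums(rep$confusion_recall)), c(1, 1))
})

test_that("missing feature values are an error listing the genes", {
  d <- make_planted()
  d$features$signal[3] <- NA
  d$features$gene_id <- sprintf("gene%03d", seq_len(nrow(d$features)))
  expect_error(run_protocol(d$features, d$labels,
                            classifier_config(n_iterations = 2)),
               "gene003")
})

test_that("age-controlled mode demotes a pure age proxy", {
  set.seed(9)
  n <- 240
  cls <- rep(c("WGD", "SSD"), each = n / 2)
  age <- ifelse(cls == "WGD", 10.6, runif(n, 0.5, 8.6))
  f <- data.frame(age_proxy = 3 * scale(age)[, 1] + rnorm(n, 0, 0.3),
                  real = rnorm(n, ifelse(cls == "WGD", 1.2, 0)),
                  n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
  cc <- classifier_config(n_iterations = 10, seed = 3)
  raw <- run_protocol(f, cls, cc)
  ctl <- run_age_controlled_protocol(f, age, cls, cc)
  expect_equal(raw$importance$feature[1], "age_proxy")
  rank_ctl <- which(ctl$importance$feature == "age_proxy")
  expect_gt(rank_ctl, 2)
  expect_equal(ctl$mode, "age_controlled")
  # degenerate age vector is rejected
  expect_error(run_age_controlled_protocol(f, rep(1, n), cls, cc),
               "constant")
})

test_that("hyperparameter search is deterministic and honours a
           single-candidate space", {
  d <- make_planted(seed = 4, n = 120, p_noise = 3)
  cc <- classifier_config(seed = 21, n_search = 5)
  one <- list(n_trees = 50, mtry = 2, max_depth = 0, min_node = 5,
              replace = TRUE)
  t1 <- tune_hyperparameters(d$features, d$labels, cc,
                             grid = lapply(one, function(v) v))
  expect_equal(t1$config$n_trees, 50)
  expect_equal(t1$config$min_node, 5)
  t2 <- tune_hyperparameters(d$features, d$labels, cc)
  t3 <- tune_hyperparameters(d$features, d$labels, cc)
  expect_identical(t2$config, t3$config)
  expect_identical(t2$candidates, t3$candidates)
  expect_gte(t2$best_f1, 0)
})

test_that("the dependence matrix flags duplicated features and clears
           independent noise", {
  set.seed(6)
  n <- 300
  base <- rnorm(n)
  f <- data.frame(a = base, a_copy = base + rnorm(n, 0, 0.05),
                  b = rnorm(n), c = rnorm(n))
  dm <- dependence_matrix(f, classifier_config(seed = 2))
  expect_gt(dm$dependence["a"], 0.8)
  expect_gt(dm$dependence["a_copy"], 0.8)
  expect_lt(dm$dependence["b"], 0.2)
  expect_lt(dm$dependence["c"], 0.2)
  expect_true(all(is.na(diag(dm$importances))))
  off <- dm$importances[!is.na(dm$importances)]
  expect_true(all(off >= 0 & off <= 1))
  expect_error(dependence_matrix(f[, 1:2], classifier_config()), "3 features")
})

test_that("isolation of a singleton group reproduces the baseline", {
  d <- make_planted(seed = 8, n = 160, p_noise = 3)
  cc <- classifier_config(n_iterations = 5, seed = 10)
  base <- run_protocol(d$features, d$labels, cc)
  iso <- isolation_analysis(d$features, d$labels, cc,
                            groups = list(solo = "signal"), baseline = base)
  expect_equal(iso$previous_rank, iso$new_rank)
  expect_equal(iso$previous_accuracy, iso$new_accuracy)
  expect_equal(iso$previous_importance, iso$new_importance)
  # overlapping groups are a config error
  expect_error(isolation_analysis(d$features, d$labels, cc,
                                  groups = list(a = "signal",
                                                b = c("signal", "noise1"))),
               "disjoint")
})
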