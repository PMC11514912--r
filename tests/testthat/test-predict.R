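test_that("the decision rules classify by the printed thresholds", {
  ## class-mean profiles: euploid means fire rule 1, non-euploid means none
  recs <- data.frame(
    te_count = c(141, 68, 75, 75),
    te_size_variance = c(222, 795, 478, 479),
    icm_area_um2 = c(5883, 4973, 8008, 8008))
  rc <- rule_classify(recs)
  expect_equal(rc$prediction, c(1L, 0L, 1L, 0L))
  expect_equal(rc$rule, c(1L, NA_integer_, 2L, NA_integer_))
  ## boundary semantics: variance threshold inclusive, ICM threshold exclusive
  edge <- data.frame(te_count = c(94, 95, 75),
                     te_size_variance = c(1000, 1000, 478),
                     icm_area_um2 = c(0, 0, 8007))
  expect_equal(rule_classify(edge)$prediction, c(0L, 1L, 0L))
})

test_that("stratified splits are disjoint, exhaustive and seeded", {
  tab <- ref_table()
  sp <- split_train_test(tab, test_frac = 0.2, seed = 3)
  expect_equal(nrow(sp$train) + nrow(sp$test), 226)
  expect_equal(nrow(sp$test), 45)
  expect_equal(nrow(sp$train), 181)
  expect_length(intersect(sp$train$id, sp$test$id), 0)
  ## stratification keeps the euploid fraction within one specimen
  frac_all <- mean(tab$ploidy_binary)
  expect_lt(abs(sum(sp$test$ploidy_binary) - frac_all * 45), 1 + 1e-9)
  ## determinism
  sp2 <- split_train_test(tab, test_frac = 0.2, seed = 3)
  expect_identical(sp$test$id, sp2$test$id)
  expect_false(identical(
    split_train_test(tab, seed = 4)$test$id, sp$test$id))
})

test_that("every registry model separates a separable cohort", {
  set.seed(41)
  n <- 120
  tab <- data.frame(
    diameter_um = rnorm(n, 180, 10), te_count = rnorm(n, 100, 20),
    te_density = rnorm(n, 1, .2), te_size_variance = rnorm(n, 400, 100),
    icm_area_um2 = rnorm(n, 5000, 1000))
  tab$ploidy_binary <- as.integer(tab$te_count > 100)
  tab$te_count <- tab$te_count + 100 * tab$ploidy_binary  # wide margin
  for (m in c("LR", "DT", "XGBoost", "RF", "SVM", "MLP")) {
    sc <- suppressWarnings(tune_and_train(m, tab, k = 3, seed = 2))
    expect_gt(sc$cv_auc, 0.99)
  }
  expect_error(tune_and_train("nope", tab), "registry")
})

test_that("label shuffling drives validation AUC to chance", {
  tab <- ref_table()
  shuf <- tab
  set.seed(55)
  shuf$ploidy_binary <- sample(shuf$ploidy_binary)
  aucs <- vapply(c(2, 3, 4), function(s) {
    suppressWarnings(tune_and_train("LR", shuf, k = 5, seed = s))$cv_auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("hyperparameter choice is deterministic under a fixed seed", {
  tab <- ref_table()
  a <- suppressWarnings(tune_and_train("DT", tab, seed = 5))
  b <- suppressWarnings(tune_and_train("DT", tab, seed = 5))
  expect_identical(a$best_pars, b$best_pars)
  expect_equal(a$cv_auc, b$cv_auc)
})

test_that("the ROC operating point is closest to (0, 1)", {
  ## perfect separation: midpoint threshold
  expect_equal(roc_threshold(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 0.5)
  ## 5-point example with one inversion: brute-force oracle
  scores <- c(0.9, 0.7, 0.55, 0.6, 0.2)
  labels <- c(1, 1, 0, 1, 0)
  thr <- roc_threshold(scores, labels)
  cand <- seq(0, 1, by = 0.001)
  dist <- vapply(cand, function(t) {
    sens <- mean(scores[labels == 1] > t)
    spec <- mean(scores[labels == 0] <= t)
    sqrt((1 - sens)^2 + (1 - spec)^2)
  }, numeric(1))
  sens_t <- mean(scores[labels == 1] > thr)
  spec_t <- mean(scores[labels == 0] <= thr)
  expect_equal(sqrt((1 - sens_t)^2 + (1 - spec_t)^2), min(dist),
               tolerance = 1e-9)
  ## rank statistic: invariant under strictly monotone transforms
  thr2 <- roc_threshold(plogis(scores * 7), labels)
  expect_equal(mean(scores[labels == 1] > thr),
               mean(plogis(scores * 7)[labels == 1] > thr2))
  expect_error(roc_threshold(rep(0.4, 6), c(1, 1, 1, 0, 0, 0)), "constant")
  ## Youden toggle exists and agrees here
  expect_equal(roc_threshold(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0),
                             criterion = "youden"), 0.5)
})

test_that("Clopper-Pearson intervals match their closed forms", {
  ## k = 0 and k = n closed forms
  ci0 <- clopper_pearson(0, 20)
  expect_equal(ci0[["low"]], 0)
  expect_equal(ci0[["high"]], 1 - 0.025^(1 / 20), tolerance = 1e-9)
  expect_equal(round(ci0[["high"]], 4), 0.1684)
  ci20 <- clopper_pearson(20, 20)
  expect_equal(ci20[["low"]], 0.025^(1 / 20), tolerance = 1e-9)
  expect_equal(ci20[["high"]], 1)
  ## symmetry
  ci <- clopper_pearson(7, 31)
  cj <- clopper_pearson(24, 31)
  expect_equal(ci[["low"]], 1 - cj[["high"]], tolerance = 1e-12)
  expect_error(clopper_pearson(5, 4), "k <= n")
})

test_that("DeLong comparisons follow the placement-value estimator", {
  ## identical scores: p = 1 by convention
  s <- c(0.9, 0.8, 0.7, 0.6, 0.5)
  l <- c(1, 1, 1, 0, 0)
  res <- delong_test(s, s, l)
  expect_equal(res$p, 1)
  expect_equal(res$aucA, 1)
  ## brute-force Mann-Whitney over all pairs
  pairs <- expand.grid(p = s[l == 1], n = s[l == 0])
  expect_equal(res$aucA, mean(pairs$p > pairs$n) + 0.5 * mean(pairs$p == pairs$n))
  expect_error(delong_test(s, s[1:4], l), "paired")
})

test_that("DeLong AUC variance agrees with a bootstrap oracle", {
  set.seed(99)
  n <- 20
  labels <- rep(c(1, 0), each = 10)
  scores <- labels * 0.8 + rnorm(n, sd = 0.6)
  dc <- auc_ci_delong(scores, labels)
  boot <- vapply(seq_len(10000), function(b) {
    ip <- sample(which(labels == 1), replace = TRUE)
    nn <- sample(which(labels == 0), replace = TRUE)
    auc_mann_whitney(c(scores[ip], scores[nn]),
                     c(labels[ip], labels[nn]))
  }, numeric(1))
  expect_equal(dc$se^2, var(boot), tolerance = 0.25)
  ## and the independent reference implementation agrees closely
  pr <- suppressMessages(pROC::roc(labels, scores, quiet = TRUE))
  expect_equal(dc$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-9)
  expect_equal(dc$se^2, as.numeric(pROC::var(pr)), tolerance = 1e-9)
})

test_that("McNemar exact p matches hand computation and symmetry", {
  labels <- rep(1, 20)
  predsA <- c(rep(1, 9), 0, rep(1, 10))
  predsB <- c(rep(0, 9), 1, rep(1, 10))
  res <- mcnemar_test(predsA, predsB, labels)
  expect_equal(res$b, 9)
  expect_equal(res$c, 1)
  expect_equal(res$p, 22 / 1024, tolerance = 1e-12)
  ## swapping A and B preserves p
  res2 <- mcnemar_test(predsB, predsA, labels)
  expect_equal(res2$p, res$p)
  ## identical predictions
  expect_equal(mcnemar_test(predsA, predsA, labels)$p, 1)
})

test_that("evaluation metrics are internally consistent with exact CIs", {
  labels <- c(rep(1, 26), rep(0, 19))
  preds <- c(rep(1, 25), 0, rep(0, 18), 1)   # tp 25, fn 1, tn 18, fp 1
  ev <- evaluate(labels, preds)
  expect_equal(ev$tp, 25); expect_equal(ev$fn, 1)
  expect_equal(ev$accuracy$value, (ev$tp + ev$tn) /
                 (ev$tp + ev$tn + ev$fp + ev$fn))
  expect_equal(ev$precision$value, ev$tp / (ev$tp + ev$fp))
  ## sensitivity 25/26 = 96.2% with exact CI (80.4%, 99.9%)
  expect_equal(round(100 * ev$sensitivity$value, 1), 96.2)
  expect_equal(round(100 * ev$sensitivity$ci_low, 1), 80.4)
  expect_equal(round(100 * ev$sensitivity$ci_high, 1), 99.9)
  ## accuracy 43/45 = 95.6% with exact CI (84.9%, 99.5%)
  ev2 <- evaluate(c(rep(1, 26), rep(0, 19)),
                  c(rep(1, 25), 0, rep(0, 18), 1))
  expect_equal(ev2$accuracy$k, 43); expect_equal(ev2$accuracy$n, 45)
  expect_equal(round(100 * ev2$accuracy$value, 1), 95.6)
  expect_equal(round(100 * ev2$accuracy$ci_low, 1), 84.9)
  expect_equal(round(100 * ev2$accuracy$ci_high, 1), 99.5)
  ## all-correct small sample: lower bound 0.025^(1/10)
  ev3 <- evaluate(rep(c(1, 0), 5), rep(c(1, 0), 5))
  expect_equal(ev3$accuracy$ci_low, 0.025^(1 / 10), tolerance = 1e-9)
  expect_equal(ev3$accuracy$ci_high, 1)
})

test_that("permutation importance finds the informative feature", {
  set.seed(70)
  n <- 300
  tab <- data.frame(
    diameter_um = rnorm(n), te_count = rnorm(n), te_density = rnorm(n),
    te_size_variance = rnorm(n), icm_area_um2 = rnorm(n))
  tab$ploidy_binary <- rbinom(n, 1, plogis(3 * tab$te_count))
  sc <- tune_and_train("LR", tab, k = 3, seed = 1)
  fi <- feature_importance(sc, tab, n_repeats = 10, seed = 2)
  expect_equal(fi$feature[1], "te_count")
  expect_gt(fi$importance[1], 0.1)
  expect_lt(max(fi$importance[-1]), fi$importance[1] / 3)
  ## a duplicated signal column shares (or, when the model leans on the
  ## copy, absorbs) the importance: no single duplicate outranks the solo
  ## signal importance, and no noise feature rises above it either
  tab2 <- tab
  tab2$te_density <- tab2$te_count
  sc2 <- suppressWarnings(tune_and_train("LR", tab2, k = 3, seed = 1))
  fi2 <- suppressWarnings(feature_importance(sc2, tab2, n_repeats = 10,
                                             seed = 2))
  dup_imp <- fi2$importance[fi2$feature %in% c("te_count", "te_density")]
  noise_imp <- fi2$importance[!fi2$feature %in% c("te_count", "te_density")]
  expect_lte(max(dup_imp), fi$importance[1] + 0.05)
  expect_lt(max(noise_imp), fi$importance[1] / 2)
  ## stability of the top feature across repeat counts on an easy problem
  fi_1 <- feature_importance(sc, tab, n_repeats = 1, seed = 3)
  expect_equal(fi_1$feature[1], "te_count")
})

test_that("the benchmark harness reports per-seed test metrics", {
  tab <- ref_table()
  bm <- suppressWarnings(
    benchmark_models(tab, models = c("LR", "DT"), seeds = 1:2))
  expect_equal(nrow(bm), 4)
  expect_true(all(bm$tp + bm$fn + bm$tn + bm$fp == 45))
  expect_true(all(bm$auc >= 0 & bm$auc <= 1))
  expect_true(all(bm$accuracy_lo <= bm$accuracy &
                    bm$accuracy <= bm$accuracy_hi))
})
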