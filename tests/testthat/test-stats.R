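test_that("a binary-predictor OR equals the 2x2 cross-product ratio", {
  x <- rep(c(1, 1, 0, 0), c(30, 10, 10, 30))
  y <- rep(c(1, 0, 1, 0), c(30, 10, 10, 30))
  res <- univariate_logistic(x, y)
  expect_equal(res$estimate, 9, tolerance = 1e-6)
  ## oracle identity on random tables without zero cells
  for (seed in 1:5) {
    set.seed(seed)
    tab <- matrix(sample(5:40, 4), 2)
    x <- rep(c(1, 1, 0, 0), as.vector(tab))
    y <- rep(c(1, 0, 1, 0), as.vector(tab))
    expect_equal(univariate_logistic(x, y)$estimate,
                 (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1]),
                 tolerance = 1e-6)
  }
})

test_that("an outcome-independent feature gives OR near 1, p near 1", {
  x <- rep(c(10, 20, 30), 200)
  y <- rep(rep(c(0, 1), each = 3), 100)
  res <- univariate_logistic(x, y)
  expect_equal(res$estimate, 1, tolerance = 1e-6)
  expect_gt(res$p_value, 0.99)
  expect_true(res$ci_low <= res$estimate && res$estimate <= res$ci_high)
})

test_that("perfect separation is flagged, not fatal", {
  x <- c(1:10, 21:30)
  y <- rep(c(0, 1), each = 10)
  res <- suppressWarnings(univariate_logistic(x, y))
  expect_true(res$separation)
  expect_true(is.infinite(res$estimate))
})

test_that("stepwise selection finds a planted signal", {
  found <- 0L; first <- 0L; extras <- 0L
  n_rep <- 40L
  for (r in seq_len(n_rep)) {
    set.seed(100 + r)
    n <- 500
    X <- data.frame(signal = rnorm(n), n1 = rnorm(n), n2 = rnorm(n),
                    n3 = rnorm(n), n4 = rnorm(n))
    y <- rbinom(n, 1, plogis(1.5 * X$signal))
    sel <- forward_stepwise_logistic(X, y)$selected
    if ("signal" %in% sel) found <- found + 1L
    if (length(sel) && sel[1] == "signal") first <- first + 1L
    extras <- extras + length(setdiff(sel, "signal"))
  }
  ## the signal always enters, and enters first; pure-noise co-entries occur
  ## at the familywise alpha rate (~0.19 with four candidates at 0.05), so
  ## the mean number of extras stays well below one
  expect_gte(found / n_rep, 0.95)
  expect_gte(first / n_rep, 0.95)
  expect_lt(extras / n_rep, 0.5)
})

test_that("all-noise features are selected at roughly the familywise rate", {
  sel_any <- 0L
  n_rep <- 60L
  for (r in seq_len(n_rep)) {
    set.seed(300 + r)
    n <- 300
    X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n), d = rnorm(n))
    y <- rbinom(n, 1, 0.5)
    if (length(forward_stepwise_logistic(X, y)$selected)) sel_any <- sel_any + 1L
  }
  ## familywise false-entry rate over 4 candidates at alpha 0.05 is ~0.19;
  ## allow generous binomial noise around it
  expect_lt(sel_any / n_rep, 0.40)
})

test_that("alpha_enter = 1 reproduces the full multivariate fit", {
  set.seed(77)
  n <- 200
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- rbinom(n, 1, plogis(0.5 * X$a - 0.3 * X$c))
  step <- forward_stepwise_logistic(X, y, alpha_enter = 1, alpha_remove = 1)
  expect_setequal(step$selected, c("a", "b", "c"))
  full <- glm(y ~ a + b + c, data = cbind(X, y = y), family = binomial())
  for (v in c("a", "b", "c")) {
    expect_equal(step$results[[v]]$estimate, exp(coef(full)[[v]]),
                 tolerance = 1e-6)
  }
})

test_that("unselected features are echoed with the aOR sentinel", {
  set.seed(78)
  n <- 400
  X <- data.frame(signal = rnorm(n), noise = rnorm(n))
  y <- rbinom(n, 1, plogis(2 * X$signal))
  res <- forward_stepwise_logistic(X, y)
  expect_equal(res$results$noise$estimate, 1)
  expect_true(is.na(res$results$noise$ci_low))
})

test_that("two-sample t matches hand computation and conventions", {
  ht <- two_sample_t(c(1, 2, 3), c(4, 5, 6), welch = FALSE)
  expect_equal(ht$t, -3.674, tolerance = 1e-3)
  expect_equal(ht$p, 0.0214, tolerance = 5e-3)
  expect_equal(ht$df, 4)
  ## same sample: t = 0, p = 1
  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  ## Welch equals pooled when variances and sizes are equal
  x <- c(1, 2, 3, 4); y <- c(5, 6, 7, 8)
  expect_equal(two_sample_t(x, y, welch = TRUE)$t,
               two_sample_t(x, y, welch = FALSE)$t)
  expect_equal(two_sample_t(x, y, welch = TRUE)$df,
               two_sample_t(x, y, welch = FALSE)$df)
  ## zero variance in both groups with equal means
  expect_equal(two_sample_t(c(2, 2), c(2, 2))$p, 1)
})

test_that("chi-squared test matches hand computation and symmetry", {
  null_tab <- matrix(10, 2, 2)
  res <- chi_square_trend(null_tab)
  expect_equal(res$chi2, 0)
  expect_equal(res$p, 1)
  res2 <- chi_square_trend(matrix(c(20, 10, 10, 20), 2))
  expect_equal(res2$chi2, 20 / 3, tolerance = 1e-9)
  expect_equal(res2$df, 1)
  ## permutation invariance
  tab <- matrix(c(12, 5, 9, 20, 7, 11), 2, 3)
  expect_equal(chi_square_trend(tab)$chi2,
               chi_square_trend(tab[2:1, c(3, 1, 2)])$chi2)
  expect_error(chi_square_trend(matrix(c(0, 0, 5, 5), 2)), "margin")
})

test_that("Pearson correlation behaves on exact and generated data", {
  x <- c(1, 2, 4, 7, 9)
  expect_equal(pearson_corr(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_corr(x, -x)$r, -1)
  expect_error(pearson_corr(x, rep(3, 5)), "variance")
  ## density and count are strongly positively correlated by construction
  tab <- simulate_feature_table(1000, seed = 6)
  expect_gt(pearson_corr(tab$te_density, tab$te_count)$r, 0.7)
})

test_that("group summaries report per-class moments with n-1 SDs", {
  tab <- ref_table()
  gs <- group_summary(tab, "ploidy_binary")
  eu <- gs[gs$feature == "te_count" & gs$group == "1", ]
  hand <- tab$te_count[tab$ploidy_binary == 1]
  expect_equal(eu$mean, mean(hand))
  expect_equal(eu$sd, sd(hand))
  expect_equal(eu$n, length(hand))
  ## constant feature has SD 0
  tab$const <- 5
  gs2 <- group_summary(tab, "ploidy_binary", features = "const")
  expect_true(all(gs2$sd[gs2$group != "all"] == 0))
})

test_that("association analysis recovers the simulated class structure", {
  tab <- ref_table()
  res <- analyze_associations(tab)
  ## TE count separates the classes strongly in the simulated cohort
  expect_lt(res$univariate$te_count$p_value, 1e-6)
  expect_gt(res$univariate$te_count$estimate, 1)
  expect_true("te_count" %in% res$multivariate$selected)
  ## every univariate CI contains its estimate
  for (u in res$univariate) {
    expect_true(u$ci_low <= u$estimate && u$estimate <= u$ci_high)
  }
})
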