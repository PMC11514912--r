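## Association statistics between 3D morphological parameters and ploidy
## status: group summaries, univariate logistic odds ratios, forward
## stepwise multivariate logistic regression, two-sample tests, trend
## chi-squared, and Pearson correlations. All tests are two-tailed.

#' Univariate logistic association of one feature with a binary outcome
#'
#' Single-predictor logistic regression by maximum likelihood; the odds
#' ratio per unit of the feature is `exp(beta)` with a Wald 95% CI
#' `exp(beta +- 1.96 * SE)` and a two-tailed Wald p-value.
#'
#' @param x numeric feature vector.
#' @param y binary outcome (0/1 or logical).
#' @return list of class `assoc_result`: `estimate` (OR), `ci_low`,
#'   `ci_high`, `p_value`, `n`, `beta`, `se`, `method`; perfect separation is
#'   flagged (`separation = TRUE`) with an infinite-OR sentinel rather than
#'   an error.
#' @export
univariate_logistic <- function(x, y) {
  y <- as.integer(y)
  stopifnot(length(x) == length(y), all(y %in% 0:1))
  if (length(unique(y)) < 2L) {
    stop("univariate_logistic: outcome has a single class", call. = FALSE)
  }
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
  beta <- stats::coef(fit)[["x"]]
  se <- sqrt(diag(stats::vcov(fit)))[["x"]]
  separated <- !fit$converged || se > 100 || abs(beta) > 50
  z <- beta / se
  structure(list(
    estimate = if (separated) sign(beta) * Inf else exp(beta),
    ci_low = exp(beta - 1.96 * se),
    ci_high = exp(beta + 1.96 * se),
    p_value = 2 * stats::pnorm(-abs(z)),
    n = length(y),
    beta = beta, se = se,
    separation = separated,
    method = "univariate logistic (Wald)"
  ), class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("<assoc_result> %s: OR %.3f (%.3f-%.3f), p = %.4g, n = %d\n",
              x$method, x$estimate, x$ci_low, x$ci_high, x$p_value, x$n))
  invisible(x)
}

#' Forward stepwise multivariate logistic regression
#'
#' SPSS-style "Forward: LR" selection: at each step the candidate with the
#' smallest likelihood-ratio p-value enters if below `alpha_enter`; after
#' each entry, any included feature whose LR p-value (against the model
#' without it) exceeds `alpha_remove` is removed; iteration stops at a
#' fixpoint. Adjusted odds ratios (aOR) with Wald CIs come from the final
#' model; unselected features are echoed with the conventional aOR sentinel
#' 1.000.
#'
#' @param X data.frame or matrix of candidate features (>= 2 columns).
#' @param y binary outcome.
#' @param alpha_enter entry threshold on the LR p-value (default 0.05).
#' @param alpha_remove removal threshold (default 0.10).
#' @return list with `selected` (character), `results` (named list of
#'   `assoc_result`, aOR = 1 sentinel with NA CIs for unselected), `model`
#'   (the final glm fit).
#' @export
forward_stepwise_logistic <- function(X, y, alpha_enter = 0.05,
                                      alpha_remove = 0.10) {
  X <- as.data.frame(X)
  stopifnot(ncol(X) >= 2)
  y <- as.integer(y)
  fit_ll <- function(vars) {
    dat <- cbind(X[, vars, drop = FALSE], .y = y)
    f <- if (length(vars)) {
      stats::glm(.y ~ ., data = dat, family = stats::binomial())
    } else {
      stats::glm(.y ~ 1, data = data.frame(.y = y), family = stats::binomial())
    }
    if (!f$converged) {
      stop(sprintf("forward_stepwise_logistic: MLE did not converge (features: %s)",
                   paste(vars, collapse = ", ")), call. = FALSE)
    }
    f
  }
  lr_p <- function(fit_big, fit_small, df) {
    stat <- 2 * (as.numeric(stats::logLik(fit_big)) -
                   as.numeric(stats::logLik(fit_small)))
    stats::pchisq(max(stat, 0), df = df, lower.tail = FALSE)
  }
  selected <- character(0)
  repeat {
    changed <- FALSE
    ## entry step
    candidates <- setdiff(names(X), selected)
    if (length(candidates)) {
      base_fit <- fit_ll(selected)
      ps <- vapply(candidates, function(v) {
        lr_p(fit_ll(c(selected, v)), base_fit, 1L)
      }, numeric(1))
      if (min(ps) < alpha_enter) {
        selected <- c(selected, candidates[which.min(ps)])
        changed <- TRUE
      }
    }
    ## removal step
    if (length(selected) > 1L) {
      full_fit <- fit_ll(selected)
      ps_rm <- vapply(selected, function(v) {
        lr_p(full_fit, fit_ll(setdiff(selected, v)), 1L)
      }, numeric(1))
      worst <- which.max(ps_rm)
      if (ps_rm[worst] > alpha_remove) {
        selected <- selected[-worst]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  final <- fit_ll(selected)
  cf <- stats::coef(final)
  se <- sqrt(diag(stats::vcov(final)))
  results <- lapply(names(X), function(v) {
    if (v %in% selected) {
      b <- cf[[v]]; s <- se[[v]]
      structure(list(
        estimate = exp(b), ci_low = exp(b - 1.96 * s),
        ci_high = exp(b + 1.96 * s),
        p_value = 2 * stats::pnorm(-abs(b / s)),
        n = length(y), beta = b, se = s, separation = FALSE,
        method = "stepwise multivariate logistic (Wald)"
      ), class = "assoc_result")
    } else {
      structure(list(
        estimate = 1, ci_low = NA_real_, ci_high = NA_real_,
        p_value = NA_real_, n = length(y), beta = 0, se = NA_real_,
        separation = FALSE,
        method = "not selected (aOR sentinel 1.000)"
      ), class = "assoc_result")
    }
  })
  names(results) <- names(X)
  list(selected = selected, results = results, model = final)
}

#' Two-sample t-test
#'
#' Two-tailed; Welch (Satterthwaite df) by default, pooled-variance
#' otherwise. Zero variance in both groups with equal means gives p = 1 by
#' convention.
#'
#' @param x,y numeric samples (>= 2 each).
#' @param welch use Welch's unequal-variance form (default TRUE).
#' @return list with `t`, `df`, `p`.
#' @export
two_sample_t <- function(x, y, welch = TRUE) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = NA_real_, p = 1))
    return(list(t = sign(mean(x) - mean(y)) * Inf, df = NA_real_, p = 0))
  }
  ht <- stats::t.test(x, y, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Pearson chi-squared test on a contingency table
#'
#' Without continuity correction; df = (r - 1)(c - 1).
#'
#' @param tab matrix of counts (at least 2 x 2).
#' @return list with `chi2`, `df`, `p`.
#' @export
chi_square_trend <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(nrow(tab) >= 2, ncol(tab) >= 2, all(tab >= 0))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) {
    stop("chi_square_trend: degenerate margin (expected count 0)",
         call. = FALSE)
  }
  chi2 <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Pearson correlation with two-tailed p-value
#'
#' @param x,y numeric vectors (n >= 3) with nonzero variance.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_corr <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("pearson_corr: zero variance, correlation undefined", call. = FALSE)
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p = unname(ht$p.value), n = length(x))
}

#' Group summary of a feature table with per-feature test p-values
#'
#' Per-group mean, SD (n - 1) and n for each feature, plus the two-group
#' t-test p-value when the grouping is binary.
#'
#' @param table a feature-table data.frame (see [read_feature_table()]).
#' @param group_by name of the grouping column (e.g. `"ploidy_binary"`).
#' @param features feature columns to summarize; defaults to the five
#'   morphological parameters present.
#' @param welch t-test flavour, see [two_sample_t()].
#' @return data.frame with one row per feature x group plus an `all` group;
#'   columns `feature`, `group`, `n`, `mean`, `sd`, `p_value` (two-group
#'   comparisons only; NA otherwise).
#' @export
group_summary <- function(table, group_by,
                          features = intersect(
                            c("diameter_um", "te_count", "te_density",
                              "te_size_variance", "icm_area_um2"),
                            names(table)),
                          welch = TRUE) {
  if (!group_by %in% names(table)) {
    stop("group_summary: no column named ", group_by, call. = FALSE)
  }
  g <- table[[group_by]]
  groups <- sort(unique(g), decreasing = TRUE)
  out <- list()
  for (f in features) {
    v <- table[[f]]
    p <- if (length(groups) == 2L) {
      two_sample_t(v[g == groups[1]], v[g == groups[2]], welch = welch)$p
    } else NA_real_
    out[[length(out) + 1L]] <- data.frame(
      feature = f, group = "all", n = length(v), mean = mean(v),
      sd = stats::sd(v), p_value = p)
    for (gr in groups) {
      vv <- v[g == gr]
      flagged <- length(vv) < 2L
      out[[length(out) + 1L]] <- data.frame(
        feature = f, group = as.character(gr), n = length(vv),
        mean = mean(vv), sd = if (flagged) NA_real_ else stats::sd(vv),
        p_value = NA_real_)
      if (flagged) {
        warning(sprintf("group_summary: group %s has n < 2; SD missing", gr),
                call. = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Table-style univariate + multivariate association analysis
#'
#' Runs [univariate_logistic()] per feature and
#' [forward_stepwise_logistic()] across the five morphological parameters
#' against the euploid/non-euploid outcome, mirroring the standard
#' association-table layout.
#'
#' @param table feature table with a `ploidy_binary` column
#'   (see [read_feature_table()]).
#' @param features candidate feature columns.
#' @return list with `summary` ([group_summary()] by ploidy), `univariate`
#'   (named list of `assoc_result`), `multivariate`
#'   (see [forward_stepwise_logistic()]).
#' @export
analyze_associations <- function(table,
                                 features = intersect(
                                   c("diameter_um", "te_count", "te_density",
                                     "te_size_variance", "icm_area_um2"),
                                   names(table))) {
  stopifnot("ploidy_binary" %in% names(table))
  y <- table$ploidy_binary
  uni <- lapply(features, function(f) univariate_logistic(table[[f]], y))
  names(uni) <- features
  multi <- forward_stepwise_logistic(table[, features, drop = FALSE], y)
  list(summary = group_summary(table, "ploidy_binary", features),
       univariate = uni, multivariate = multi)
}
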