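## Interpretable euploidy prediction: the printed decision-rule classifier,
## a six-model benchmark harness (stratified split, k-fold tuning by AUC,
## ROC operating point closest to (0,1)), and the evaluation statistics
## (exact binomial CIs, DeLong AUC comparison, McNemar, permutation
## feature importance).

#' Decision-rule set for euploidy prediction
#'
#' Thresholds extracted from the decision-tree model: a blastocyst is
#' predicted euploid if its TE cell count exceeds `te_count_threshold`, or if
#' its TE cell size variance is at most `variance_threshold` while its ICM
#' area exceeds `icm_threshold`.
#'
#' @param te_count_threshold TE cell count threshold (default 94, exclusive).
#' @param variance_threshold size-variance threshold in um^2 (default 478,
#'   inclusive).
#' @param icm_threshold ICM area threshold in um^2 (default 8007, exclusive).
#' @return An object of class `rule_set`.
#' @export
rule_set <- function(te_count_threshold = 94, variance_threshold = 478,
                     icm_threshold = 8007) {
  stopifnot(te_count_threshold > 0, variance_threshold > 0, icm_threshold > 0)
  structure(list(te_count_threshold = te_count_threshold,
                 variance_threshold = variance_threshold,
                 icm_threshold = icm_threshold), class = "rule_set")
}

#' Classify blastocysts by the decision rules
#'
#' Euploid iff `te_count > te_count_threshold` OR
#' (`te_size_variance <= variance_threshold` AND `icm_area > icm_threshold`);
#' inequality strictness follows the printed rules exactly.
#'
#' @param records data.frame with columns `te_count`, `te_size_variance`,
#'   `icm_area_um2` (a feature table or [record_to_row()] output).
#' @param rules a [rule_set()].
#' @return list with `prediction` (integer 0/1 vector) and `rule` (1, 2, or
#'   NA per blastocyst: which rule fired).
#' @export
rule_classify <- function(records, rules = rule_set()) {
  r1 <- records$te_count > rules$te_count_threshold
  r2 <- records$te_size_variance <= rules$variance_threshold &
    records$icm_area_um2 > rules$icm_threshold
  list(prediction = as.integer(r1 | r2),
       rule = ifelse(r1, 1L, ifelse(r2, 2L, NA_integer_)))
}

#' Stratified train/test split
#'
#' @param table feature table with a `ploidy_binary` column.
#' @param test_frac test fraction (default 0.2).
#' @param stratify stratify by the binary outcome (default TRUE).
#' @param seed RNG seed.
#' @return list with `train` and `test` data.frames (disjoint, exhaustive).
#' @export
split_train_test <- function(table, test_frac = 0.2, stratify = TRUE,
                             seed = 1L) {
  y <- table$ploidy_binary
  if (min(table(y)) < 2L) {
    stop("split_train_test: each class needs at least 2 members", call. = FALSE)
  }
  rng <- local_rng(seed)
  pick <- logical(nrow(table))
  if (stratify) {
    ## largest-remainder allocation: per-class counts sum to the overall
    ## rounded test size, with class fractions within one specimen
    classes <- unique(y)
    exact <- vapply(classes, function(cl) test_frac * sum(y == cl), numeric(1))
    k_cl <- floor(exact)
    short <- round(test_frac * nrow(table)) - sum(k_cl)
    if (short > 0) {
      bump <- order(exact - k_cl, decreasing = TRUE)[seq_len(short)]
      k_cl[bump] <- k_cl[bump] + 1L
    }
    for (j in seq_along(classes)) {
      idx <- which(y == classes[j])
      pick[idx[order(rng$runif(length(idx)))[seq_len(k_cl[j])]]] <- TRUE
    }
  } else {
    k <- round(test_frac * nrow(table))
    pick[order(rng$runif(nrow(table)))[seq_len(k)]] <- TRUE
  }
  list(train = table[!pick, , drop = FALSE], test = table[pick, , drop = FALSE])
}

#' AUC by the Mann-Whitney statistic
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels.
#' @return AUC in `[0, 1]`.
#' @export
auc_mann_whitney <- function(scores, labels) {
  labels <- as.integer(labels)
  pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
  stopifnot(length(pos) > 0, length(neg) > 0)
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

## ---- six-model registry -------------------------------------------------

model_registry <- function() {
  list(
    LR = list(
      grid = expand.grid(dummy = 1),
      fit = function(tr, pars) {
        f <- stats::glm(ploidy_binary ~ ., data = tr,
                        family = stats::binomial())
        function(newdata) {
          as.numeric(stats::predict(f, newdata = newdata, type = "response"))
        }
      }),
    DT = list(
      grid = expand.grid(maxdepth = c(2, 3, 4), cp = c(0.0, 0.01),
                         minsplit = c(5, 10)),
      fit = function(tr, pars) {
        f <- rpart::rpart(ploidy_binary ~ ., data = tr, method = "class",
                          control = rpart::rpart.control(
                            maxdepth = pars$maxdepth, cp = pars$cp,
                            minsplit = pars$minsplit, xval = 0))
        function(newdata) {
          as.numeric(stats::predict(f, newdata = newdata)[, "1"])
        }
      }),
    XGBoost = list(
      grid = expand.grid(max_depth = c(2, 3), eta = c(0.1, 0.3),
                         nrounds = c(30, 60)),
      fit = function(tr, pars) {
        X <- as.matrix(tr[, setdiff(names(tr), "ploidy_binary")])
        dtrain <- xgboost::xgb.DMatrix(X, label = tr$ploidy_binary,
                                       nthread = 1)
        f <- xgboost::xgb.train(
          params = list(objective = "binary:logistic",
                        max_depth = pars$max_depth, eta = pars$eta,
                        tree_method = "exact", nthread = 1),
          data = dtrain, nrounds = pars$nrounds, verbose = 0)
        function(newdata) {
          nd <- as.matrix(newdata[, colnames(X), drop = FALSE])
          as.numeric(stats::predict(f, xgboost::xgb.DMatrix(nd, nthread = 1)))
        }
      }),
    RF = list(
      grid = expand.grid(ntree = c(300), mtry = c(2, 3), nodesize = c(1, 5)),
      fit = function(tr, pars) {
        f <- randomForest::randomForest(
          x = tr[, setdiff(names(tr), "ploidy_binary")],
          y = factor(tr$ploidy_binary, levels = c(0, 1)),
          ntree = pars$ntree, mtry = pars$mtry, nodesize = pars$nodesize)
        function(newdata) {
          nd <- newdata[, setdiff(names(tr), "ploidy_binary"), drop = FALSE]
          as.numeric(stats::predict(f, nd, type = "prob")[, "1"])
        }
      }),
    SVM = list(
      grid = expand.grid(cost = c(0.5, 1, 4), gamma_scale = c(0.5, 1, 2)),
      fit = function(tr, pars) {
        X <- tr[, setdiff(names(tr), "ploidy_binary"), drop = FALSE]
        f <- e1071::svm(x = X, y = factor(tr$ploidy_binary, levels = c(0, 1)),
                        kernel = "radial", cost = pars$cost,
                        gamma = pars$gamma_scale / ncol(X),
                        probability = TRUE, scale = TRUE)
        function(newdata) {
          nd <- newdata[, colnames(X), drop = FALSE]
          pr <- stats::predict(f, nd, probability = TRUE)
          as.numeric(attr(pr, "probabilities")[, "1"])
        }
      }),
    MLP = list(
      grid = expand.grid(size = c(3, 5, 8), decay = c(0.01, 0.1)),
      fit = function(tr, pars) {
        X <- as.matrix(tr[, setdiff(names(tr), "ploidy_binary")])
        mu <- colMeans(X); sg <- apply(X, 2, stats::sd)
        sg[sg == 0] <- 1
        Xs <- sweep(sweep(X, 2, mu), 2, sg, "/")
        f <- nnet::nnet(Xs, tr$ploidy_binary, size = pars$size,
                        decay = pars$decay, maxit = 500, entropy = TRUE,
                        trace = FALSE)
        function(newdata) {
          nd <- as.matrix(newdata[, colnames(X), drop = FALSE])
          nds <- sweep(sweep(nd, 2, mu), 2, sg, "/")
          as.numeric(stats::predict(f, nds))
        }
      })
  )
}

#' Tune and train one of the six benchmark models
#'
#' Grid search over a small documented hyperparameter grid, selecting by mean
#' validation AUC over k stratified folds, then refitting on the full
#' training set. The returned scorer maps a feature data.frame to scores in
#' `[0, 1]`.
#'
#' @param model_name one of `"LR"`, `"DT"`, `"XGBoost"`, `"RF"`, `"SVM"`,
#'   `"MLP"`.
#' @param train training feature table (five features + `ploidy_binary`).
#' @param k number of cross-validation folds (default 5).
#' @param seed RNG seed (folds and any stochastic learner).
#' @param features feature columns used as model input.
#' @return list of class `fitted_scorer`: `score` (function), `model_name`,
#'   `best_pars`, `cv_auc` (mean validation AUC of the chosen setting).
#' @export
tune_and_train <- function(model_name, train, k = 5L, seed = 1L,
                           features = intersect(
                             c("diameter_um", "te_count", "te_density",
                               "te_size_variance", "icm_area_um2"),
                             names(train))) {
  reg <- model_registry()
  if (!model_name %in% names(reg)) {
    stop("tune_and_train: unknown model '", model_name, "'; registry: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  }
  spec <- reg[[model_name]]
  tr <- train[, c(features, "ploidy_binary")]
  if (length(unique(tr$ploidy_binary)) < 2L) {
    stop("tune_and_train: training data has a single class", call. = FALSE)
  }
  folds <- stratified_folds(tr$ploidy_binary, k, seed)
  grid <- spec$grid
  cv_auc <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    pars <- grid[gi, , drop = FALSE]
    aucs <- vapply(seq_len(k), function(fi) {
      tr_f <- tr[folds != fi, , drop = FALSE]
      va_f <- tr[folds == fi, , drop = FALSE]
      if (length(unique(va_f$ploidy_binary)) < 2L ||
          length(unique(tr_f$ploidy_binary)) < 2L) return(NA_real_)
      set.seed(seed + 1000L * gi + fi)
      sc <- spec$fit(tr_f, pars)
      auc_mann_whitney(sc(va_f), va_f$ploidy_binary)
    }, numeric(1))
    cv_auc[gi] <- mean(aucs, na.rm = TRUE)
  }
  best <- which.max(cv_auc)
  set.seed(seed)
  scorer <- spec$fit(tr, grid[best, , drop = FALSE])
  structure(list(score = scorer, model_name = model_name,
                 best_pars = grid[best, , drop = FALSE],
                 cv_auc = cv_auc[best], features = features),
            class = "fitted_scorer")
}

stratified_folds <- function(y, k, seed) {
  rng <- local_rng(seed)
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    folds[idx[order(rng$runif(length(idx)))]] <-
      rep(seq_len(k), length.out = length(idx))
  }
  folds
}

#' ROC operating threshold closest to the top-left corner (0, 1)
#'
#' Over all midpoints between consecutive sorted unique scores (plus the two
#' outer extremes), minimizes `sqrt((1 - sens)^2 + (1 - spec)^2)`; ties break
#' toward higher specificity.
#'
#' @param scores numeric scores.
#' @param labels binary labels.
#' @param criterion `"topleft"` (default) or `"youden"` (maximize
#'   sens + spec - 1).
#' @return the threshold (predict positive when score >= threshold is FALSE;
#'   the convention here is positive when score > threshold).
#' @export
roc_threshold <- function(scores, labels, criterion = c("topleft", "youden")) {
  criterion <- match.arg(criterion)
  labels <- as.integer(labels)
  stopifnot(any(labels == 1L), any(labels == 0L))
  u <- sort(unique(scores))
  if (length(u) < 2L) {
    stop("roc_threshold: constant scores, no discrimination", call. = FALSE)
  }
  cand <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  sens <- vapply(cand, function(t) sum(scores > t & labels == 1L) / n_pos,
                 numeric(1))
  spec <- vapply(cand, function(t) sum(scores <= t & labels == 0L) / n_neg,
                 numeric(1))
  obj <- if (criterion == "topleft") {
    sqrt((1 - sens)^2 + (1 - spec)^2)
  } else {
    -(sens + spec - 1)
  }
  best <- which(obj == min(obj))
  cand[best[which.max(spec[best])]]
}

#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' Beta-quantile formulation: the lower bound is the 0.025 quantile of
#' Beta(k, n - k + 1) (0 when k = 0) and the upper bound the 0.975 quantile
#' of Beta(k + 1, n - k) (1 when k = n).
#'
#' @param k number of successes.
#' @param n number of trials.
#' @param conf confidence level (default 0.95).
#' @return numeric length-2 vector (low, high) as proportions.
#' @export
clopper_pearson <- function(k, n, conf = 0.95) {
  if (n < 1 || k < 0 || k > n || k != round(k) || n != round(n)) {
    stop("clopper_pearson: need integers 0 <= k <= n, n >= 1", call. = FALSE)
  }
  a <- (1 - conf) / 2
  low <- if (k == 0) 0 else stats::qbeta(a, k, n - k + 1)
  high <- if (k == n) 1 else stats::qbeta(1 - a, k + 1, n - k)
  c(low = low, high = high)
}

#' DeLong variance-covariance of one or two AUCs
#'
#' Placement-value (structural components) estimator.
#'
#' @keywords internal
delong_components <- function(score_list, labels) {
  labels <- as.integer(labels)
  pos <- which(labels == 1L); neg <- which(labels == 0L)
  m <- length(pos); n <- length(neg)
  aucs <- numeric(length(score_list))
  V10 <- matrix(0, m, length(score_list))
  V01 <- matrix(0, n, length(score_list))
  for (k in seq_along(score_list)) {
    s <- score_list[[k]]
    psi <- outer(s[pos], s[neg], function(a, b) {
      (a > b) + 0.5 * (a == b)
    })
    aucs[k] <- mean(psi)
    V10[, k] <- rowMeans(psi)
    V01[, k] <- colMeans(psi)
  }
  S10 <- stats::cov(V10); S01 <- stats::cov(V01)
  list(aucs = aucs, S = S10 / m + S01 / n, m = m, n = n)
}

#' DeLong test comparing two paired AUCs
#'
#' Nonparametric comparison of two ROC curves measured on the same
#' specimens; two-tailed z-test on the AUC difference with the DeLong
#' placement-value covariance. Identical scores give p = 1 by convention.
#'
#' @param scoresA,scoresB paired score vectors.
#' @param labels binary labels.
#' @return list with `aucA`, `aucB`, `var_diff`, `z`, `p`.
#' @export
delong_test <- function(scoresA, scoresB, labels) {
  if (length(scoresA) != length(scoresB) ||
      length(scoresA) != length(labels)) {
    stop("delong_test: scores and labels must be paired (equal length)",
         call. = FALSE)
  }
  dc <- delong_components(list(scoresA, scoresB), labels)
  var_diff <- dc$S[1, 1] + dc$S[2, 2] - 2 * dc$S[1, 2]
  d <- dc$aucs[1] - dc$aucs[2]
  if (var_diff <= 1e-15) {
    return(list(aucA = dc$aucs[1], aucB = dc$aucs[2], var_diff = 0,
                z = 0, p = 1))
  }
  z <- d / sqrt(var_diff)
  list(aucA = dc$aucs[1], aucB = dc$aucs[2], var_diff = var_diff,
       z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' AUC with a DeLong confidence interval (logit transform)
#'
#' @param scores numeric scores; @param labels binary labels.
#' @param conf confidence level.
#' @return list with `auc`, `ci_low`, `ci_high`, `se`.
#' @export
auc_ci_delong <- function(scores, labels, conf = 0.95) {
  dc <- delong_components(list(scores), labels)
  auc <- dc$aucs[1]
  se <- sqrt(dc$S[1, 1])
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  if (auc <= 0 || auc >= 1 || se == 0) {
    ## degenerate: fall back to clipped Wald
    return(list(auc = auc, ci_low = max(0, auc - zq * se),
                ci_high = min(1, auc + zq * se), se = se))
  }
  lg <- log(auc / (1 - auc))
  se_lg <- se / (auc * (1 - auc))
  lo <- lg - zq * se_lg; hi <- lg + zq * se_lg
  list(auc = auc, ci_low = 1 / (1 + exp(-lo)), ci_high = 1 / (1 + exp(-hi)),
       se = se)
}

#' McNemar exact test comparing two paired classifiers
#'
#' Exact two-sided binomial test on the discordant pairs: b = A correct and
#' B wrong, c = A wrong and B correct; p = min(1, 2 P(X <= min(b, c))) with
#' X ~ Binomial(b + c, 1/2).
#'
#' @param predsA,predsB paired binary predictions.
#' @param labels true binary labels.
#' @return list with `b`, `c`, `p`.
#' @export
mcnemar_test <- function(predsA, predsB, labels) {
  stopifnot(length(predsA) == length(predsB),
            length(predsA) == length(labels))
  okA <- as.integer(predsA) == as.integer(labels)
  okB <- as.integer(predsB) == as.integer(labels)
  b <- sum(okA & !okB); cc <- sum(!okA & okB)
  if (b + cc == 0) return(list(b = 0L, c = 0L, p = 1))
  p <- min(1, 2 * stats::pbinom(min(b, cc), b + cc, 0.5))
  list(b = b, c = cc, p = p)
}

#' Evaluate predictions (or scores + threshold) against labels
#'
#' Confusion counts with sensitivity, specificity, precision and accuracy,
#' each with an exact Clopper-Pearson 95% CI; when scores are supplied, also
#' the AUC with a DeLong CI.
#'
#' @param labels true binary labels.
#' @param predictions binary predictions, or NULL to derive them from
#'   `scores > threshold`.
#' @param scores optional numeric scores (for AUC).
#' @param threshold decision threshold applied to scores.
#' @param conf confidence level.
#' @return An object of class `model_eval`: confusion counts `tp`, `fp`,
#'   `tn`, `fn`; `sensitivity`, `specificity`, `precision`, `accuracy`
#'   (each a list with `value`, `ci_low`, `ci_high`, as proportions);
#'   `auc` (with CI) when scores are given; `threshold`.
#' @export
evaluate <- function(labels, predictions = NULL, scores = NULL,
                     threshold = NULL, conf = 0.95) {
  labels <- as.integer(labels)
  stopifnot(any(labels == 1L), any(labels == 0L))
  if (is.null(predictions)) {
    if (is.null(scores) || is.null(threshold)) {
      stop("evaluate: need predictions, or scores + threshold", call. = FALSE)
    }
    predictions <- as.integer(scores > threshold)
  }
  predictions <- as.integer(predictions)
  tp <- sum(predictions == 1L & labels == 1L)
  fp <- sum(predictions == 1L & labels == 0L)
  tn <- sum(predictions == 0L & labels == 0L)
  fn <- sum(predictions == 0L & labels == 1L)
  met <- function(k, n) {
    if (n == 0) return(list(value = NA_real_, ci_low = NA_real_,
                            ci_high = NA_real_, k = k, n = n))
    ci <- clopper_pearson(k, n, conf)
    list(value = k / n, ci_low = ci[["low"]], ci_high = ci[["high"]],
         k = k, n = n)
  }
  out <- list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = met(tp, tp + fn),
    specificity = met(tn, tn + fp),
    precision = met(tp, tp + fp),
    accuracy = met(tp + tn, tp + tn + fp + fn),
    threshold = threshold
  )
  if (!is.null(scores)) out$auc <- auc_ci_delong(scores, labels, conf)
  structure(out, class = "model_eval")
}

#' @export
print.model_eval <- function(x, ...) {
  pm <- function(m) sprintf("%.1f%% (%.1f-%.1f%%)", 100 * m$value,
                            100 * m$ci_low, 100 * m$ci_high)
  cat("<model_eval>\n")
  cat("  confusion  tp", x$tp, "fp", x$fp, "tn", x$tn, "fn", x$fn, "\n")
  cat("  sensitivity", pm(x$sensitivity), "\n")
  cat("  specificity", pm(x$specificity), "\n")
  cat("  precision  ", pm(x$precision), "\n")
  cat("  accuracy   ", pm(x$accuracy), "\n")
  if (!is.null(x$auc)) {
    cat(sprintf("  AUC         %.3f (%.3f-%.3f)\n", x$auc$auc,
                x$auc$ci_low, x$auc$ci_high))
  }
  invisible(x)
}

#' Permutation feature importance (AUC drop)
#'
#' Mean decrease in AUC over `n_repeats` shuffles of each feature column on
#' a validation table; uniform across all model types.
#'
#' @param scorer a [tune_and_train()] result (or any list with `score` and
#'   `features`).
#' @param validation validation feature table with `ploidy_binary`.
#' @param n_repeats shuffles per feature (default 20).
#' @param seed RNG seed.
#' @return data.frame sorted by decreasing `importance` with columns
#'   `feature`, `importance`, `sd`.
#' @export
feature_importance <- function(scorer, validation, n_repeats = 20L,
                               seed = 1L) {
  feats <- scorer$features
  base_auc <- auc_mann_whitney(scorer$score(validation),
                               validation$ploidy_binary)
  rng <- local_rng(seed)
  imp <- lapply(feats, function(f) {
    drops <- vapply(seq_len(n_repeats), function(r) {
      shuf <- validation
      shuf[[f]] <- shuf[[f]][order(rng$runif(nrow(shuf)))]
      base_auc - auc_mann_whitney(scorer$score(shuf), shuf$ploidy_binary)
    }, numeric(1))
    c(mean(drops), stats::sd(drops))
  })
  out <- data.frame(feature = feats,
                    importance = vapply(imp, `[`, numeric(1), 1),
                    sd = vapply(imp, `[`, numeric(1), 2))
  out[order(-out$importance), ]
}

#' Benchmark the six models over one or more split seeds
#'
#' For each seed: stratified 80/20 split, k-fold tuning on the training
#' portion, ROC threshold closest to (0, 1) on the training scores, and
#' evaluation on the held-out test set. Point metrics depend on the split
#' seed, so the harness reports the per-seed distribution rather than a
#' single value.
#'
#' @param table feature table with `ploidy_binary`.
#' @param models model names (default all six).
#' @param seeds integer vector of split seeds.
#' @param k cross-validation folds.
#' @param test_frac held-out fraction.
#' @return data.frame with one row per model x seed: threshold, confusion
#'   counts, the four proportion metrics with CIs, and AUC with CI.
#' @export
benchmark_models <- function(table, models = c("LR", "DT", "XGBoost", "RF",
                                               "SVM", "MLP"),
                             seeds = 1:5, k = 5L, test_frac = 0.2) {
  rows <- list()
  for (seed in seeds) {
    sp <- split_train_test(table, test_frac = test_frac, seed = seed)
    for (m in models) {
      sc <- tune_and_train(m, sp$train, k = k, seed = seed)
      thr <- roc_threshold(sc$score(sp$train), sp$train$ploidy_binary)
      ev <- evaluate(sp$test$ploidy_binary, scores = sc$score(sp$test),
                     threshold = thr)
      rows[[length(rows) + 1L]] <- data.frame(
        model = m, seed = seed, threshold = thr,
        tp = ev$tp, fp = ev$fp, tn = ev$tn, fn = ev$fn,
        sensitivity = ev$sensitivity$value,
        specificity = ev$specificity$value,
        precision = ev$precision$value,
        accuracy = ev$accuracy$value,
        accuracy_lo = ev$accuracy$ci_low, accuracy_hi = ev$accuracy$ci_high,
        auc = ev$auc$auc, auc_lo = ev$auc$ci_low, auc_hi = ev$auc$ci_high,
        cv_auc = sc$cv_auc)
    }
  }
  do.call(rbind, rows)
}
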