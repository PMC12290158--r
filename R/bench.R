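#' Model adapters
#'
#' An adapter is any pair of functions `fit(X, y) -> model` and
#' `predict(model, X) -> class-1 probabilities in [0, 1]`. The shipped
#' adapters are a (lightly ridge-stabilized) logistic regression and, when
#' the xgboost package is installed, a gradient-boosted tree model. Deep
#' networks are out of scope but pluggable through the same contract.
#'
#' @param name adapter label used in result tables.
#' @param fit function(features data.frame, labels) returning a fitted model.
#' @param predict function(model, features data.frame) returning scores.
#' @return A `model_adapter`.
#' @export
model_adapter <- function(name, fit, predict) {
  stopifnot(is.character(name), is.function(fit), is.function(predict))
  structure(list(name = name, fit = fit, predict = predict),
            class = "model_adapter")
}

#' @rdname model_adapter
#' @export
adapter_logistic <- function() {
  model_adapter("logistic",
    fit = function(X, y) {
      df <- cbind(X, .y = y)
      suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
    },
    predict = function(model, X) {
      clamp(as.numeric(stats::predict(model, newdata = X, type = "response")), 0, 1)
    })
}

#' @rdname model_adapter
#' @param nrounds,max_depth,eta xgboost hyperparameters.
#' @export
adapter_xgboost <- function(nrounds = 50, max_depth = 3, eta = 0.3) {
  if (!requireNamespace("xgboost", quietly = TRUE))
    stop_fairpost("the xgboost package is not installed", "fairpost_invalid_argument")
  model_adapter("xgboost",
    fit = function(X, y) {
      dtrain <- xgboost::xgb.DMatrix(as.matrix(X), label = y, nthread = 1)
      xgboost::xgb.train(params = list(objective = "binary:logistic",
                                       max_depth = max_depth, eta = eta,
                                       nthread = 1),
                         data = dtrain, nrounds = nrounds, verbose = 0)
    },
    predict = function(model, X) {
      d <- xgboost::xgb.DMatrix(as.matrix(X), nthread = 1)
      clamp(as.numeric(stats::predict(model, d)), 0, 1)
    })
}

# Stratified calibration split: indices (within `idx`) reserved for policy
# fitting, stratified by (class, group). Used only when calib_frac is set;
# by default policies are fit on the full training predictions, since at low
# unprivileged representation a held-out split leaves too few unprivileged
# rows to estimate group rates at all.
calib_split <- function(labels, group, idx, frac, seed) {
  strata <- interaction(labels[idx], group[idx], drop = TRUE)
  withr::with_seed(seed, {
    unlist(lapply(levels(strata), function(lev) {
      pool <- idx[strata == lev]
      pool <- pool[sample.int(length(pool))]
      pool[seq_len(max(1L, round_half_up(frac * length(pool))))]
    }), use.names = FALSE)
  })
}

metric_row <- function(score, y, group, labels) {
  gs <- grouped_scores(score, y, group, predicted_label = labels)
  tryCatch(suppressWarnings(fairness_report(gs)),
           fairpost_error = function(e)
             data.frame(acc = NA_real_, bacc = NA_real_, f1 = NA_real_,
                        eop = NA_real_, eod = NA_real_))
}

#' Run the cross-validated debiasing benchmark
#'
#' For every (dataset, treated protected attribute, model adapter, method,
#' fold): trains the model on the training portion of the fold (optionally
#' resampled to a target unprivileged-group rate — the test set always stays
#' the fold's full, untouched test split), fits each method's policy on a
#' held-out calibration share of the training data, applies it to the test
#' fold, and records fairness/performance reports both for the treated
#' attribute and for every untreated attribute. Randomized policies are
#' applied `draws` times and their metrics averaged.
#'
#' @param datasets named list of `tabular_dataset`s.
#' @param adapters named list of [model_adapter()]s.
#' @param methods character vector from [debias_methods()].
#' @param k folds (default 5).
#' @param seed master seed; folds, splits and policy draws use named
#'   substreams of it.
#' @param train_ugr optional target unprivileged-group rate applied to every
#'   training set (test folds are untouched).
#' @param calib_frac optional share of the training rows held out for policy
#'   fitting (stratified by class and group). The default, `NULL`, fits both
#'   the model and the policies on the full training set — at low
#'   unprivileged representation a further split leaves too few unprivileged
#'   rows for any group-rate estimate.
#' @param draws application draws averaged for randomized policies (default 10).
#' @param settings fit settings passed to [fit_context()].
#' @return A `bench_store`: list with `results` (long data.frame: dataset,
#'   attr_treated, attr_eval, model, method, fold, phase before/after, the
#'   five metrics), `policies` (serialized policies per run), and `meta`.
#' @export
run_benchmark <- function(datasets, adapters = list(logistic = adapter_logistic()),
                          methods = c("identity", "roc", "psta"),
                          k = 5L, seed = 1L, train_ugr = NULL,
                          calib_frac = NULL, draws = 10L, settings = list()) {
  stopifnot(is.list(datasets), length(datasets) > 0)
  if (is.null(names(datasets)) || any(!nzchar(names(datasets))))
    stop_fairpost("datasets must be a named list", "fairpost_invalid_argument")
  methods <- vapply(methods, function(m) match.arg(m, debias_methods()), character(1))
  results <- list(); policies <- list()
  for (ds_name in names(datasets)) {
    ds <- datasets[[ds_name]]
    folds <- make_cv_folds(ds, k = k, seed = substream_seed(seed, paste0("folds-", ds_name)))
    for (fold_i in seq_len(k)) {
      test_idx <- folds[[fold_i]]
      train_idx <- setdiff(seq_len(dataset_n(ds)), test_idx)
      train <- dataset_subset(ds, train_idx)
      if (!is.null(train_ugr)) {
        plan <- plan_ugr(train, train_ugr)
        if (!plan$feasible)
          stop_fairpost("train_ugr infeasible on a training fold", "fairpost_precondition_error")
        train <- resample_to_ugr(train, list(plan),
                                 seed = substream_seed(seed, paste0("ugr-", ds_name, "-", fold_i)))[[1]]
      }
      if (is.null(calib_frac)) {
        cal_pos <- fit_pos <- seq_len(dataset_n(train))
      } else {
        cal_pos <- calib_split(train$labels, train$protected[[1]],
                               seq_len(dataset_n(train)), calib_frac,
                               substream_seed(seed, paste0("calib-", ds_name, "-", fold_i)))
        fit_pos <- setdiff(seq_len(dataset_n(train)), cal_pos)
      }
      for (ad_name in names(adapters)) {
        ad <- adapters[[ad_name]]
        model <- ad$fit(train$features[fit_pos, , drop = FALSE], train$labels[fit_pos])
        score_cal <- ad$predict(model, train$features[cal_pos, , drop = FALSE])
        score_test <- ad$predict(model, ds$features[test_idx, , drop = FALSE])
        if (any(!is.finite(score_cal)) || any(score_cal < 0 | score_cal > 1) ||
            any(!is.finite(score_test)) || any(score_test < 0 | score_test > 1))
          stop_fairpost(sprintf("adapter '%s' emitted scores outside [0, 1]", ad_name),
                        "fairpost_adapter_error")
        y_test <- ds$labels[test_idx]
        base_labels <- threshold_labels(score_test)
        for (attr_t in names(ds$protected)) {
          ctx <- fit_context(score_cal, train$labels[cal_pos],
                             train$protected[[attr_t]][cal_pos],
                             features = as.matrix(train$features[cal_pos, , drop = FALSE]),
                             settings = utils::modifyList(settings,
                               list(seed = substream_seed(seed, paste0("policy-", ds_name, "-", fold_i, "-", attr_t)))))
          for (attr_e in names(ds$protected)) {
            results[[length(results) + 1]] <- cbind(
              data.frame(dataset = ds_name, attr_treated = attr_t,
                         attr_eval = attr_e, model = ad_name,
                         method = "baseline", fold = fold_i, phase = "before"),
              metric_row(score_test, y_test, ds$protected[[attr_e]][test_idx], base_labels))
          }
          for (method in methods) {
            pol <- fit_policy(method, ctx)
            n_draws <- if (is_randomized_policy(pol)) draws else 1L
            gs_test <- grouped_scores(score_test, y_test,
                                      ds$protected[[attr_t]][test_idx])
            feats_test <- as.matrix(ds$features[test_idx, , drop = FALSE])
            reps <- lapply(seq_len(n_draws), function(d) {
              lab <- apply_policy(pol, gs_test,
                                  seed = substream_seed(pol$seed, paste0("draw-", d)),
                                  features = feats_test)
              lapply(names(ds$protected), function(attr_e)
                metric_row(score_test, y_test, ds$protected[[attr_e]][test_idx], lab))
            })
            for (ei in seq_along(names(ds$protected))) {
              avg <- Reduce(`+`, lapply(reps, `[[`, ei)) / n_draws
              results[[length(results) + 1]] <- cbind(
                data.frame(dataset = ds_name, attr_treated = attr_t,
                           attr_eval = names(ds$protected)[ei], model = ad_name,
                           method = method, fold = fold_i, phase = "after"),
                avg)
            }
            policies[[length(policies) + 1]] <- data.frame(
              dataset = ds_name, attr = attr_t, model = ad_name,
              method = method, fold = fold_i,
              policy = as.character(policy_to_json(pol)))
          }
        }
      }
    }
  }
  structure(list(results = do.call(rbind, results),
                 policies = do.call(rbind, policies),
                 meta = list(seed = seed, k = k, methods = methods,
                             train_ugr = train_ugr, calib_frac = calib_frac,
                             draws = draws)),
            class = "bench_store")
}

store_metrics <- function() c("acc", "bacc", "f1", "eop", "eod")

# Pair each after-row with its before-row from the same (dataset, attrs,
# model, fold). Returns long data.frame with before/after/delta per metric.
paired_changes <- function(store) {
  res <- store$results
  before <- res[res$phase == "before", ]
  after <- res[res$phase == "after", ]
  key <- function(d) paste(d$dataset, d$attr_treated, d$attr_eval, d$model, d$fold, sep = "\r")
  bmap <- before[match(key(after), key(before)), store_metrics()]
  out <- do.call(rbind, lapply(store_metrics(), function(m) {
    data.frame(dataset = after$dataset, attr_treated = after$attr_treated,
               attr_eval = after$attr_eval, model = after$model,
               method = after$method, fold = after$fold, metric = m,
               before = bmap[[m]], after = after[[m]],
               delta = after[[m]] - bmap[[m]])
  }))
  rownames(out) <- NULL
  out
}

#' Absolute and relative change table
#'
#' Mean absolute change (after minus before) and mean relative change (in
#' percent of the baseline value) per method and metric, computed from the
#' same paired runs. Negative values mean decline for performance metrics
#' and improvement for fairness metrics. Relative changes whose baseline
#' magnitude is below `min_baseline` are excluded from the relative mean and
#' counted.
#'
#' @param store a `bench_store` from [run_benchmark()].
#' @param min_baseline exclusion threshold for relative-change denominators
#'   (default 1e-6).
#' @param treated_only restrict to rows where the evaluated attribute is the
#'   treated one (default TRUE).
#' @return A `change_table` data.frame: method, metric, abs_change,
#'   rel_change_pct, n, n_rel_excluded.
#' @export
change_table <- function(store, min_baseline = 1e-6, treated_only = TRUE) {
  pc <- paired_changes(store)
  if (treated_only) pc <- pc[pc$attr_eval == pc$attr_treated, ]
  pc <- pc[stats::complete.cases(pc[, c("before", "after")]), ]
  out <- do.call(rbind, lapply(split(pc, list(pc$method, pc$metric), drop = TRUE),
    function(d) {
      rel_ok <- abs(d$before) >= min_baseline
      data.frame(method = d$method[1], metric = d$metric[1],
                 abs_change = mean(d$delta),
                 rel_change_pct = if (any(rel_ok))
                   mean(100 * d$delta[rel_ok] / d$before[rel_ok]) else NA_real_,
                 n = nrow(d), n_rel_excluded = sum(!rel_ok))
    }))
  rownames(out) <- NULL
  class(out) <- c("change_table", "data.frame")
  out
}

#' Categorize class and attribute imbalance
#'
#' Interval maps: favorable class proportion (FCP) in [0, 0.25) is low,
#' [0.25, 0.75) medium, [0.75, 1] high class imbalance level; unprivileged
#' group rate (UGR) in [0, 0.20) is low, [0.20, 0.50) medium, [0.50, 1] high
#' representation.
#'
#' @param fcp favorable class proportion in [0, 1].
#' @param ugr unprivileged group rate in [0, 1].
#' @return List with `fcp`, `ugr`, `class_level`, `attr_level`.
#' @export
categorize_imbalance <- function(fcp, ugr) {
  if (!is.finite(fcp) || !is.finite(ugr) || fcp < 0 || fcp > 1 || ugr < 0 || ugr > 1)
    stop_fairpost("fcp and ugr must lie in [0, 1]", "fairpost_invalid_argument")
  class_level <- if (fcp < 0.25) "low" else if (fcp < 0.75) "medium" else "high"
  attr_level <- if (ugr < 0.20) "low" else if (ugr < 0.50) "medium" else "high"
  list(fcp = fcp, ugr = ugr, class_level = class_level, attr_level = attr_level)
}

#' Impact of debiasing on untreated protected attributes
#'
#' For every (dataset, treated attribute, untreated attribute, method,
#' fairness metric) case, compares the untreated attribute's fairness metric
#' before vs after debiasing across folds and models: mean change, direction,
#' and a large-effect flag from Cliff's delta on the paired fold-level
#' values.
#'
#' @param store a `bench_store`.
#' @param metrics fairness metrics to assess (default eop, eod).
#' @param tol changes smaller than this count as unchanged (default 1e-12).
#' @return List with `cases` (one row per case) and `summary` (per method and
#'   metric: proportions of cases with increased / decreased / unchanged
#'   disparity and with a significant, large-effect increase or decrease).
#' @export
untreated_impact <- function(store, metrics = c("eop", "eod"), tol = 1e-12) {
  pc <- paired_changes(store)
  pc <- pc[pc$attr_eval != pc$attr_treated & pc$metric %in% metrics, ]
  if (!nrow(pc))
    stop_fairpost("store contains no multi-attribute dataset runs",
                  "fairpost_invalid_argument")
  pc <- pc[stats::complete.cases(pc[, c("before", "after")]), ]
  keys <- list(pc$dataset, pc$attr_treated, pc$attr_eval, pc$method, pc$metric)
  cases <- do.call(rbind, lapply(split(pc, keys, drop = TRUE), function(d) {
    delta <- mean(d$delta)
    cd <- cliffs_delta(d$after, d$before)
    data.frame(dataset = d$dataset[1], attr_treated = d$attr_treated[1],
               attr_eval = d$attr_eval[1], method = d$method[1],
               metric = d$metric[1], mean_delta = delta,
               direction = if (abs(delta) <= tol) "unchanged"
                           else if (delta > 0) "increased" else "decreased",
               cliffs = cd$delta, large_effect = cd$large)
  }))
  rownames(cases) <- NULL
  summary <- do.call(rbind, lapply(split(cases, list(cases$method, cases$metric), drop = TRUE),
    function(d) data.frame(
      method = d$method[1], metric = d$metric[1], n_cases = nrow(d),
      prop_increased = mean(d$direction == "increased"),
      prop_decreased = mean(d$direction == "decreased"),
      prop_unchanged = mean(d$direction == "unchanged"),
      prop_sig_increase = mean(d$direction == "increased" & d$large_effect),
      prop_sig_decrease = mean(d$direction == "decreased" & d$large_effect))))
  rownames(summary) <- NULL
  list(cases = cases, summary = summary)
}

#' Correlate attribute correlations with untreated-attribute harm
#'
#' Tests, per method, whether the Spearman correlation between the treated
#' and untreated attribute predicts the proportion of runs in which the
#' method worsened the untreated attribute's fairness. Strong negative
#' coefficients indicate that inversely correlated attributes drive the
#' unintended fairness shifts.
#'
#' @param impact result of [untreated_impact()].
#' @param correlations data.frame with columns dataset, attr_treated,
#'   attr_eval, rho (e.g. built from [spearman_attr_corr()] per dataset).
#' @param min_cases minimum cases per method (default 3).
#' @return Data.frame per method and metric: Pearson coefficient, p-value,
#'   n_cases, and a `defined` flag (FALSE when there are too few cases or a
#'   constant vector).
#' @export
correlation_vs_impact <- function(impact, correlations, min_cases = 3L) {
  cases <- merge(impact$cases, correlations,
                 by = c("dataset", "attr_treated", "attr_eval"))
  worse <- as.numeric(cases$direction == "increased")
  cases$worse <- worse
  do.call(rbind, lapply(split(cases, list(cases$method, cases$metric), drop = TRUE),
    function(d) {
      ok <- nrow(d) >= min_cases && stats::sd(d$worse) > 0 && stats::sd(d$rho) > 0
      if (ok) {
        ct <- stats::cor.test(d$rho, d$worse)
        data.frame(method = d$method[1], metric = d$metric[1],
                   corr = unname(ct$estimate), p_value = ct$p.value,
                   n_cases = nrow(d), defined = TRUE)
      } else {
        data.frame(method = d$method[1], metric = d$metric[1],
                   corr = NA_real_, p_value = NA_real_,
                   n_cases = nrow(d), defined = FALSE)
      }
    }))
}

#' Proportion of cases beating the trade-off baseline
#'
#' A case is one (dataset, treated attribute, model, fairness metric,
#' performance metric) combination; its point is the mean after-debiasing
#' (fairness, performance) across folds, and it beats the baseline when it
#' falls in the win-win or good trade-off regions.
#'
#' @param store a `bench_store`.
#' @param baselines named list of [build_baseline()] results keyed
#'   `"dataset|attr|model|fairness|perf"`.
#' @param healthcare_only count only the stricter good-2.2 sub-region (and
#'   win-win) as beating the baseline (default FALSE).
#' @return Data.frame per method: `prop_over`, `n_cases`, `n_skipped`
#'   (cases without a baseline).
#' @export
proportion_over_baseline <- function(store, baselines, healthcare_only = FALSE) {
  pc <- paired_changes(store)
  pc <- pc[pc$attr_eval == pc$attr_treated, ]
  out <- list()
  for (method in setdiff(unique(pc$method), "baseline")) {
    hits <- 0L; n_cases <- 0L; skipped <- 0L
    d <- pc[pc$method == method, ]
    for (key in unique(paste(d$dataset, d$attr_treated, d$model, sep = "|"))) {
      parts <- strsplit(key, "|", fixed = TRUE)[[1]]
      dd <- d[d$dataset == parts[1] & d$attr_treated == parts[2] & d$model == parts[3], ]
      for (bl_key in names(baselines)) {
        bp <- strsplit(bl_key, "|", fixed = TRUE)[[1]]
        if (!identical(bp[1:3], parts)) next
        bl <- baselines[[bl_key]]
        fvals <- dd$after[dd$metric == bl$fairness]
        pvals <- dd$after[dd$metric == bl$perf]
        if (!length(fvals) || !length(pvals)) { skipped <- skipped + 1L; next }
        oc <- classify_region(c(fairness = mean(fvals, na.rm = TRUE),
                                performance = mean(pvals, na.rm = TRUE)), bl)
        good <- if (healthcare_only) c("win-win", "good-2.2")
                else c("win-win", "good-2.1", "good-2.2")
        n_cases <- n_cases + 1L
        if (oc$region %in% good) hits <- hits + 1L
      }
    }
    out[[method]] <- data.frame(method = method,
                                prop_over = if (n_cases) hits / n_cases else NA_real_,
                                n_cases = n_cases, n_skipped = skipped)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
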