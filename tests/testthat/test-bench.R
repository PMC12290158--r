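# Minimal hand-built store for the summary-table arithmetic tests.
mk_store <- function(rows) {
  structure(list(results = rows, policies = NULL, meta = list()),
            class = "bench_store")
}

row_df <- function(dataset, attr_t, attr_e, model, method, fold, phase,
                   eop = NA, eod = NA, acc = NA, bacc = NA, f1 = NA) {
  data.frame(dataset = dataset, attr_treated = attr_t, attr_eval = attr_e,
             model = model, method = method, fold = fold, phase = phase,
             acc = acc, bacc = bacc, f1 = f1, eop = eop, eod = eod)
}

baseline_fixture_bench <- function(seed = 2, n = 200) {
  dat <- withr::with_seed(seed, {
    g <- rep(0:1, each = n / 2)
    y <- rbinom(n, 1, 0.45)
    s <- pmin(pmax(0.3 + 0.35 * y + 0.15 * g + rnorm(n, 0, 0.2), 0.01), 0.99)
    list(s = s, y = y, g = g)
  })
  grouped_scores(dat$s, dat$y, dat$g, predicted_label = threshold_labels(dat$s))
}

test_that("the identity method leaves every metric unchanged", {
  ds <- simulate_dataset(synth_config(s = 0, n_per_class = 150, seed = 6))
  store <- run_benchmark(list(synth = ds), methods = "identity", k = 3, seed = 2)
  pc <- fairpost:::paired_changes(store)
  expect_true(all(abs(pc$delta) < 1e-12))
})

test_that("benchmark runs are bit-identical under the same seed", {
  ds <- simulate_dataset(synth_config(s = 0, n_per_class = 150, seed = 6))
  s1 <- run_benchmark(list(synth = ds), methods = c("identity", "psta"), k = 3, seed = 2)
  s2 <- run_benchmark(list(synth = ds), methods = c("identity", "psta"), k = 3, seed = 2)
  expect_identical(s1$results, s2$results)
  expect_identical(s1$policies, s2$policies)
  # held-out calibration split protocol is reproducible too
  s3 <- run_benchmark(list(synth = ds), methods = "psta", k = 3, seed = 2,
                      calib_frac = 0.25)
  s4 <- run_benchmark(list(synth = ds), methods = "psta", k = 3, seed = 2,
                      calib_frac = 0.25)
  expect_identical(s3$results, s4$results)
  expect_false(identical(s3$policies$policy, s1$policies$policy[s1$policies$method == "psta"]))
})

test_that("the gradient-boosted adapter honours the score contract", {
  ds <- simulate_dataset(synth_config(s = 1, n_per_class = 100, seed = 3))
  ad <- adapter_xgboost(nrounds = 10)
  mod <- ad$fit(ds$features, ds$labels)
  sc <- ad$predict(mod, ds$features)
  expect_true(all(sc >= 0 & sc <= 1))
  expect_gt(mean((sc >= 0.5) == ds$labels), 0.8)
})

test_that("change_table computes paired absolute and relative changes", {
  rows <- rbind(
    row_df("d", "A", "A", "m", "baseline", 1, "before", eop = 0.2),
    row_df("d", "A", "A", "m", "meth", 1, "after", eop = 0.1))
  ct <- change_table(mk_store(rows))
  ct <- ct[ct$metric == "eop", ]
  expect_equal(ct$abs_change, -0.1)
  expect_equal(ct$rel_change_pct, -50)

  # near-zero baselines are excluded from the relative mean, with a count
  rows2 <- rbind(
    row_df("d", "A", "A", "m", "baseline", 1, "before", eop = 0),
    row_df("d", "A", "A", "m", "meth", 1, "after", eop = 0.1))
  ct2 <- change_table(mk_store(rows2))
  ct2 <- ct2[ct2$metric == "eop", ]
  expect_true(is.na(ct2$rel_change_pct))
  expect_equal(ct2$n_rel_excluded, 1L)
})

test_that("separate averaging of absolute and relative changes can invert rankings", {
  rows <- rbind(
    row_df("d1", "A", "A", "m", "baseline", 1, "before", eop = 0.5),
    row_df("d1", "A", "A", "m", "methX", 1, "after", eop = 0.4),    # -0.1, -20%
    row_df("d2", "A", "A", "m", "baseline", 1, "before", eop = 0.01),
    row_df("d2", "A", "A", "m", "methX", 1, "after", eop = 0.009),  # -0.001, -10%
    row_df("d1", "A", "A", "m", "methZ", 1, "after", eop = 0.46),   # -0.04, -8%
    row_df("d2", "A", "A", "m", "methZ", 1, "after", eop = 0.006))  # -0.004, -40%
  ct <- change_table(mk_store(rows))
  x <- ct[ct$method == "methX" & ct$metric == "eop", ]
  z <- ct[ct$method == "methZ" & ct$metric == "eop", ]
  expect_lt(x$abs_change, z$abs_change)        # X wins on absolute change
  expect_lt(z$rel_change_pct, x$rel_change_pct) # Z wins on relative change
})

test_that("imbalance categorization follows the printed interval maps", {
  expect_equal(categorize_imbalance(0.5, 0.19)$attr_level, "low")
  expect_equal(categorize_imbalance(0.5, 0.20)$attr_level, "medium")
  expect_equal(categorize_imbalance(0.5, 0.50)$attr_level, "high")
  expect_equal(categorize_imbalance(0.25, 0.5)$class_level, "medium")
  expect_equal(categorize_imbalance(0.24, 0.5)$class_level, "low")
  expect_equal(categorize_imbalance(0.75, 0.5)$class_level, "high")
  expect_equal(categorize_imbalance(0, 0)$class_level, "low")
  expect_equal(categorize_imbalance(1, 1)$attr_level, "high")
  expect_error(categorize_imbalance(1.1, 0.5), class = "fairpost_invalid_argument")
})

test_that("untreated-attribute impact detects spillover between correlated attributes", {
  ds <- simulate_dataset(synth_config(s = 0, n_per_class = 400, seed = 8))
  # a duplicate attribute moves exactly with the treated one; the second
  # attribute is negatively correlated with A and its unprivileged group is
  # the low-score stratum of A's privileged group — the intersectional
  # pattern under which group-specific adjustments for A bypass (or harm)
  # negB's unprivileged members
  ds$protected$dup <- ds$protected$A
  med <- stats::median(ds$features$x1[ds$protected$A == 1])
  ds$protected$negB <- ifelse(ds$protected$A == 0L, 1L,
                              as.integer(ds$features$x1 > med))
  expect_lt(stats::cor(ds$protected$A, ds$protected$negB), -0.3)
  store <- run_benchmark(list(synth = ds), methods = c("identity", "psta"),
                         k = 5, seed = 4)
  imp <- untreated_impact(store)

  # identity policy: every untreated case is unchanged
  id_sum <- imp$summary[imp$summary$method == "identity", ]
  expect_true(all(id_sum$prop_unchanged == 1))
  expect_true(all(id_sum$prop_increased == 0))

  # duplicated attribute mirrors the treated one exactly
  dup_case <- fairpost:::paired_changes(store)
  dup_case <- dup_case[dup_case$method == "psta" & dup_case$metric == "eop", ]
  treated <- dup_case[dup_case$attr_treated == "A" & dup_case$attr_eval == "A", ]
  mirrored <- dup_case[dup_case$attr_treated == "A" & dup_case$attr_eval == "dup", ]
  expect_equal(mirrored$delta[order(mirrored$fold)], treated$delta[order(treated$fold)])

  # group-threshold debiasing of A worsens fairness for the anti-correlated
  # attribute in at least some cases
  psta_cases <- imp$cases[imp$cases$method == "psta" &
                          imp$cases$attr_treated == "A" &
                          imp$cases$attr_eval == "negB", ]
  expect_gt(sum(psta_cases$direction == "increased"), 0)
})

test_that("correlation_vs_impact recovers planted monotone relations", {
  mk_cases <- function(rhos, props, method = "m1") {
    n <- length(rhos)
    data.frame(dataset = paste0("d", seq_len(n)), attr_treated = "A",
               attr_eval = "B", method = method, metric = "eop",
               mean_delta = ifelse(props > 0.5, 0.1, -0.1),
               direction = ifelse(props > 0.5, "increased", "decreased"),
               cliffs = 0, large_effect = FALSE)
  }
  rhos <- seq(-0.9, 0.9, length.out = 13)
  props <- as.numeric(rhos < 0)   # worsening exactly when negatively correlated
  impact <- list(cases = mk_cases(rhos, props))
  corr <- data.frame(dataset = paste0("d", 1:13), attr_treated = "A",
                     attr_eval = "B", rho = rhos)
  res <- correlation_vs_impact(impact, corr)
  expect_true(res$defined[1])
  expect_lt(res$corr[1], -0.8)    # strong negative relation recovered

  # constant worsening proportions are flagged undefined
  impact2 <- list(cases = mk_cases(rhos, rep(1, 13)))
  res2 <- correlation_vs_impact(impact2, corr)
  expect_false(res2$defined[1])
  expect_true(is.na(res2$corr[1]))

  # too few cases are flagged undefined
  impact3 <- list(cases = mk_cases(rhos[1:2], props[1:2]))
  res3 <- correlation_vs_impact(impact3, corr[1:2, ])
  expect_false(res3$defined[1])
})

test_that("proportion over baseline counts win-win and good cases", {
  # constructed four-case store: two clear wins, one poor, one lose-lose
  rows <- do.call(rbind, lapply(1:4, function(i) rbind(
    row_df(paste0("d", i), "A", "A", "m", "baseline", 1, "before",
           eop = 0.3, acc = 0.8),
    row_df(paste0("d", i), "A", "A", "m", "meth", 1, "after",
           eop = c(0.1, 0.05, 0.25, 0.4)[i],
           acc = c(0.85, 0.82, 0.3, 0.7)[i]))))
  store <- mk_store(rows)
  gs <- baseline_fixture_bench()
  bl <- build_baseline(gs, n_trials = 10, seed = 5, fairness = "eop", perf = "acc")
  bl$origin <- c(fairness = 0.3, performance = 0.8)
  baselines <- setNames(rep(list(bl), 4),
                        paste0("d", 1:4, "|A|m|eop|acc"))
  res <- proportion_over_baseline(store, baselines)
  expect_equal(res$prop_over[res$method == "meth"], 0.5)
  expect_equal(res$n_cases[res$method == "meth"], 4L)

  # identity deltas never beat the baseline (no strict fairness improvement)
  rows_id <- rbind(
    row_df("d1", "A", "A", "m", "baseline", 1, "before", eop = 0.3, acc = 0.8),
    row_df("d1", "A", "A", "m", "identity", 1, "after", eop = 0.3, acc = 0.8))
  res_id <- proportion_over_baseline(mk_store(rows_id), baselines)
  expect_equal(res_id$prop_over[res_id$method == "identity"], 0)
})
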