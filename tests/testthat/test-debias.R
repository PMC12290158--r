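test_that("fit_context rejects degenerate validation sets", {
  expect_error(fit_context(c(0.6, 0.4), c(1, 0), c(1, 1)),
               class = "fairpost_fit_error")
  expect_error(fit_context(c(0.6, 0.6, 0.4), c(1, 1, 0), c(0, 1, 1)),
               class = "fairpost_fit_error")
})

test_that("calibrated mixing (CPP) equalizes the false-negative cost", {
  # groups already FNR-equal: identity mixing
  s <- c(0.8, 0.6, 0.3, 0.2, 0.8, 0.6, 0.3, 0.2)
  y <- c(1, 1, 0, 0, 1, 1, 0, 0)
  g <- rep(0:1, each = 4)
  pol <- fit_cpp(fit_context(s, y, g))
  expect_equal(pol$params$p, c(0, 0))

  # closed-form mixing rate matches the exhaustive grid oracle
  ctx <- toy_ctx(seed = 7)
  pol <- fit_cpp(ctx)
  p_oracle <- oracle_cpp_p(ctx$score, ctx$true_label, ctx$group)
  expect_lte(max(abs(pol$params$p - p_oracle)), 0.01 + 1e-9)
  # base-rate constants are the group favorable rates
  for (gr in 0:1)
    expect_equal(pol$params$const[gr + 1],
                 mean(ctx$true_label[ctx$group == gr] == 1))
})

test_that("equalized-odds flipping (EPP) satisfies its constraints optimally", {
  # classifier already satisfying equalized odds: no flips
  s <- rep(c(0.8, 0.8, 0.2, 0.3, 0.3, 0.7), 2)
  y <- rep(c(1, 1, 1, 0, 0, 0), 2)
  g <- rep(0:1, each = 6)
  pol <- fit_epp(fit_context(s, y, g))
  expect_equal(policy_flat_rates(pol), c(0, 1, 0, 1))

  for (seed in c(7, 21)) {
    ctx <- toy_ctx(seed = seed)
    pol <- fit_epp(ctx)
    # analytic post-policy rates are equalized to numerical precision
    conf <- confusion_by_group(grouped_scores(
      ctx$score, ctx$true_label, ctx$group, threshold_labels(ctx$score)))
    rates <- expected_group_rates(pol, conf)
    expect_lte(abs(rates$tpr[1] - rates$tpr[2]), 1e-6)
    expect_lte(abs(rates$fpr[1] - rates$fpr[2]), 1e-6)
    # no feasible grid point does better than the vertex-enumeration optimum
    terms <- oracle_flip_terms(ctx$score, ctx$true_label, ctx$group)
    impl_err <- terms$err(policy_flat_rates(pol))
    expect_lte(impl_err,
               oracle_epp_best_err(ctx$score, ctx$true_label, ctx$group) + 1e-9)
  }
})

test_that("reject-option margin (ROC) matches the exhaustive margin scan", {
  ctx <- toy_ctx(seed = 7)
  pol <- fit_roc(ctx)
  m_oracle <- oracle_roc_margin(ctx$score, ctx$true_label, ctx$group,
                                ctx$settings$roc_margin_grid,
                                ctx$settings$eop_band)
  expect_equal(pol$params$margin, m_oracle)

  # EOp already inside the band: zero margin (identity behaviour)
  s <- rep(c(0.9, 0.8, 0.2, 0.1), 2)
  y <- rep(c(1, 1, 0, 0), 2)
  g <- rep(0:1, each = 4)
  fair <- fit_roc(fit_context(s, y, g))
  expect_equal(fair$params$margin, 0)
})

test_that("sensitivity-guided threshold (PSTA) matches the brute-force search", {
  for (seed in c(7, 13, 29)) {
    ctx <- toy_ctx(seed = seed)
    pol <- fit_psta(ctx)
    expect_equal(pol$params$theta1, 0.5)
    expect_equal(pol$params$theta0,
                 oracle_psta_theta(ctx$score, ctx$true_label, ctx$group))
  }
  # equal group TPRs: stays at 0.5
  s <- rep(c(0.9, 0.8, 0.2, 0.1), 2)
  y <- rep(c(1, 1, 0, 0), 2)
  g <- rep(0:1, each = 4)
  expect_equal(fit_psta(fit_context(s, y, g))$params$theta0, 0.5)
  # lowering the unprivileged threshold never decreases unprivileged TPR
  ctx <- toy_ctx(seed = 7)
  ths <- seq(0.9, 0.1, by = -0.1)
  tprs <- sapply(ths, function(th) {
    sel <- ctx$group == 0 & ctx$true_label == 1
    mean(ctx$score[sel] >= th)
  })
  expect_true(all(diff(tprs) >= 0))
})

test_that("confusion-tensor flipping (FACT) beats a dense probability grid", {
  for (lam in c(1, 0.2)) {
    ctx <- toy_ctx(seed = 7, settings = list(fact_lambda = lam))
    pol <- fit_fact(ctx)
    terms <- oracle_flip_terms(ctx$score, ctx$true_label, ctx$group)
    x <- policy_flat_rates(pol)
    impl_obj <- terms$err(x) + lam * abs(sum(terms$dT * x))
    grid_obj <- oracle_fact_best_obj(ctx$score, ctx$true_label, ctx$group, lam)
    expect_lte(impl_obj, grid_obj + 1e-9)
  }
  # vanishing fairness weight recovers the accuracy-optimal identity policy
  ctx0 <- toy_ctx(seed = 7, settings = list(fact_lambda = 0))
  expect_equal(policy_flat_rates(fit_fact(ctx0)), c(0, 1, 0, 1))
})

test_that("group thresholds (GSTAR) reach the exhaustive 2-D scan optimum", {
  for (lam in c(1, 0)) {
    ctx <- toy_ctx(seed = 7, n = 80, settings = list(gstar_lambda = lam))
    pol <- fit_gstar(ctx)
    obj <- oracle_gstar_objective(ctx$score, ctx$true_label, ctx$group, lam)
    impl <- obj(pol$params$theta0, pol$params$theta1)
    brute <- oracle_gstar_best(ctx$score, ctx$true_label, ctx$group, lam)
    expect_lte(impl, brute + 1e-6)
  }
  # identical group score distributions: symmetric thresholds
  dat <- withr::with_seed(5, {
    s1 <- pmin(pmax(c(runif(20, 0.4, 0.95), runif(20, 0.05, 0.6)), 0), 1)
    list(s = c(s1, s1), y = rep(rep(c(1, 0), each = 20), 2))
  })
  pol <- fit_gstar(fit_context(dat$s, dat$y, rep(0:1, each = 40)))
  expect_equal(pol$params$theta0, pol$params$theta1, tolerance = 1e-6)
})

test_that("multiaccuracy boosting (MAB) corrects a planted subgroup bias", {
  d <- planted_bias_data(seed = 9)
  X <- cbind(x = d$x)
  ctx <- fit_context(d$score, d$y, as.integer(d$x > 0.5), features = X,
                     settings = list(mab_eta = 0.5, mab_rounds = 300,
                                     mab_alpha = 0.01))
  pol <- fit_mab(ctx)
  expect_gt(length(pol$params$rounds), 0)
  corrected <- fairpost:::correct_scores(pol, d$score, X)
  sub <- d$x > 0
  expect_gt(abs(mean(d$y[sub] - d$score[sub])), 0.25)    # planted bias visible
  expect_lt(abs(mean(d$y[sub] - corrected[sub])), 0.05)  # removed after fitting

  # perfectly calibrated scores need no rounds
  cal <- fit_context(pmin(pmax(as.numeric(d$y), 0.01), 0.99), d$y,
                     as.integer(d$x > 0), features = X)
  expect_length(fit_mab(cal)$params$rounds, 0)
})

test_that("the auditor never sees the protected attribute", {
  d <- planted_bias_data(seed = 9)
  X <- cbind(x = d$x)
  g1 <- as.integer(d$x > 0.5)
  g2 <- withr::with_seed(1, sample(g1))   # scrambled groups, same cells
  mk <- function(g) fit_context(d$score, d$y, g, features = X,
                                settings = list(mab_eta = 0.5, mab_rounds = 50,
                                                mab_alpha = 0.01))
  expect_identical(policy_to_json(fit_mab(mk(g1))), policy_to_json(fit_mab(mk(g2))))
})

test_that("fairness-targeting methods improve their objective on held-out folds", {
  ds <- simulate_dataset(synth_config(s = 0, n_per_class = 500, seed = 2))
  folds <- make_cv_folds(ds, k = 5, seed = 4)
  wins <- list(epp = 0, roc = 0, psta = 0, gstar = 0)
  for (fi in 1:5) {
    test_idx <- folds[[fi]]
    tr <- dataset_subset(ds, setdiff(seq_len(dataset_n(ds)), test_idx))
    ad <- adapter_logistic()
    mod <- ad$fit(tr$features, tr$labels)
    ctx <- fit_context(ad$predict(mod, tr$features), tr$labels, tr$protected$A)
    s_te <- ad$predict(mod, ds$features[test_idx, ])
    gs <- grouped_scores(s_te, ds$labels[test_idx], ds$protected$A[test_idx])
    gs$predicted_label <- threshold_labels(s_te)
    base <- list(eop = eop(confusion_by_group(gs)), eod = eod(confusion_by_group(gs)))
    target <- c(epp = "eod", roc = "eop", psta = "eop", gstar = "eod")
    for (m in names(wins)) {
      pol <- fit_policy(m, ctx)
      gs$predicted_label <- apply_policy(pol, gs, seed = 8)
      conf <- confusion_by_group(gs)
      val <- if (target[[m]] == "eop") eop(conf) else eod(conf)
      if (val < base[[target[[m]]]]) wins[[m]] <- wins[[m]] + 1
    }
  }
  for (m in names(wins)) expect_gte(wins[[m]], 4)
})
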