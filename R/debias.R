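#' Validation context for fitting a decision policy
#'
#' Every debiasing method is fit on a held-out calibration set of scored
#' instances: scores, true labels and group membership (plus raw features for
#' the auditor-based method, which never receives the group). The context
#' checks the non-degeneracy every optimizer needs: each (group, class) cell
#' must be non-empty.
#'
#' @param score class-1 probabilities in [0, 1].
#' @param true_label vector in \{0, 1\}.
#' @param group vector in \{0, 1\}; 0 = unprivileged.
#' @param features optional numeric matrix (required by [fit_mab()]).
#' @param settings named list overriding [default_fit_settings()].
#' @return A `fit_context`.
#' @export
fit_context <- function(score, true_label, group, features = NULL,
                        settings = list()) {
  gs <- grouped_scores(score, true_label, group)
  for (g in 0:1) for (y in 0:1) {
    if (!any(gs$group == g & gs$true_label == y))
      stop_fairpost(sprintf("degenerate validation set: no instances with group %d, class %d", g, y),
                    "fairpost_fit_error")
  }
  cfg <- utils::modifyList(default_fit_settings(), settings)
  if (!is.null(features)) features <- as.matrix(features)
  structure(list(score = gs$score, true_label = gs$true_label,
                 group = gs$group, features = features, settings = cfg),
            class = "fit_context")
}

#' Default optimizer settings for the debiasing methods
#'
#' @return Named list:
#' \describe{
#'   \item{eop_band}{EOp level the reject-option search targets (0.05).}
#'   \item{roc_margin_grid}{candidate symmetric margins (0 to 0.5 by 0.01).}
#'   \item{fpr_ceiling}{allowed FPR excess over the population FPR for the
#'     sensitivity-guided threshold (0.10).}
#'   \item{fact_lambda, gstar_lambda}{fairness weights in the respective
#'     objectives (1).}
#'   \item{cpp_cost}{which generalized cost the calibrated-mixing method
#'     equalizes: "fnr" (default, recall-preserving) or "fpr".}
#'   \item{mab_eta, mab_alpha, mab_rounds, mab_ridge}{auditor step size,
#'     residual tolerance, max rounds, ridge penalty (0.1, 0.01, 50, 1e-3).}
#'   \item{seed}{seed stored on returned policies.}
#' }
#' @export
default_fit_settings <- function() {
  list(eop_band = 0.05,
       roc_margin_grid = seq(0, 0.5, by = 0.01),
       fpr_ceiling = 0.10,
       fact_lambda = 1,
       gstar_lambda = 1,
       cpp_cost = "fnr",
       mab_eta = 0.1, mab_alpha = 0.01, mab_rounds = 50L, mab_ridge = 1e-3,
       seed = 1L)
}

# ---- shared helpers --------------------------------------------------------

# Per-group base quantities at the 0.5 threshold.
ctx_group_stats <- function(ctx) {
  base <- threshold_labels(ctx$score)
  stats <- lapply(0:1, function(g) {
    sel <- ctx$group == g
    y <- ctx$true_label[sel]; p <- base[sel]
    list(n = sum(sel), pi = mean(y == 1),
         tpr = mean(p[y == 1] == 1), fpr = mean(p[y == 0] == 1))
  })
  names(stats) <- c("g0", "g1")
  stats
}

# Linear coefficients of expected error and group rates in the four flip
# probabilities x = (p0_base0, p0_base1, p1_base0, p1_base1), where
# p_g_b = P(output favorable | group g, base label b).
flip_lp_terms <- function(ctx) {
  st <- ctx_group_stats(ctx)
  n <- length(ctx$score)
  cT <- list(c(1 - st$g0$tpr, st$g0$tpr, 0, 0),
             c(0, 0, 1 - st$g1$tpr, st$g1$tpr))
  cF <- list(c(1 - st$g0$fpr, st$g0$fpr, 0, 0),
             c(0, 0, 1 - st$g1$fpr, st$g1$fpr))
  w <- c(st$g0$n, st$g1$n) / n
  pi <- c(st$g0$pi, st$g1$pi)
  grad <- -w[1] * pi[1] * cT[[1]] + w[1] * (1 - pi[1]) * cF[[1]] +
          -w[2] * pi[2] * cT[[2]] + w[2] * (1 - pi[2]) * cF[[2]]
  list(err_const = w[1] * pi[1] + w[2] * pi[2], err_grad = grad,
       dT = cT[[1]] - cT[[2]], dF = cF[[1]] - cF[[2]], stats = st)
}

flip_err <- function(terms, x) terms$err_const + sum(terms$err_grad * x)

flip_policy <- function(x, seed) {
  decision_policy("flip_rates",
                  list(p_out1 = matrix(clamp(x, 0, 1), 2, 2, byrow = TRUE)),
                  seed = seed)
}

# ---- CPP: calibrated score mixing ------------------------------------------

#' Calibrated equalized-odds mixing (CPP)
#'
#' Equalizes a generalized cost across groups by randomly replacing, for the
#' lower-cost group, the calibrated score with that group's constant
#' base-rate predictor. Only one of the false-negative or false-positive
#' costs can be equalized for calibrated scores; the default equalizes the
#' generalized false-negative rate, prioritizing recall so at-risk cases are
#' not missed. The fitted mixing probability solves the cost-matching
#' equation in closed form.
#'
#' @param ctx a [fit_context()].
#' @return A `mixing_rates` [decision_policy()] with per-group mixing
#'   probabilities `p` and base-rate constants `const`.
#' @export
fit_cpp <- function(ctx) {
  stopifnot(inherits(ctx, "fit_context"))
  variant <- match.arg(ctx$settings$cpp_cost, c("fnr", "fpr"))
  cost_of <- function(scores, sel) {
    if (variant == "fnr") mean(1 - scores[sel]) else mean(scores[sel])
  }
  cost <- base_rate <- triv_cost <- numeric(2)
  for (g in 0:1) {
    gsel <- ctx$group == g
    ysel <- if (variant == "fnr") ctx$true_label == 1 else ctx$true_label == 0
    cost[g + 1] <- cost_of(ctx$score, gsel & ysel)
    base_rate[g + 1] <- mean(ctx$true_label[gsel] == 1)
    triv_cost[g + 1] <- if (variant == "fnr") 1 - base_rate[g + 1] else base_rate[g + 1]
  }
  p <- c(0, 0)
  gap <- cost[2] - cost[1]
  if (abs(gap) > 1e-12) {
    low <- if (gap > 0) 1L else 2L          # group index (1-based) with lower cost
    high <- 3L - low
    denom <- triv_cost[low] - cost[low]
    if (denom > 1e-12)
      p[low] <- clamp((cost[high] - cost[low]) / denom, 0, 1)
  }
  decision_policy("mixing_rates", list(p = p, const = base_rate),
                  seed = ctx$settings$seed)
}

# ---- EPP: equalized-odds label flipping (exact LP) -------------------------

#' Equalized-odds post-processing (EPP)
#'
#' Derives per-group, per-predicted-label flip probabilities minimizing the
#' expected misclassification rate subject to exact equalized odds: the
#' post-policy expected TPR and FPR are equal across groups. The feasible set
#' is the unit box intersected with two hyperplanes; the optimum of the
#' linear objective is found exactly by enumerating the polytope's vertices
#' (all-zeros / all-ones mixings are always feasible, so the program is never
#' empty).
#'
#' @param ctx a [fit_context()].
#' @return A `flip_rates` [decision_policy()].
#' @export
fit_epp <- function(ctx) {
  stopifnot(inherits(ctx, "fit_context"))
  terms <- flip_lp_terms(ctx)
  A <- rbind(terms$dT, terms$dF)
  cand <- list(rep(0, 4), rep(1, 4))
  combos <- utils::combn(4, 2)
  bounds <- as.matrix(expand.grid(c(0, 1), c(0, 1)))
  for (ci in seq_len(ncol(combos))) {
    free <- combos[, ci]
    fixed <- setdiff(1:4, free)
    M <- A[, free, drop = FALSE]
    if (abs(det(M)) < 1e-12) next
    for (bi in seq_len(nrow(bounds))) {
      x <- numeric(4)
      x[fixed] <- bounds[bi, ]
      rhs <- -A[, fixed, drop = FALSE] %*% x[fixed]
      sol <- solve(M, rhs)
      if (all(sol >= -1e-9 & sol <= 1 + 1e-9)) {
        x[free] <- clamp(sol, 0, 1)
        cand[[length(cand) + 1]] <- x
      }
    }
  }
  feas <- Filter(function(x) max(abs(A %*% x)) <= 1e-8, cand)
  objs <- vapply(feas, function(x) flip_err(terms, x), numeric(1))
  flip_policy(feas[[which.min(objs)]], seed = ctx$settings$seed)
}

# ---- ROC: reject-option classification -------------------------------------

#' Reject-option classification (ROC)
#'
#' Searches a grid of symmetric margins around the 0.5 decision boundary;
#' inside the margin, unprivileged instances are relabeled favorable and
#' privileged ones unfavorable. The smallest margin bringing the validation
#' equal-opportunity difference inside the target band is returned; if no
#' margin reaches the band, the margin minimizing EOp is used.
#'
#' @param ctx a [fit_context()].
#' @return A `flip_region` [decision_policy()].
#' @export
fit_roc <- function(ctx) {
  stopifnot(inherits(ctx, "fit_context"))
  gs <- grouped_scores(ctx$score, ctx$true_label, ctx$group)
  eops <- vapply(ctx$settings$roc_margin_grid, function(m) {
    pol <- decision_policy("flip_region", list(margin = m))
    gs$predicted_label <- apply_policy(pol, gs)
    eop(confusion_by_group(gs))
  }, numeric(1))
  ok <- which(eops <= ctx$settings$eop_band)
  pick <- if (length(ok)) ok[1] else which.min(eops)
  decision_policy("flip_region",
                  list(margin = ctx$settings$roc_margin_grid[pick]),
                  seed = ctx$settings$seed)
}

# ---- PSTA: population-sensitivity-guided threshold adjustment --------------

#' Population-sensitivity-guided threshold adjustment (PSTA)
#'
#' Keeps the privileged threshold at 0.5 and moves the unprivileged
#' threshold, over the sorted unique validation scores, to the candidate
#' whose unprivileged TPR is closest to the whole-population TPR at 0.5 —
#' subject to the unprivileged FPR staying below the population FPR plus a
#' configurable ceiling. Ties prefer the candidate closest to 0.5 (least
#' intervention), then the larger threshold.
#'
#' @param ctx a [fit_context()].
#' @return A `group_thresholds` [decision_policy()].
#' @export
fit_psta <- function(ctx) {
  stopifnot(inherits(ctx, "fit_context"))
  s <- ctx$score; y <- ctx$true_label; g <- ctx$group
  pop_tpr <- mean(s[y == 1] >= 0.5)
  pop_fpr <- mean(s[y == 0] >= 0.5)
  ceiling_ <- pop_fpr + ctx$settings$fpr_ceiling
  cands <- sort(unique(c(s, 0.5)))
  s1 <- s[g == 0 & y == 1]; s0 <- s[g == 0 & y == 0]
  tpr0 <- vapply(cands, function(th) mean(s1 >= th), numeric(1))
  fpr0 <- vapply(cands, function(th) mean(s0 >= th), numeric(1))
  ok <- fpr0 <= ceiling_ + 1e-12
  if (!any(ok)) ok <- rep(TRUE, length(cands))  # unreachable for sane scores
  dev <- abs(tpr0 - pop_tpr)
  key <- order(!ok, dev, abs(cands - 0.5), -cands)[1]
  decision_policy("group_thresholds",
                  list(theta0 = cands[key], theta1 = 0.5),
                  seed = ctx$settings$seed)
}

# ---- FACT: fairness-confusion tensor optimization --------------------------

#' Fairness-confusion tensor optimization (FACT)
#'
#' Chooses per-group, per-predicted-label flip rates minimizing expected
#' misclassification plus `lambda` times the expected equal-opportunity
#' violation, `err(x) + lambda * |TPR0'(x) - TPR1'(x)|`. The objective is
#' convex piecewise-linear over the unit box, so its minimum sits at a box
#' vertex or on the kink hyperplane; both candidate sets are enumerated
#' exactly. With `lambda -> 0` the accuracy-optimal identity policy is
#' recovered.
#'
#' @param ctx a [fit_context()]; `settings$fact_lambda` weighs fairness.
#' @return A `flip_rates` [decision_policy()].
#' @export
fit_fact <- function(ctx) {
  stopifnot(inherits(ctx, "fit_context"))
  terms <- flip_lp_terms(ctx)
  lambda <- ctx$settings$fact_lambda
  obj <- function(x) flip_err(terms, x) + lambda * abs(sum(terms$dT * x))
  cand <- lapply(seq_len(16) - 1, function(i) as.numeric(intToBits(i)[1:4]))
  for (free in 1:4) {
    if (abs(terms$dT[free]) < 1e-12) next
    fixed <- setdiff(1:4, free)
    grid <- as.matrix(expand.grid(c(0, 1), c(0, 1), c(0, 1)))
    for (bi in seq_len(nrow(grid))) {
      x <- numeric(4)
      x[fixed] <- grid[bi, ]
      sol <- -sum(terms$dT[fixed] * x[fixed]) / terms$dT[free]
      if (sol >= -1e-9 && sol <= 1 + 1e-9) {
        x[free] <- clamp(sol, 0, 1)
        cand[[length(cand) + 1]] <- x
      }
    }
  }
  objs <- vapply(cand, obj, numeric(1))
  flip_policy(cand[[which.min(objs)]], seed = ctx$settings$seed)
}

# ---- GSTAR: group-specific thresholds from smoothed distributions ----------

# Kernel-smoothed empirical CDF evaluated at thresholds `at`.
smoothed_cdf <- function(x, at) {
  bw <- stats::bw.nrd0(x)
  if (!is.finite(bw) || bw <= 0) bw <- 1e-3
  vapply(at, function(t) mean(stats::pnorm((t - x) / bw)), numeric(1))
}

#' Group-specific threshold adaptation (GSTAR)
#'
#' Learns one threshold per group minimizing classification error plus
#' `lambda` times the equalized-odds difference, both estimated from
#' kernel-smoothed group- and class-conditional score distributions
#' (Silverman bandwidth). A grid over the empirical scores seeds a
#' Nelder-Mead refinement of the smooth surrogate.
#'
#' @param ctx a [fit_context()]; `settings$gstar_lambda` weighs fairness.
#' @return A `group_thresholds` [decision_policy()].
#' @export
fit_gstar <- function(ctx) {
  stopifnot(inherits(ctx, "fit_context"))
  s <- ctx$score; y <- ctx$true_label; g <- ctx$group
  lambda <- ctx$settings$gstar_lambda
  n <- length(s)
  parts <- list(F01 = s[g == 0 & y == 1], F00 = s[g == 0 & y == 0],
                F11 = s[g == 1 & y == 1], F10 = s[g == 1 & y == 0])
  w <- c(mean(g == 0), mean(g == 1))
  pi <- c(mean(y[g == 0] == 1), mean(y[g == 1] == 1))
  cdf <- function(part, th) smoothed_cdf(parts[[part]], th)
  objective <- function(th) {
    th <- clamp(th, 0, 1)
    tpr <- c(1 - cdf("F01", th[1]), 1 - cdf("F11", th[2]))
    fpr <- c(1 - cdf("F00", th[1]), 1 - cdf("F10", th[2]))
    err <- sum(w * (pi * (1 - tpr) + (1 - pi) * fpr))
    err + lambda * (abs(tpr[1] - tpr[2]) + abs(fpr[1] - fpr[2])) / 2
  }
  cand0 <- sort(unique(c(s[g == 0], 0.5)))
  cand1 <- sort(unique(c(s[g == 1], 0.5)))
  if (length(cand0) > 60) cand0 <- unique(stats::quantile(cand0, seq(0, 1, length.out = 60), names = FALSE))
  if (length(cand1) > 60) cand1 <- unique(stats::quantile(cand1, seq(0, 1, length.out = 60), names = FALSE))
  # precompute CDF values once per candidate axis, then scan the grid
  t0 <- 1 - smoothed_cdf(parts$F01, cand0); f0 <- 1 - smoothed_cdf(parts$F00, cand0)
  t1 <- 1 - smoothed_cdf(parts$F11, cand1); f1 <- 1 - smoothed_cdf(parts$F10, cand1)
  G <- outer(w[1] * (pi[1] * (1 - t0) + (1 - pi[1]) * f0),
             w[2] * (pi[2] * (1 - t1) + (1 - pi[2]) * f1), `+`) +
       lambda * (abs(outer(t0, t1, `-`)) + abs(outer(f0, f1, `-`))) / 2
  ij <- arrayInd(which.min(G), dim(G))
  start <- c(cand0[ij[1]], cand1[ij[2]])
  fit <- stats::optim(start, objective, method = "Nelder-Mead",
                      control = list(maxit = 200, reltol = 1e-8))
  th <- clamp(fit$par, 0, 1)
  decision_policy("group_thresholds", list(theta0 = th[1], theta1 = th[2]),
                  seed = ctx$settings$seed)
}

# ---- MAB: multiaccuracy boosting -------------------------------------------

ridge_fit <- function(X, r, lambda) {
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  beta <- solve(crossprod(Xc) + diag(lambda, ncol(Xc)), crossprod(Xc, r))
  list(center = center, beta = drop(beta), intercept = mean(r))
}

ridge_predict <- function(fit, X)
  drop(sweep(X, 2, fit$center) %*% fit$beta) + fit$intercept

#' Multiaccuracy boosting (MAB)
#'
#' Iteratively corrects systematic score miscalibration on auditor-identified
#' subpopulations, without ever seeing the protected attribute. Each round
#' fits a ridge-regression auditor to the residuals (true label minus score)
#' as a function of the raw features; if the subpopulation where the auditor
#' predicts positive (or negative) residuals has mean residual magnitude
#' above the tolerance `mab_alpha`, scores receive an additive logit
#' correction of `mab_eta` times the auditor prediction. A round is kept only
#' if it strictly reduces the detected residual magnitude; fitting stops when
#' no region exceeds the tolerance, a round fails to improve, or `mab_rounds`
#' is reached. Perfectly calibrated scores yield an identity correction list.
#'
#' @param ctx a [fit_context()] with `features` set. The group column is
#'   never consulted.
#' @return A `score_corrections` [decision_policy()] storing the accepted
#'   auditor rounds.
#' @export
fit_mab <- function(ctx) {
  stopifnot(inherits(ctx, "fit_context"))
  if (is.null(ctx$features))
    stop_fairpost("the multiaccuracy auditor requires features in the context",
                  "fairpost_fit_error")
  mab_fit_core(ctx$score, ctx$true_label, ctx$features, ctx$settings)
}

# Deliberately takes no group argument: the auditor works from features only.
mab_fit_core <- function(score, y, X, cfg) {
  eps <- 1e-6
  s <- clamp(score, eps, 1 - eps)
  rounds <- list()
  detect <- function(aud_pred, r) {
    mags <- c(pos = if (any(aud_pred > 0)) abs(mean(r[aud_pred > 0])) else 0,
              neg = if (any(aud_pred <= 0)) abs(mean(r[aud_pred <= 0])) else 0)
    max(mags)
  }
  for (t in seq_len(cfg$mab_rounds)) {
    r <- y - s
    fit <- ridge_fit(X, r, cfg$mab_ridge)
    pred <- ridge_predict(fit, X)
    mag <- detect(pred, r)
    if (mag <= cfg$mab_alpha) break
    s_new <- stats::plogis(stats::qlogis(s) + cfg$mab_eta * pred)
    # a round is accepted only if it strictly shrinks the residual magnitude
    # on the region this round's auditor detected
    if (detect(pred, y - s_new) >= mag - 1e-12) break
    s <- clamp(s_new, eps, 1 - eps)
    rounds[[length(rounds) + 1]] <- fit
  }
  decision_policy("score_corrections",
                  list(eta = cfg$mab_eta, rounds = rounds),
                  seed = cfg$seed)
}

# ---- registry --------------------------------------------------------------

#' Registered debiasing methods
#'
#' @return Character vector of method names accepted by [fit_policy()] and
#'   the benchmark harness ("identity" is the no-op control).
#' @export
debias_methods <- function() c("identity", "cpp", "epp", "roc", "psta",
                               "fact", "gstar", "mab")

#' Fit a debiasing policy by method name
#'
#' @param method one of [debias_methods()].
#' @param ctx a [fit_context()].
#' @return A [decision_policy()].
#' @export
fit_policy <- function(method, ctx) {
  method <- match.arg(method, debias_methods())
  switch(method,
    identity = decision_policy("identity", seed = ctx$settings$seed),
    cpp = fit_cpp(ctx), epp = fit_epp(ctx), roc = fit_roc(ctx),
    psta = fit_psta(ctx), fact = fit_fact(ctx), gstar = fit_gstar(ctx),
    mab = fit_mab(ctx))
}
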