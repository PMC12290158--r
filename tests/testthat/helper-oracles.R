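# Independent brute-force oracles and shared toy fixtures. These deliberately
# re-derive every quantity from first principles (loops, pair enumeration,
# exhaustive grids) so they share no code path with the implementation.

cliffs_brute <- function(x, y) {
  gt <- 0; lt <- 0
  for (a in x) for (b in y) {
    if (a > b) gt <- gt + 1 else if (a < b) lt <- lt + 1
  }
  (gt - lt) / (length(x) * length(y))
}

# A deterministic two-group scored sample with a planted TPR gap; used as the
# common validation set for the optimizer-vs-oracle comparisons.
toy_ctx <- function(seed = 7, n = 120, settings = list()) {
  dat <- withr::with_seed(seed, {
    g <- rep(0:1, length.out = n)
    y <- stats::rbinom(n, 1, 0.45 + 0.1 * g)
    s <- pmin(pmax(0.3 + 0.35 * y + 0.12 * g + stats::rnorm(n, 0, 0.18), 0.01), 0.99)
    list(s = s, y = y, g = g, X = cbind(x = stats::rnorm(n)))
  })
  fit_context(dat$s, dat$y, dat$g, features = dat$X, settings = settings)
}

# Per-group rates at threshold 0.5, computed with plain loops.
oracle_group_stats <- function(s, y, g) {
  out <- list()
  for (gr in 0:1) {
    sel <- g == gr
    pred <- as.integer(s[sel] >= 0.5)
    ys <- y[sel]
    out[[gr + 1]] <- list(
      n = sum(sel), pi = mean(ys == 1),
      tpr = mean(pred[ys == 1] == 1), fpr = mean(pred[ys == 0] == 1))
  }
  out
}

# Expected error and TPR/FPR gaps as functions of the four flip probabilities
# x = (p0_b0, p0_b1, p1_b0, p1_b1); hand-derived linear coefficients.
oracle_flip_terms <- function(s, y, g) {
  st <- oracle_group_stats(s, y, g)
  n <- length(s)
  w <- c(st[[1]]$n, st[[2]]$n) / n
  tpr_coef <- function(gr) {
    v <- numeric(4); v[2 * gr + 1] <- 1 - st[[gr + 1]]$tpr; v[2 * gr + 2] <- st[[gr + 1]]$tpr; v
  }
  fpr_coef <- function(gr) {
    v <- numeric(4); v[2 * gr + 1] <- 1 - st[[gr + 1]]$fpr; v[2 * gr + 2] <- st[[gr + 1]]$fpr; v
  }
  err <- function(x) {
    total <- 0
    for (gr in 0:1) {
      tpr_p <- sum(tpr_coef(gr) * x); fpr_p <- sum(fpr_coef(gr) * x)
      total <- total + w[gr + 1] * (st[[gr + 1]]$pi * (1 - tpr_p) +
                                    (1 - st[[gr + 1]]$pi) * fpr_p)
    }
    total
  }
  list(err = err,
       dT = tpr_coef(0) - tpr_coef(1),
       dF = fpr_coef(0) - fpr_coef(1))
}

policy_flat_rates <- function(policy) {
  P <- policy$params$p_out1
  c(P[1, 1], P[1, 2], P[2, 1], P[2, 2])
}

# Exhaustive CPP oracle: mixing probability grid minimizing the generalized
# false-negative cost gap.
oracle_cpp_p <- function(s, y, g) {
  cost <- tc <- numeric(2)
  for (gr in 0:1) {
    cost[gr + 1] <- mean(1 - s[g == gr & y == 1])
    tc[gr + 1] <- 1 - mean(y[g == gr] == 1)
  }
  low <- which.min(cost); high <- 3 - low
  grid <- seq(0, 1, by = 0.01)
  gaps <- sapply(grid, function(p)
    abs((1 - p) * cost[low] + p * tc[low] - cost[high]))
  p <- c(0, 0)
  p[low] <- grid[which.min(gaps)]
  p
}

# Exhaustive EPP oracle: grid the two group-0 probabilities, solve the two
# equalized-odds equations for the group-1 probabilities, keep feasible
# points, return the minimal expected error found.
oracle_epp_best_err <- function(s, y, g, step = 0.02) {
  terms <- oracle_flip_terms(s, y, g)
  A <- rbind(terms$dT, terms$dF)
  M <- A[, 3:4]
  best <- Inf
  for (x1 in seq(0, 1, by = step)) for (x2 in seq(0, 1, by = step)) {
    rhs <- -(A[, 1:2] %*% c(x1, x2))
    if (abs(det(M)) < 1e-12) next
    sol <- solve(M, rhs)
    if (all(sol >= -1e-9 & sol <= 1 + 1e-9)) {
      e <- terms$err(c(x1, x2, pmin(pmax(sol, 0), 1)))
      if (e < best) best <- e
    }
  }
  best
}

# Exhaustive FACT oracle on a 0.05 probability grid (vectorized).
oracle_fact_best_obj <- function(s, y, g, lambda, step = 0.05) {
  terms <- oracle_flip_terms(s, y, g)
  ax <- seq(0, 1, by = step)
  grid <- as.matrix(expand.grid(ax, ax, ax, ax))
  errs <- apply(grid, 1, terms$err)
  min(errs + lambda * abs(grid %*% terms$dT))
}

# Loop-based ROC margin scan mirroring the published selection rule.
oracle_roc_margin <- function(s, y, g, margins, band) {
  eops <- numeric(length(margins))
  for (i in seq_along(margins)) {
    m <- margins[i]
    lab <- as.integer(s >= 0.5)
    inside <- s >= 0.5 - m & s <= 0.5 + m
    lab[inside & g == 0] <- 1L
    lab[inside & g == 1] <- 0L
    tpr0 <- mean(lab[g == 0 & y == 1] == 1)
    tpr1 <- mean(lab[g == 1 & y == 1] == 1)
    eops[i] <- abs(tpr0 - tpr1)
  }
  ok <- which(eops <= band)
  if (length(ok)) margins[ok[1]] else margins[which.min(eops)]
}

# Loop-based PSTA threshold search with the same feasibility and tie rules.
oracle_psta_theta <- function(s, y, g, ceiling_add = 0.1) {
  pop_tpr <- mean(s[y == 1] >= 0.5)
  pop_fpr <- mean(s[y == 0] >= 0.5)
  cands <- sort(unique(c(s, 0.5)))
  best <- NA; best_key <- c(Inf, Inf, Inf)
  for (th in cands) {
    tpr0 <- mean(s[g == 0 & y == 1] >= th)
    fpr0 <- mean(s[g == 0 & y == 0] >= th)
    if (fpr0 > pop_fpr + ceiling_add + 1e-12) next
    key <- c(abs(tpr0 - pop_tpr), abs(th - 0.5), -th)
    for (i in 1:3) {
      if (key[i] < best_key[i] - 1e-15) { best <- th; best_key <- key; break }
      if (key[i] > best_key[i] + 1e-15) break
    }
  }
  best
}

# Smoothed GSTAR objective re-derived independently (Gaussian-kernel CDF with
# Silverman bandwidth), plus its exhaustive 2-D threshold scan.
oracle_gstar_objective <- function(s, y, g, lambda) {
  kcdf <- function(x, t) {
    bw <- stats::bw.nrd0(x)
    if (!is.finite(bw) || bw <= 0) bw <- 1e-3
    mean(stats::pnorm((t - x) / bw))
  }
  w <- c(mean(g == 0), mean(g == 1))
  pi <- c(mean(y[g == 0] == 1), mean(y[g == 1] == 1))
  function(th0, th1) {
    tpr <- c(1 - kcdf(s[g == 0 & y == 1], th0), 1 - kcdf(s[g == 1 & y == 1], th1))
    fpr <- c(1 - kcdf(s[g == 0 & y == 0], th0), 1 - kcdf(s[g == 1 & y == 0], th1))
    err <- sum(w * (pi * (1 - tpr) + (1 - pi) * fpr))
    err + lambda * (abs(tpr[1] - tpr[2]) + abs(fpr[1] - fpr[2])) / 2
  }
}

oracle_gstar_best <- function(s, y, g, lambda) {
  obj <- oracle_gstar_objective(s, y, g, lambda)
  cand0 <- sort(unique(c(s[g == 0], 0.5)))
  cand1 <- sort(unique(c(s[g == 1], 0.5)))
  best <- Inf
  for (a in cand0) for (b in cand1) {
    v <- obj(a, b)
    if (v < best) best <- v
  }
  best
}

# One-feature scores with a planted subgroup miscalibration (scores 0.3 too
# low wherever x > 0).
planted_bias_data <- function(seed = 9, n = 400) {
  withr::with_seed(seed, {
    x <- stats::runif(n, -1, 1)
    ptrue <- stats::plogis(2 * x)
    y <- as.integer(stats::runif(n) < ptrue)
    score <- pmin(pmax(ptrue - 0.3 * (x > 0), 0.01), 0.99)
    list(x = x, y = y, score = score)
  })
}
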