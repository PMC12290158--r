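#' Configuration for the synthetic biased-data generator
#'
#' The generator draws two-dimensional features from class-conditional
#' bivariate Gaussians. The favorable class (Y = 1) has mean `(2, 2 + s)` and
#' covariance `[[5, 1], [1, 5]]`; the unfavorable class (Y = 0) has mean
#' `(-2, -(2 + s))` and covariance `[[10, 1], [1, 3]]`. The separation shift
#' `s` moves the class means apart along the second feature: `s = -1` gives
#' heavily overlapping classes (a hard task), `s = 0` a medium one, `s = 1` an
#' easy one. The protected attribute is the sign of the first feature, so the
#' unprivileged group (A = 0, x0 < 0) is naturally depleted in the favorable
#' class — the structural bias the debiasing methods are evaluated against.
#'
#' @param s real separation shift (unitless), typically in \{-1, 0, 1\}.
#' @param n_per_class positive integer; rows drawn per class.
#' @param seed integer RNG seed.
#' @return A `synth_config` object holding the fixed means/covariances.
#' @export
synth_config <- function(s = 0, n_per_class = 1000L, seed = 1L) {
  if (!is.numeric(s) || length(s) != 1L || !is.finite(s))
    stop_fairpost("s must be a finite number", "fairpost_invalid_argument")
  n_per_class <- as.integer(n_per_class)
  if (is.na(n_per_class) || n_per_class < 1L)
    stop_fairpost("n_per_class must be a positive integer", "fairpost_invalid_argument")
  structure(list(
    s = s, n_per_class = n_per_class, seed = as.integer(seed),
    mean_pos = c(2, 2 + s),
    mean_neg = c(-2, -(2 + s)),
    cov_pos = matrix(c(5, 1, 1, 5), 2, 2),
    cov_neg = matrix(c(10, 1, 1, 3), 2, 2)
  ), class = "synth_config")
}

#' Protected-group assignment from the first feature
#'
#' The unprivileged group is `A = 0` for `x0 < 0`; `x0 >= 0` maps to the
#' privileged group `A = 1`. `x0 = 0` is a probability-zero event under the
#' continuous model and is assigned, by documented convention, to the
#' privileged group. Under the generator's Gaussians the `x0 < 0` group has
#' the lower favorable rate, which is why it is the unprivileged one.
#'
#' @param x0 numeric vector of first-feature values; must be finite.
#' @return Integer vector in \{0, 1\}.
#' @export
assign_protected <- function(x0) {
  if (!is.numeric(x0) || any(!is.finite(x0)))
    stop_fairpost("x0 must be finite numeric", "fairpost_invalid_argument")
  as.integer(x0 >= 0)
}

#' Simulate a class-balanced biased dataset
#'
#' Draws `n_per_class` rows from each class-conditional Gaussian of
#' [synth_config()] and attaches the protected attribute `A = sgn(x0)`.
#' With `s = 0`, roughly 18% of favorable-class rows and 73% of
#' unfavorable-class rows fall in the unprivileged group (the normal tail
#' probabilities of the marginal distributions of x0 at zero).
#'
#' @param config a `synth_config`.
#' @return A [tabular_dataset()] with `2 * n_per_class` rows, features `x0`,
#'   `x1`, and protected attribute `A`. Reproducible given `config$seed`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_per_class
  draws <- withr::with_seed(config$seed, {
    pos <- MASS::mvrnorm(n, config$mean_pos, config$cov_pos)
    neg <- MASS::mvrnorm(n, config$mean_neg, config$cov_neg)
    list(pos = matrix(pos, ncol = 2), neg = matrix(neg, ncol = 2))
  })
  X <- rbind(draws$pos, draws$neg)
  y <- rep(c(1L, 0L), each = n)
  tabular_dataset(data.frame(x0 = X[, 1], x1 = X[, 2]),
                  labels = y,
                  protected = data.frame(A = assign_protected(X[, 1])))
}

#' Plan a class-balanced subsample with a target unprivileged-group rate
#'
#' Finds the largest feasible even total `m` such that demanding
#' `u = round(target_ugr * m / 2)` rows from each unprivileged (group, class)
#' cell and `m/2 - u` rows from each privileged cell stays within the cell
#' supplies of `dataset`. Imposing equal unprivileged counts across the two
#' classes (`u1 = u0`) resolves the degree of freedom the two constraints
#' (class balance, target rate) leave open, and keeps every subsample
#' class-balanced within each group. The search decrements `m` in steps of 2
#' from the largest even total, so it is deterministic.
#'
#' @param dataset a `tabular_dataset` containing attribute `attr`.
#' @param target_ugr target unprivileged-group rate in (0, 1).
#' @param attr protected attribute name (default "A").
#' @return A `ugr_plan` with components `target_ugr`, `m`, `counts`
#'   (named u1, u0, p1, p0 for the four (group, class) cells), `achieved_ugr`
#'   and `feasible`. `feasible` is FALSE only when no `m >= 4` works.
#' @export
plan_ugr <- function(dataset, target_ugr, attr = "A") {
  if (!is.numeric(target_ugr) || length(target_ugr) != 1L ||
      target_ugr <= 0 || target_ugr >= 1)
    stop_fairpost("target_ugr must lie strictly in (0, 1)", "fairpost_invalid_argument")
  if (!attr %in% names(dataset$protected))
    stop_fairpost(sprintf("protected attribute '%s' not present", attr),
                  "fairpost_schema_error")
  a <- dataset$protected[[attr]]
  y <- dataset$labels
  supply <- c(u1 = sum(a == 0 & y == 1), u0 = sum(a == 0 & y == 0),
              p1 = sum(a == 1 & y == 1), p0 = sum(a == 1 & y == 0))
  m_max <- 2L * (dataset_n(dataset) %/% 2L)
  m <- m_max
  while (m >= 4L) {
    u <- round_half_up(target_ugr * m / 2)
    p <- m %/% 2L - u
    if (u >= 0 && p >= 0 && u <= supply[["u1"]] && u <= supply[["u0"]] &&
        p <= supply[["p1"]] && p <= supply[["p0"]]) {
      return(structure(list(target_ugr = target_ugr, m = m,
                            counts = c(u1 = u, u0 = u, p1 = p, p0 = p),
                            achieved_ugr = 2 * u / m, feasible = TRUE,
                            attr = attr),
                       class = "ugr_plan"))
    }
    m <- m - 2L
  }
  structure(list(target_ugr = target_ugr, m = 0L,
                 counts = c(u1 = 0L, u0 = 0L, p1 = 0L, p0 = 0L),
                 achieved_ugr = NA_real_, feasible = FALSE, attr = attr),
            class = "ugr_plan")
}

#' Resample a dataset to one or more unprivileged-group rates
#'
#' Each of the four (group, class) cells receives one fixed seeded
#' permutation; every plan's demanded cell count is taken as a prefix of that
#' permutation. Cell-wise prefix nesting follows: the rows a cell contributes
#' under a smaller demand are a subset of those it contributes under a larger
#' demand, so training sets at low unprivileged representation are (cell-wise)
#' nested within those at higher representation.
#'
#' @param dataset a `tabular_dataset`.
#' @param plans list of feasible `ugr_plan`s, sorted by `target_ugr`.
#' @param seed integer seed for the cell permutations.
#' @return List of `tabular_dataset`s, one per plan, each exactly
#'   class-balanced with unprivileged fraction within 1/m of its target.
#' @export
resample_to_ugr <- function(dataset, plans, seed = 1L) {
  if (inherits(plans, "ugr_plan")) plans <- list(plans)
  if (!length(plans)) stop_fairpost("plans must be non-empty", "fairpost_invalid_argument")
  if (any(!vapply(plans, function(p) isTRUE(p$feasible), logical(1))))
    stop_fairpost("all plans must be feasible", "fairpost_precondition_error")
  attr_ <- plans[[1]]$attr
  a <- dataset$protected[[attr_]]
  y <- dataset$labels
  cells <- list(u1 = which(a == 0 & y == 1), u0 = which(a == 0 & y == 0),
                p1 = which(a == 1 & y == 1), p0 = which(a == 1 & y == 0))
  perms <- lapply(names(cells), function(nm) {
    idx <- cells[[nm]]
    withr::with_seed(substream_seed(seed, paste0("ugr-cell-", nm)),
                     idx[sample.int(length(idx))])
  })
  names(perms) <- names(cells)
  lapply(plans, function(plan) {
    take <- unlist(lapply(names(cells), function(nm) {
      k <- plan$counts[[nm]]
      if (k > length(perms[[nm]]))
        stop_fairpost("plan demands exceed cell supply", "fairpost_precondition_error")
      perms[[nm]][seq_len(k)]
    }), use.names = FALSE)
    dataset_subset(dataset, sort(take))
  })
}

#' Stratified cross-validation folds
#'
#' Partitions rows into `k` disjoint test sets, stratified jointly by class
#' and by the (first) protected attribute so every fold sees both groups and
#' both classes in near-global proportions.
#'
#' @param dataset a `tabular_dataset`.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @param attr protected attribute used for stratification.
#' @return List of `k` integer vectors of test-row positions.
#' @export
make_cv_folds <- function(dataset, k = 5L, seed = 1L,
                          attr = names(dataset$protected)[1]) {
  n <- dataset_n(dataset)
  k <- as.integer(k)
  if (k < 2L || k > n)
    stop_fairpost("k must satisfy 2 <= k <= n", "fairpost_invalid_argument")
  strata <- interaction(dataset$labels, dataset$protected[[attr]], drop = TRUE)
  assign <- integer(n)
  withr::with_seed(substream_seed(seed, "cv-folds"), {
    offset <- 0L
    for (lev in levels(strata)) {
      idx <- which(strata == lev)
      idx <- idx[sample.int(length(idx))]
      # rotate the starting fold between strata so fold sizes stay even
      assign[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
      offset <- offset + length(idx)
    }
  })
  lapply(seq_len(k), function(i) which(assign == i))
}
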