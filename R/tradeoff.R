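resolve_fairness_fun <- function(name) {
  switch(match.arg(name, c("eop", "eod")),
         eop = function(gs) eop(confusion_by_group(gs)),
         eod = function(gs) eod(confusion_by_group(gs)))
}

resolve_performance_fun <- function(name) {
  name <- match.arg(name, c("acc", "bacc", "f1"))
  function(gs) suppressWarnings(performance(gs))[[name]]
}

#' Build a mutation-based fairness-performance baseline
#'
#' Constructs the reference trade-off curve against which mitigation
#' outcomes are judged: for each mutation degree `d`, a uniformly chosen
#' fraction `d` of the unmitigated predictions is replaced by the majority
#' label, over `n_trials` seeded trials; the per-degree mean (fairness,
#' performance) points, together with the unmitigated origin, form a
#' polyline. At degree 1 the predictor is constant, so the equal-opportunity
#' difference is exactly 0 and accuracy equals the majority-class proportion.
#'
#' @param data a `grouped_scores` with unmitigated `predicted_label`.
#' @param degrees mutation degrees in (0, 1]; default 0.1 to 1 by 0.1.
#' @param n_trials trials per degree (default 50).
#' @param seed integer seed for the mutation draws.
#' @param fairness fairness metric name, "eop" (default) or "eod".
#' @param perf performance metric name, "acc" (default), "bacc" or "f1".
#' @param majority_label mutation target; defaults to the majority true
#'   label (ties resolved to the favorable label 1).
#' @param healthcare_factor fraction of origin performance marking the
#'   stricter sub-region of the good trade-off region (default 0.9; up to
#'   0.99 for high-stakes settings).
#' @return A `tradeoff_baseline` with the origin, the per-degree points, and
#'   the classification parameters.
#' @export
build_baseline <- function(data, degrees = seq(0.1, 1, by = 0.1),
                           n_trials = 50L, seed = 1L,
                           fairness = "eop", perf = "acc",
                           majority_label = NULL, healthcare_factor = 0.9) {
  stopifnot(inherits(data, "grouped_scores"))
  if (is.null(data$predicted_label))
    stop_fairpost("unmitigated predicted labels are required", "fairpost_schema_error")
  if (!length(degrees) || any(degrees <= 0 | degrees > 1))
    stop_fairpost("degrees must be non-empty and lie in (0, 1]",
                  "fairpost_invalid_argument")
  if (healthcare_factor <= 0 || healthcare_factor > 0.99)
    stop_fairpost("healthcare_factor must lie in (0, 0.99]",
                  "fairpost_invalid_argument")
  degrees <- sort(degrees)
  ffun <- resolve_fairness_fun(fairness)
  pfun <- resolve_performance_fun(perf)
  if (is.null(majority_label)) {
    majority_label <- if (mean(data$true_label) >= 0.5) 1L else 0L
  }
  n <- length(data$score)
  origin <- c(fairness = ffun(data), performance = pfun(data))
  pts <- withr::with_seed(substream_seed(seed, "mutations"), {
    do.call(rbind, lapply(degrees, function(d) {
      k <- round_half_up(d * n)
      vals <- vapply(seq_len(n_trials), function(trial) {
        mut <- data
        idx <- sample.int(n, k)
        mut$predicted_label[idx] <- majority_label
        c(ffun(mut), pfun(mut))
      }, numeric(2))
      data.frame(degree = d, fairness = mean(vals[1, ]),
                 performance = mean(vals[2, ]))
    }))
  })
  structure(list(origin = origin, points = pts,
                 fairness = fairness, perf = perf,
                 majority_label = majority_label,
                 healthcare_factor = healthcare_factor),
            class = "tradeoff_baseline")
}

# Baseline performance at a given fairness value: linear interpolation along
# the polyline (origin + degree points), flat beyond its fairness range.
baseline_performance_at <- function(baseline, fairness) {
  pts <- rbind(data.frame(degree = 0,
                          fairness = baseline$origin[["fairness"]],
                          performance = baseline$origin[["performance"]]),
               baseline$points)
  o <- order(pts$fairness)
  stats::approx(pts$fairness[o], pts$performance[o], xout = fairness,
                rule = 2, ties = mean)$y
}

#' Classify a mitigation outcome into a trade-off region
#'
#' Fairness is smaller-better, performance larger-better. Relative to the
#' unmitigated origin:
#' \itemize{
#'   \item both strictly improve: `win-win`;
#'   \item fairness improves, performance does not: `good` when the point
#'     lies on or above the baseline polyline at its fairness value
#'     (sub-region `good-2.2` when performance also retains at least
#'     `healthcare_factor` of the origin performance, `good-2.1` otherwise),
#'     else `poor`;
#'   \item fairness does not improve but performance does: `inverted`;
#'   \item neither improves: `lose-lose`.
#' }
#' Equality on fairness counts as "not improved" and equality on performance
#' as "not worsened" — the conservative reading under which a method is
#' effective only strictly above the baseline.
#'
#' @param point numeric vector or list with elements `fairness` and
#'   `performance`, both in [0, 1].
#' @param baseline a [build_baseline()] result.
#' @return A `mitigation_outcome`: list with `region` (one of win-win,
#'   good-2.1, good-2.2, poor, inverted, lose-lose), `fairness`,
#'   `performance`.
#' @export
classify_region <- function(point, baseline) {
  stopifnot(inherits(baseline, "tradeoff_baseline"))
  f <- point[["fairness"]]; p <- point[["performance"]]
  if (!is.finite(f) || !is.finite(p) || f < 0 || f > 1 || p < 0 || p > 1)
    stop_fairpost("point must lie in the unit square", "fairpost_invalid_argument")
  f0 <- baseline$origin[["fairness"]]; p0 <- baseline$origin[["performance"]]
  region <- if (f < f0) {
    if (p > p0) "win-win"
    else if (p >= baseline_performance_at(baseline, f)) {
      if (p >= baseline$healthcare_factor * p0) "good-2.2" else "good-2.1"
    } else "poor"
  } else {
    if (p > p0) "inverted" else "lose-lose"
  }
  structure(list(region = region, fairness = f, performance = p),
            class = "mitigation_outcome")
}
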