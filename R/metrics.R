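#' Per-instance scores, labels and group membership
#'
#' The evaluation container: a probability score, the true label, the binary
#' group, and (optionally, until a decision policy has been applied) a
#' predicted label per instance.
#'
#' @param score numeric vector of class-1 probabilities in [0, 1].
#' @param true_label vector in \{0, 1\}.
#' @param group vector in \{0, 1\}; 0 = unprivileged.
#' @param predicted_label optional vector in \{0, 1\}.
#' @return A `grouped_scores` object.
#' @export
grouped_scores <- function(score, true_label, group, predicted_label = NULL) {
  n <- length(score)
  if (length(true_label) != n || length(group) != n)
    stop_fairpost("score, true_label and group must have equal length",
                  "fairpost_schema_error")
  if (any(!is.finite(score)) || any(score < 0) || any(score > 1))
    stop_fairpost("scores must lie in [0, 1]", "fairpost_invalid_argument")
  if (!all(true_label %in% c(0, 1)) || !all(group %in% c(0, 1)))
    stop_fairpost("true_label and group must be coded 0/1", "fairpost_schema_error")
  if (!is.null(predicted_label)) {
    if (length(predicted_label) != n || !all(predicted_label %in% c(0, 1)))
      stop_fairpost("predicted_label must be 0/1 of length n", "fairpost_schema_error")
    predicted_label <- as.integer(predicted_label)
  }
  structure(list(score = as.numeric(score), true_label = as.integer(true_label),
                 group = as.integer(group), predicted_label = predicted_label),
            class = "grouped_scores")
}

#' Threshold scores into labels
#'
#' Ties at the threshold go to the favorable label (score >= threshold -> 1),
#' the convention used consistently across all policies in the package.
#'
#' @param score numeric scores.
#' @param threshold decision threshold (default 0.5).
#' @export
threshold_labels <- function(score, threshold = 0.5) as.integer(score >= threshold)

#' Per-group confusion counts and rates
#'
#' @param data a `grouped_scores` with `predicted_label` set.
#' @return A `group_confusion`: for each group, TP/FP/TN/FN counts plus TPR,
#'   FPR, FNR, TNR (NA where the denominator is zero).
#' @export
confusion_by_group <- function(data) {
  stopifnot(inherits(data, "grouped_scores"))
  if (is.null(data$predicted_label))
    stop_fairpost("predicted labels are required; apply a policy first",
                  "fairpost_schema_error")
  for (g in 0:1) if (!any(data$group == g))
    stop_fairpost(sprintf("group %d absent from data", g), "fairpost_degenerate_group")
  per_group <- lapply(0:1, function(g) {
    sel <- data$group == g
    y <- data$true_label[sel]; p <- data$predicted_label[sel]
    tp <- sum(y == 1 & p == 1); fn <- sum(y == 1 & p == 0)
    fp <- sum(y == 0 & p == 1); tn <- sum(y == 0 & p == 0)
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
         fnr = if (tp + fn > 0) fn / (tp + fn) else NA_real_,
         tnr = if (fp + tn > 0) tn / (fp + tn) else NA_real_)
  })
  structure(list(g0 = per_group[[1]], g1 = per_group[[2]],
                 n = length(data$score)),
            class = "group_confusion")
}

#' Equal opportunity difference
#'
#' `EOp = |TPR0 - TPR1|`: the absolute gap in true-positive rates between the
#' unprivileged and privileged groups; 0 means the groups' at-risk members are
#' detected equally well.
#'
#' @param conf a `group_confusion`.
#' @return Numeric in [0, 1].
#' @export
eop <- function(conf) {
  stopifnot(inherits(conf, "group_confusion"))
  if (is.na(conf$g0$tpr) || is.na(conf$g1$tpr))
    stop_fairpost("TPR undefined for a group (no positive instances)",
                  "fairpost_undefined_rate")
  abs(conf$g0$tpr - conf$g1$tpr)
}

#' Equalized odds difference
#'
#' `EOd = (|FPR0 - FPR1| + |TPR0 - TPR1|) / 2`: the mean of the absolute
#' true-positive-rate and false-positive-rate gaps; balances detection of
#' at-risk members against false alarms across groups.
#'
#' @param conf a `group_confusion`.
#' @return Numeric in [0, 1].
#' @export
eod <- function(conf) {
  stopifnot(inherits(conf, "group_confusion"))
  if (is.na(conf$g0$tpr) || is.na(conf$g1$tpr) ||
      is.na(conf$g0$fpr) || is.na(conf$g1$fpr))
    stop_fairpost("a component rate is undefined for a group",
                  "fairpost_undefined_rate")
  (abs(conf$g0$fpr - conf$g1$fpr) + abs(conf$g0$tpr - conf$g1$tpr)) / 2
}

#' Pooled predictive performance: accuracy, balanced accuracy, F1
#'
#' Balanced accuracy is pooled over groups, `(TPR + TNR) / 2`. F1 is the
#' harmonic mean of precision and recall for the favorable class; with zero
#' predicted positives it is defined as 0 with a warning (the usual
#' convention under severe imbalance).
#'
#' @param data a `grouped_scores` with `predicted_label` set.
#' @return Named list with `acc`, `bacc`, `f1`.
#' @export
performance <- function(data) {
  stopifnot(inherits(data, "grouped_scores"))
  if (is.null(data$predicted_label))
    stop_fairpost("predicted labels are required", "fairpost_schema_error")
  y <- data$true_label; p <- data$predicted_label
  acc <- mean(y == p)
  if (length(unique(y)) < 2L)
    stop_fairpost("balanced accuracy and F1 need both classes in the truth",
                  "fairpost_undefined_metric")
  tp <- sum(y == 1 & p == 1); fn <- sum(y == 1 & p == 0)
  fp <- sum(y == 0 & p == 1); tn <- sum(y == 0 & p == 0)
  bacc <- (tp / (tp + fn) + tn / (tn + fp)) / 2
  if (tp + fp == 0) {
    warning("no predicted positives; F1 defined as 0")
    f1 <- 0
  } else {
    prec <- tp / (tp + fp); rec <- tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }
  list(acc = acc, bacc = bacc, f1 = f1)
}

#' Full fairness/performance report for one prediction set
#'
#' @param data a `grouped_scores` with `predicted_label` set.
#' @return One-row data.frame with columns acc, bacc, f1, eop, eod.
#' @export
fairness_report <- function(data) {
  conf <- confusion_by_group(data)
  perf <- performance(data)
  data.frame(acc = perf$acc, bacc = perf$bacc, f1 = perf$f1,
             eop = eop(conf), eod = eod(conf))
}

#' Cliff's delta effect size
#'
#' Nonparametric dominance effect size between two samples:
#' `delta = (#\{x > y\} - #\{x < y\}) / (nx * ny)`, in [-1, 1]. Computed via
#' the midrank identity with the Mann-Whitney statistic (ties contribute
#' zero), which avoids the quadratic pair enumeration. An absolute value of
#' 0.428 or more is flagged as a large effect.
#'
#' @param x,y non-empty numeric vectors (e.g. a metric after vs before an
#'   intervention).
#' @param large_threshold threshold for the large-effect flag (default 0.428).
#' @return List with `delta` and logical `large`.
#' @export
cliffs_delta <- function(x, y, large_threshold = 0.428) {
  if (!length(x) || !length(y))
    stop_fairpost("both samples must be non-empty", "fairpost_invalid_argument")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))          # midranks handle ties
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  delta <- 2 * u / (nx * ny) - 1
  # boundary-inclusive up to floating-point rounding of the rank arithmetic
  list(delta = delta, large = abs(delta) >= large_threshold - 1e-12)
}

#' Pairwise Spearman correlations between protected attributes
#'
#' Rank correlation between every pair of protected attribute columns, with
#' two-sided p-values from the asymptotic t approximation (binary attributes
#' always carry ties, so exact null distributions do not apply). Significance
#' is conventionally read at p < 0.05.
#'
#' @param dataset a `tabular_dataset` with at least two protected attributes.
#' @return List with symmetric matrices `rho` and `p` (diagonal: 1 and NA).
#' @export
spearman_attr_corr <- function(dataset) {
  P <- dataset$protected
  if (ncol(P) < 2L)
    stop_fairpost("at least two protected attributes are required",
                  "fairpost_invalid_argument")
  for (nm in names(P)) if (length(unique(P[[nm]])) < 2L)
    stop_fairpost(sprintf("attribute '%s' is constant; correlation undefined", nm),
                  "fairpost_undefined_correlation")
  k <- ncol(P); n <- nrow(P)
  rho <- diag(1, k); pmat <- matrix(NA_real_, k, k)
  dimnames(rho) <- dimnames(pmat) <- list(names(P), names(P))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    r <- stats::cor(rank(P[[i]]), rank(P[[j]]))
    p <- if (abs(r) >= 1) 0 else {
      tval <- r * sqrt((n - 2) / (1 - r^2))
      2 * stats::pt(-abs(tval), df = n - 2)
    }
    rho[i, j] <- rho[j, i] <- r
    pmat[i, j] <- pmat[j, i] <- p
  }
  list(rho = rho, p = pmat)
}
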