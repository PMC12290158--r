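POLICY_KINDS <- c("identity", "group_thresholds", "flip_region",
                  "mixing_rates", "flip_rates", "score_corrections")

#' Construct a post-processing decision policy
#'
#' A decision policy is the transform a debiasing method learns and later
#' applies to a model's scores without retraining. Kinds:
#' \describe{
#'   \item{identity}{threshold scores at 0.5.}
#'   \item{group_thresholds}{per-group thresholds `theta0`, `theta1` in [0,1].}
#'   \item{flip_region}{symmetric margin `margin` around the 0.5 boundary;
#'     inside it, unprivileged instances are labeled favorable and privileged
#'     ones unfavorable (reject-option rule).}
#'   \item{mixing_rates}{per-group probabilities `p` of replacing the score
#'     with that group's constant base-rate predictor `const` (randomized).}
#'   \item{flip_rates}{per-group, per-predicted-label probabilities of
#'     emitting the favorable label, as a 2x2 matrix `p_out1` with rows =
#'     group (0, 1) and columns = base label (0, 1) (randomized).}
#'   \item{score_corrections}{an ordered list of additive logit corrections
#'     learned from residuals; applying it requires the feature matrix.}
#' }
#'
#' @param kind one of the kinds above.
#' @param params kind-specific parameter list (see Details).
#' @param seed default seed for randomized application; can be overridden in
#'   [apply_policy()].
#' @return A `decision_policy`.
#' @export
decision_policy <- function(kind, params = list(), seed = 1L) {
  kind <- match.arg(kind, POLICY_KINDS)
  chk01 <- function(x, what) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
      stop_fairpost(sprintf("%s must lie in [0, 1]", what), "fairpost_invalid_argument")
  }
  switch(kind,
    group_thresholds = chk01(c(params$theta0, params$theta1), "thresholds"),
    flip_region = chk01(params$margin, "margin"),
    mixing_rates = { chk01(params$p, "mixing probabilities"); chk01(params$const, "constants") },
    flip_rates = chk01(params$p_out1, "flip probabilities"),
    score_corrections = stopifnot(is.list(params$rounds), is.numeric(params$eta)),
    identity = NULL)
  structure(list(kind = kind, params = params, seed = as.integer(seed)),
            class = "decision_policy")
}

#' @export
print.decision_policy <- function(x, ...) {
  cat(sprintf("<decision_policy: %s>\n", x$kind))
  utils::str(x$params, give.attr = FALSE)
  invisible(x)
}

is_randomized_policy <- function(policy)
  policy$kind %in% c("mixing_rates", "flip_rates")

#' Apply a decision policy to scored instances
#'
#' Deterministic policies are idempotent in the labels they produce;
#' randomized policies (mixing_rates, flip_rates) draw from a seeded stream
#' and are reproducible given the seed.
#'
#' @param policy a `decision_policy`.
#' @param data a `grouped_scores`.
#' @param seed seed for randomized policies; defaults to the policy's own.
#' @param features numeric matrix of features, required for
#'   `score_corrections` policies (which never see the protected attribute).
#' @return Integer vector of predicted labels in \{0, 1\}.
#' @export
apply_policy <- function(policy, data, seed = NULL, features = NULL) {
  stopifnot(inherits(policy, "decision_policy"), inherits(data, "grouped_scores"))
  s <- data$score
  g <- data$group
  base <- threshold_labels(s)
  needs_group <- policy$kind %in% c("group_thresholds", "flip_region",
                                    "mixing_rates", "flip_rates")
  if (needs_group && is.null(g))
    stop_fairpost("policy is group-aware but data has no groups", "fairpost_schema_error")
  seed <- seed %||% policy$seed
  switch(policy$kind,
    identity = base,
    group_thresholds = {
      th <- ifelse(g == 0L, policy$params$theta0, policy$params$theta1)
      as.integer(s >= th)
    },
    flip_region = {
      m <- policy$params$margin
      lab <- base
      inside <- s >= 0.5 - m & s <= 0.5 + m
      lab[inside & g == 0L] <- 1L
      lab[inside & g == 1L] <- 0L
      lab
    },
    mixing_rates = {
      p <- policy$params$p        # length 2: group 0, group 1
      const <- policy$params$const
      withr::with_seed(seed, {
        mix <- stats::runif(length(s)) < p[g + 1L]
        s2 <- ifelse(mix, const[g + 1L], s)
        threshold_labels(s2)
      })
    },
    flip_rates = {
      P <- policy$params$p_out1   # 2x2: [group + 1, base label + 1]
      pr <- P[cbind(g + 1L, base + 1L)]
      withr::with_seed(seed, as.integer(stats::runif(length(s)) < pr))
    },
    score_corrections = {
      if (is.null(features))
        stop_fairpost("score_corrections policies require the feature matrix",
                      "fairpost_schema_error")
      threshold_labels(correct_scores(policy, s, as.matrix(features)))
    })
}

# Replay the accepted auditor rounds of a score_corrections policy.
correct_scores <- function(policy, score, X) {
  eta <- policy$params$eta
  eps <- 1e-6
  s <- clamp(score, eps, 1 - eps)
  for (rd in policy$params$rounds) {
    pred <- drop(sweep(X, 2, rd$center) %*% rd$beta) + rd$intercept
    s <- stats::plogis(stats::qlogis(clamp(s, eps, 1 - eps)) + eta * pred)
  }
  s
}

#' Expected post-policy group rates for a label-flipping policy
#'
#' For a `flip_rates` policy the randomized output's expected TPR/FPR per
#' group are linear in the flip probabilities; this computes them from a base
#' confusion, which is how equalized-odds constraint satisfaction is checked
#' without Monte-Carlo noise. Identity policies return the base rates.
#'
#' @param policy a `decision_policy` of kind `flip_rates` or `identity`.
#' @param conf the `group_confusion` of the base (threshold-0.5) labels.
#' @return List with vectors `tpr` and `fpr`, each indexed by group (g0, g1).
#' @export
expected_group_rates <- function(policy, conf) {
  stopifnot(inherits(conf, "group_confusion"))
  base <- list(tpr = c(conf$g0$tpr, conf$g1$tpr),
               fpr = c(conf$g0$fpr, conf$g1$fpr))
  if (policy$kind == "identity") return(base)
  if (policy$kind != "flip_rates")
    stop_fairpost("expected rates are defined for flip_rates/identity policies",
                  "fairpost_invalid_argument")
  P <- policy$params$p_out1
  tpr <- P[, 2] * base$tpr + P[, 1] * (1 - base$tpr)
  fpr <- P[, 2] * base$fpr + P[, 1] * (1 - base$fpr)
  list(tpr = tpr, fpr = fpr)
}

#' Serialize a decision policy to JSON
#'
#' Kind, parameters and seed round-trip exactly, enabling replay of any
#' stored benchmark run.
#'
#' @param policy a `decision_policy`.
#' @return A JSON string.
#' @export
policy_to_json <- function(policy) {
  p <- policy$params
  if (policy$kind == "flip_rates") p$p_out1 <- as.vector(p$p_out1)
  # 17 significant digits round-trip IEEE doubles exactly; thresholds are
  # often set to exact score values, so lossy printing could flip labels.
  jsonlite::toJSON(list(kind = policy$kind, params = p, seed = policy$seed),
                   auto_unbox = TRUE, digits = I(17))
}

#' @rdname policy_to_json
#' @param json a JSON string produced by `policy_to_json`.
#' @export
policy_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  params <- obj$params
  if (obj$kind == "flip_rates")
    params$p_out1 <- matrix(unlist(params$p_out1), 2, 2)
  if (obj$kind == "score_corrections")
    params$rounds <- lapply(params$rounds, function(rd)
      list(center = as.numeric(unlist(rd$center)),
           beta = as.numeric(unlist(rd$beta)),
           intercept = as.numeric(rd$intercept)))
  decision_policy(obj$kind, params, seed = obj$seed)
}
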