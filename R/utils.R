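`%||%` <- function(a, b) if (is.null(a)) b else a

# round() in R rounds half to even; demanded cell counts use half-up so that
# the achieved rate never undershoots the target by a full unit.
round_half_up <- function(x) floor(x + 0.5)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a named substream seed from a master seed
#'
#' All randomness in the package flows from a single integer seed fanned out
#' into named substreams (data, folds, policies, mutations, ...) so that, for
#' example, fold assignment does not depend on how many datasets were
#' simulated beforehand.
#'
#' @param seed master integer seed.
#' @param name substream name (character scalar).
#' @return An integer seed below 2^31, deterministic in `(seed, name)`.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes)) %% 65537
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483629)
}

stop_fairpost <- function(msg, class) {
  stop(structure(class = c(class, "fairpost_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}
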