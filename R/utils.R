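#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn .data
#' @importFrom stats coef cor glm binomial plogis pchisq pf pt qnorm rnorm
#'   runif rpois rbinom rlnorm sd setNames optim optimHess t.test p.adjust
#'   complete.cases
#' @importFrom utils head
NULL

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# stream; seed = NULL uses the current stream.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) {
    expr
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1].", name))
  }
  x
}

# Numerically stable log(sum(exp(x))).
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# z-score a vector; constant input maps to 0 (callers warn where relevant).
zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Column fallbacks used across response-table consumers.
resp_clean_col <- function(tbl) {
  if ("response_clean" %in% names(tbl)) tbl$response_clean
  else normalize_response(tbl$response_raw)
}
session_col <- function(tbl) {
  if ("session" %in% names(tbl)) tbl$session else tbl$participant
}
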