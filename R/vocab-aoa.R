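#' Estimate a word's age of acquisition from production norms
#'
#' Fits a logistic regression of production on age across children and
#' returns the age at which the fitted probability of production is 0.5,
#' i.e. `-intercept / slope`. A word gets status `"no_aoa"` when the fitted
#' slope is not positive, the fit is degenerate, or the estimated crossing
#' age exceeds `max_month` (the word is not produced by half the children
#' within the assessment window); such words are excluded from trajectories.
#'
#' Fits that fail to converge (typically quasi-separated production curves)
#' are retried with Firth's bias-reducing penalized likelihood, which always
#' yields finite estimates.
#'
#' @param production A production table (`child`, `age`, `word`, `produces`).
#' @param word The word to fit.
#' @param max_month Oldest assessment age in months.
#' @return A one-row tibble with `word`, `aoa`, `slope`, `status`.
#' @export
fit_word_aoa <- function(production, word, max_month = 30) {
  rows <- production[production$word == word, ]
  if (nrow(rows) == 0L) {
    abort(sprintf("word '%s' absent from the production table", word))
  }
  agg <- dplyr::count(rows, .data$age, wt = .data$produces, name = "k")
  agg$n <- dplyr::count(rows, .data$age)$n
  fit_aoa_curve(word, agg$age, agg$k, agg$n, max_month)
}

# Shared per-word fitting on (age, successes, trials) aggregates.
fit_aoa_curve <- function(word, age, k, n, max_month) {
  no_aoa <- tibble::tibble(word = word, aoa = NA_real_, slope = NA_real_,
                           status = "no_aoa")
  if (length(unique(age)) < 2L || sum(k) == 0L || sum(k) == sum(n)) {
    return(no_aoa)
  }
  fit <- suppressWarnings(
    try(glm(cbind(k, n - k) ~ age, family = binomial()), silent = TRUE)
  )
  b <- if (!inherits(fit, "try-error") && fit$converged) {
    coef(fit)
  } else {
    firth_logistic(age, k, n)
  }
  if (is.null(b) || any(!is.finite(b)) || b[2L] <= 0) return(no_aoa)
  aoa <- unname(-b[1L] / b[2L])
  if (!is.finite(aoa) || aoa > max_month) return(no_aoa)
  tibble::tibble(word = word, aoa = aoa, slope = unname(b[2L]), status = "ok")
}

#' Estimate ages of acquisition for every word in a production table
#'
#' Applies [fit_word_aoa()] to each word. The returned table is the input
#' for [build_trajectory()] after filtering to `status == "ok"`.
#'
#' @inheritParams fit_word_aoa
#' @return A tibble with one row per word: `word`, `aoa`, `slope`, `status`.
#' @export
fit_aoa <- function(production, max_month = 30) {
  agg <- production |>
    dplyr::group_by(.data$word, .data$age) |>
    dplyr::summarise(k = sum(.data$produces), n = dplyr::n(),
                     .groups = "drop")
  agg |>
    dplyr::group_by(.data$word) |>
    dplyr::group_map(~ fit_aoa_curve(.y$word, .x$age, .x$k, .x$n,
                                     max_month)) |>
    dplyr::bind_rows()
}

# Firth-penalized logistic regression of successes/trials on age.
# IRLS with the hat-diagonal score correction; returns c(intercept, slope).
firth_logistic <- function(age, k, n, max_iter = 100, tol = 1e-8) {
  X <- cbind(1, age)
  b <- c(0, 0)
  for (i in seq_len(max_iter)) {
    p <- plogis(drop(X %*% b))
    W <- n * p * (1 - p)
    XWX <- crossprod(X, X * W)
    inv <- try(solve(XWX), silent = TRUE)
    if (inherits(inv, "try-error")) return(NULL)
    h <- rowSums((X %*% inv) * X) * W
    U <- drop(crossprod(X, k - n * p + h * (0.5 - p)))
    step <- drop(inv %*% U)
    b <- b + step
    if (max(abs(step)) < tol) break
  }
  setNames(b, c("(Intercept)", "age"))
}

new_trajectory <- function(tbl, months) {
  structure(tbl, months = as.integer(months),
            class = c("vocab_trajectory", class(tbl)))
}

#' Build a monthly vocabulary trajectory from AoA estimates
#'
#' Buckets each word by the first month at which it counts as known: a word
#' is known at month `m` iff its estimated AoA is `<= m` (ties at integer
#' months go to the earlier month), so the bucket is `ceiling(aoa)`. Words
#' with AoA at or below the first month form the initial vocabulary and
#' carry the first month as their bucket.
#'
#' @param estimates AoA estimates (from [fit_aoa()]), all with status
#'   `"ok"`; rows with `status == "no_aoa"` are rejected and must be
#'   filtered out by the caller.
#' @param months Integer vector of assessment months.
#' @return A `vocab_trajectory`: a tibble (`word`, `bucket`, `aoa`) with a
#'   `months` attribute. Derive vocabularies with [known_at()] /
#'   [unknown_at()].
#' @export
#' @examples
#' est <- tibble::tibble(word = c("a", "b", "c"),
#'                       aoa = c(15.2, 16.4, 29.5), status = "ok")
#' traj <- build_trajectory(est)
#' known_at(traj, 16)
build_trajectory <- function(estimates, months = 16:30) {
  stopifnot(all(c("word", "aoa") %in% names(estimates)))
  if ("status" %in% names(estimates) && any(estimates$status != "ok")) {
    abort("`estimates` contains status 'no_aoa' rows; filter them first.")
  }
  if (any(!is.finite(estimates$aoa))) abort("all `aoa` values must be finite.")
  months <- sort(as.integer(months))
  m0 <- months[1L]
  bucket <- pmax(m0, as.integer(ceiling(estimates$aoa)))
  if (any(bucket > max(months))) {
    abort("some AoA estimates exceed the final month; drop them first.")
  }
  new_trajectory(
    tibble::tibble(word = estimates$word, bucket = bucket,
                   aoa = estimates$aoa),
    months = months
  )
}

#' Words known (acquired) at a given month
#' @param traj A `vocab_trajectory`.
#' @param month Integer month.
#' @return Character vector of words with bucket at or before `month`.
#' @export
known_at <- function(traj, month) {
  stopifnot(inherits(traj, "vocab_trajectory"))
  traj$word[!is.na(traj$bucket) & traj$bucket <= month]
}

#' Words still unknown at a given month
#'
#' Includes words never acquired within the window (bucket `NA`).
#' @inheritParams known_at
#' @export
unknown_at <- function(traj, month) {
  stopifnot(inherits(traj, "vocab_trajectory"))
  traj$word[is.na(traj$bucket) | traj$bucket > month]
}
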