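#' Assemble a predictor matrix for the softmax acquisition model
#'
#' Combines static word-level predictors (psycholinguistic covariates such
#' as phoneme count, corpus frequency, phonotactic probability,
#' neighborhood density) with optional month-varying growth-value columns.
#' Static columns are z-standardized across words (recommended so that
#' coefficient magnitudes are comparable); growth values enter as their
#' within-month z-scores and are left untouched.
#'
#' @param norms Data frame with a `word` column and numeric covariate
#'   columns; every word that can ever be scored must appear.
#' @param growth Optional growth value table ([monthly_growth_table()]) or
#'   a named list of them (names become column prefixes, e.g. one table per
#'   network); each contributes one column per selected model whose value
#'   for a word at month `m` is its z-score in month `m`.
#' @param models Growth models to include from `growth`.
#' @param months Months at which choice sets are formed (the prediction
#'   months); defaults to the growth tables' months, or `16:29`.
#' @param standardize Z-standardize the static columns?
#' @return A `predictor_matrix`: list with `words`, `months`, `columns`,
#'   and `X` (a list of word-by-column matrices, one per month).
#' @export
build_predictor_matrix <- function(norms, growth = NULL,
                                   models = c("attachment", "acquisition",
                                              "lure"),
                                   months = NULL, standardize = TRUE) {
  stopifnot(is.data.frame(norms), "word" %in% names(norms))
  words <- norms$word
  static_cols <- setdiff(names(norms), "word")
  S <- as.matrix(norms[, static_cols, drop = FALSE])
  if (any(!is.finite(S))) abort("non-finite values among static predictors.")
  if (standardize && ncol(S) > 0L) S <- apply(S, 2, zscore)

  growth_list <- if (is.null(growth)) {
    list()
  } else if (is.data.frame(growth)) {
    list(growth = growth)
  } else {
    growth
  }
  months <- months %||% (
    if (length(growth_list) > 0L) sort(unique(growth_list[[1L]]$month))
    else 16:29
  )

  gcols <- character()
  lookup <- list()
  for (nm in names(growth_list)) {
    g <- growth_list[[nm]]
    for (mod in intersect(models, unique(g$model))) {
      col <- if (length(growth_list) == 1L && nm == "growth") {
        mod
      } else {
        paste(nm, mod, sep = "_")
      }
      gcols <- c(gcols, col)
      sub <- g[g$model == mod, c("word", "month", "z")]
      lookup[[col]] <- sub
    }
  }

  X <- lapply(months, function(m) {
    M <- matrix(0, length(words), length(gcols),
                dimnames = list(words, gcols))
    for (col in gcols) {
      sub <- lookup[[col]]
      sub_m <- sub[sub$month == m, ]
      M[match(sub_m$word, words), col] <- sub_m$z
    }
    cbind(S, M)
  })
  names(X) <- as.character(months)
  structure(
    list(words = words, months = as.integer(months),
         columns = c(static_cols, gcols), X = X),
    class = "predictor_matrix"
  )
}

# Resolve scored events: for each prediction month m, the words acquired at
# m + 1 (learners) and the choice set of all words unknown at m. All
# learners of a month share one denominator (no within-month depletion).
scoring_sets <- function(predictors, traj, include_final_month = TRUE) {
  months <- predictors$months
  traj_months <- attr(traj, "months")
  m_last <- traj_months[length(traj_months)]
  sets <- list()
  for (m in months) {
    if (!include_final_month && m + 1L >= m_last) next
    learners <- traj$word[!is.na(traj$bucket) & traj$bucket == m + 1L]
    if (length(learners) == 0L) next
    unknown <- unknown_at(traj, m)
    li <- match(learners, predictors$words)
    ui <- match(unknown, predictors$words)
    if (anyNA(li) || anyNA(ui)) {
      abort("trajectory words missing from the predictor matrix.")
    }
    sets[[as.character(m)]] <- list(month = m, learners = li, unknown = ui)
  }
  sets
}

#' Softmax acquisition log-likelihood
#'
#' The probability that word `i` (acquired in month `m + 1`) was the one
#' learned is a ratio of strengths over the words unknown at month `m`:
#' `p_i = exp(beta . x_i) / sum_j exp(beta . x_j)`, `j` ranging over that
#' month's unknown words. The log-likelihood sums `log p_i` over all scored
#' acquisitions, computed with log-sum-exp stabilization.
#'
#' @param beta Numeric coefficient vector (one per predictor column).
#' @param predictors A `predictor_matrix`.
#' @param traj A `vocab_trajectory`.
#' @param include_final_month Score words acquired in the trajectory's
#'   final month? (Their choice set is the previous month's unknown set.)
#' @return The log-likelihood (a nonpositive number).
#' @export
log_likelihood <- function(beta, predictors, traj,
                           include_final_month = TRUE) {
  sets <- scoring_sets(predictors, traj, include_final_month)
  softmax_loglik(beta, predictors, sets)
}

softmax_loglik <- function(beta, predictors, sets) {
  ll <- 0
  for (s in sets) {
    eta <- drop(predictors$X[[as.character(s$month)]] %*% beta)
    ll <- ll + sum(eta[s$learners]) -
      length(s$learners) * logsumexp(eta[s$unknown])
  }
  ll
}

softmax_grad <- function(beta, predictors, sets) {
  g <- numeric(length(beta))
  for (s in sets) {
    Xm <- predictors$X[[as.character(s$month)]]
    eta <- drop(Xm %*% beta)
    eu <- eta[s$unknown]
    w <- exp(eu - max(eu))
    w <- w / sum(w)
    g <- g + colSums(Xm[s$learners, , drop = FALSE]) -
      length(s$learners) * drop(crossprod(Xm[s$unknown, , drop = FALSE], w))
  }
  g
}

#' Fit the softmax acquisition model by maximum likelihood
#'
#' Maximizes the [log_likelihood()] over the coefficient vector with
#' quasi-Newton (BFGS) optimization from a zero start, using the analytic
#' softmax gradient, and verifies the optimum with one restart from a
#' deterministic perturbed start (keeping the better of the two).
#' Standard errors come from the inverse observed information at the
#' optimum. Exactly collinear predictor columns trigger a warning (the
#' likelihood is still well defined, but individual coefficients are not
#' identified and their standard errors are reported as `NA`).
#'
#' @param predictors A `predictor_matrix`.
#' @param traj A `vocab_trajectory`.
#' @param include_final_month Score final-month acquisitions (default TRUE;
#'   the Figure-4-style at-acquisition analyses exclude them instead).
#' @param restart Run the perturbed-start convergence check?
#' @param reltol Relative convergence tolerance passed to [stats::optim()].
#' @return A `model_fit`: list with `beta`, `se`, `logL`, `k`, `n_events`,
#'   `converged`, `columns`.
#' @export
fit_acquisition <- function(predictors, traj, include_final_month = TRUE,
                            restart = TRUE, reltol = 1e-12) {
  stopifnot(inherits(predictors, "predictor_matrix"))
  k <- length(predictors$columns)
  if (k == 0L) abort("at least one predictor column is required.")
  sets <- scoring_sets(predictors, traj, include_final_month)
  n_events <- sum(vapply(sets, function(s) length(s$learners), integer(1)))
  if (n_events == 0L) abort("no scored acquisitions in the trajectory.")

  Xall <- do.call(rbind, unname(predictors$X))
  qrX <- qr(Xall)
  if (qrX$rank < k) {
    warn("predictor columns are collinear; coefficients are not identified.")
  }

  nll <- function(b) -softmax_loglik(b, predictors, sets)
  ngr <- function(b) -softmax_grad(b, predictors, sets)
  ctl <- list(maxit = 1000L, reltol = reltol)
  opt <- optim(rep(0, k), nll, ngr, method = "BFGS", control = ctl)
  if (restart) {
    start2 <- 0.25 * rep_len(c(1, -1), k)
    opt2 <- optim(start2, nll, ngr, method = "BFGS", control = ctl)
    if (opt2$value < opt$value) opt <- opt2
  }

  H <- optimHess(opt$par, nll, ngr)
  se <- rep(NA_real_, k)
  Hinv <- try(solve(H), silent = TRUE)
  if (!inherits(Hinv, "try-error")) {
    d <- diag(Hinv)
    se[d > 0] <- sqrt(d[d > 0])
  }

  structure(
    list(beta = setNames(opt$par, predictors$columns),
         se = setNames(se, predictors$columns),
         logL = -opt$value, k = k, n_events = n_events,
         converged = opt$convergence == 0L,
         columns = predictors$columns),
    class = "model_fit"
  )
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit> logL = %.3f, k = %d, events = %d%s\n",
              x$logL, x$k, x$n_events,
              if (x$converged) "" else " (NOT converged)"))
  print(round(rbind(beta = x$beta, se = x$se), 4))
  invisible(x)
}

#' Likelihood-ratio statistic and BIC from two log-likelihoods
#'
#' `chi2 = 2 * (logL_full - logL_restricted)`, compared to a chi-squared
#' distribution with `df` degrees of freedom, and a BIC difference on the
#' "large positive favours the full model" convention:
#' `bic = chi2 - df * log(n)`.
#'
#' @param logL0,logL1 Restricted and full log-likelihoods.
#' @param df Difference in parameter count.
#' @param n Number of observations for the BIC penalty.
#' @return A tibble with `chi2`, `df`, `p`, `bic`.
#' @export
lrt_bic <- function(logL0, logL1, df, n) {
  chi2 <- 2 * (logL1 - logL0)
  tibble::tibble(
    chi2 = chi2,
    df = as.integer(df),
    p = pchisq(chi2, df, lower.tail = FALSE),
    bic = chi2 - df * log(n)
  )
}

#' Compare two nested softmax model fits
#'
#' The restricted model's columns must be a strict subset of the full
#' model's, and both must be fit on the same scoring set. The BIC sample
#' size defaults to the number of scored acquisition events but can be
#' overridden.
#'
#' @param restricted,full `model_fit` objects from [fit_acquisition()].
#' @param n Observations for the BIC penalty (default: scored events).
#' @return A one-row tibble `chi2`, `df`, `p`, `bic` (add FDR-adjusted
#'   p-values across a family of comparisons with [fdr_adjust()]).
#' @export
compare_nested <- function(restricted, full, n = NULL) {
  stopifnot(inherits(restricted, "model_fit"), inherits(full, "model_fit"))
  if (!all(restricted$columns %in% full$columns) ||
      length(restricted$columns) >= length(full$columns)) {
    abort("`restricted` must be strictly nested within `full`.")
  }
  if (restricted$n_events != full$n_events) {
    abort("fits were scored on different acquisition sets.")
  }
  n <- n %||% full$n_events
  lrt_bic(restricted$logL, full$logL, full$k - restricted$k, n)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values via [stats::p.adjust()]; input outside
#' `[0, 1]` is an error rather than being clipped.
#'
#' @param pvalues Numeric vector of p-values.
#' @return Adjusted p-values, same length and order.
#' @export
fdr_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(pvalues, method = "BH")
}
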