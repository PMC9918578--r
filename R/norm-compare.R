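#' Annotate association responses with word-level norms
#'
#' Joins a norm table (frequency, length, age-of-acquisition ratings, ...)
#' onto each cleaned response. Unmatched responses are dropped or flagged
#' according to `policy`, and the number affected is reported via a
#' message.
#'
#' @param table A response table; responses are normalized before lookup.
#' @param norms Data frame keyed by `word` with numeric covariate columns.
#' @param policy `"drop"` removes unmatched rows; `"flag"` keeps them with
#'   `NA` covariates and a logical `norm_matched` column.
#' @return The augmented tibble.
#' @export
attach_norms <- function(table, norms, policy = c("drop", "flag")) {
  policy <- match.arg(policy)
  stopifnot(is.data.frame(norms), "word" %in% names(norms))
  if (nrow(norms) == 0L) abort("`norms` must be non-empty.")
  norms <- dplyr::distinct(norms, .data$word, .keep_all = TRUE)
  out <- tibble::as_tibble(table)
  if (!"response_clean" %in% names(out)) {
    out$response_clean <- normalize_response(out$response_raw)
  }
  out <- dplyr::left_join(out, norms,
                          by = c(response_clean = "word"))
  matched <- out$response_clean %in% norms$word
  n_miss <- sum(!matched)
  if (n_miss > 0L) {
    rlang::inform(sprintf("%d of %d responses lack norm coverage (%s)",
                          n_miss, nrow(out), policy))
  }
  if (policy == "drop") {
    out[matched, ]
  } else {
    out$norm_matched <- matched
    out
  }
}

#' Per-unit cell means for a two-factor within design
#'
#' Averages a dependent variable within each unit x factorA x factorB cell
#' (typically cue x condition x response order, or word x network x growth
#' model). Units missing any cell are dropped listwise, with the count
#' reported.
#'
#' @param data Data frame containing the columns named below.
#' @param dependent Column name of the dependent variable.
#' @param unit,factor_a,factor_b Column names of the unit identifier and
#'   the two within factors.
#' @return A tibble `unit`, `factor_a`, `factor_b`, `value` with complete
#'   crossing for every retained unit.
#' @export
cell_means <- function(data, dependent, unit = "cue",
                       factor_a = "condition", factor_b = "position") {
  stopifnot(all(c(dependent, unit, factor_a, factor_b) %in% names(data)))
  cells <- data |>
    dplyr::group_by(unit = .data[[unit]],
                    factor_a = factor(.data[[factor_a]]),
                    factor_b = factor(.data[[factor_b]])) |>
    dplyr::summarise(value = mean(.data[[dependent]], na.rm = TRUE),
                     .groups = "drop")
  n_cells <- nlevels(cells$factor_a) * nlevels(cells$factor_b)
  counts <- dplyr::count(cells, .data$unit)
  complete <- counts$unit[counts$n == n_cells]
  dropped <- dplyr::n_distinct(cells$unit) - length(complete)
  if (dropped > 0L) {
    rlang::inform(sprintf("%d unit(s) dropped for incomplete cells", dropped))
  }
  out <- cells[cells$unit %in% complete, ]
  if (nrow(out) == 0L) abort("no unit has a complete factor crossing.")
  out
}

#' Two-factor fully-within repeated-measures ANOVA
#'
#' Classical univariate repeated-measures ANOVA on per-unit cell means with
#' both factors within units: each effect is tested against its own
#' effect-by-unit interaction, degrees of freedom are multiplied by the
#' Greenhouse-Geisser epsilon estimated from the covariance of the
#' effect's orthonormal contrast scores (epsilon is exactly 1 for
#' two-level factors), and effect size is generalized eta-squared with all
#' unit-related sums of squares in the denominator (the convention for
#' fully-within designs).
#'
#' @param cells Output of [cell_means()] (complete crossing per unit).
#' @return A tibble with one row per effect (`factor_a`, `factor_b`,
#'   `factor_a:factor_b`): `df1`, `df2` (corrected), `epsilon`, `F`, `p`,
#'   `eta_g2`.
#' @export
rm_anova_within <- function(cells) {
  stopifnot(all(c("unit", "factor_a", "factor_b", "value") %in% names(cells)))
  units <- sort(unique(as.character(cells$unit)))
  a_lev <- levels(factor(cells$factor_a))
  b_lev <- levels(factor(cells$factor_b))
  n <- length(units); p <- length(a_lev); q <- length(b_lev)
  if (n < 3L) abort("need at least 3 complete units.")

  Y <- array(NA_real_, dim = c(n, p, q))
  Y[cbind(match(as.character(cells$unit), units),
          match(as.character(cells$factor_a), a_lev),
          match(as.character(cells$factor_b), b_lev))] <- cells$value
  if (anyNA(Y)) abort("`cells` must contain a complete crossing per unit.")
  if (sd(c(Y)) == 0) abort("dependent variable is constant; F undefined.")

  G <- mean(Y)
  A_m <- apply(Y, 2, mean); B_m <- apply(Y, 3, mean)
  AB_m <- apply(Y, c(2, 3), mean)
  S_m <- apply(Y, 1, mean)
  AS_m <- apply(Y, c(1, 2), mean)
  BS_m <- apply(Y, c(1, 3), mean)

  ss_a <- n * q * sum((A_m - G)^2)
  ss_b <- n * p * sum((B_m - G)^2)
  ss_ab <- n * sum((AB_m - outer(A_m, rep(1, q)) -
                      outer(rep(1, p), B_m) + G)^2)
  ss_s <- p * q * sum((S_m - G)^2)
  ss_as <- q * sum((AS_m - outer(S_m, rep(1, p)) -
                      outer(rep(1, n), A_m) + G)^2)
  ss_bs <- p * sum((BS_m - outer(S_m, rep(1, q)) -
                      outer(rep(1, n), B_m) + G)^2)
  ss_tot <- sum((Y - G)^2)
  ss_abs <- ss_tot - ss_a - ss_b - ss_ab - ss_s - ss_as - ss_bs

  gg_eps <- function(Z, d) {
    # Z: n x levels matrix of contrast scores; d = effect df
    M <- contr.helmert(ncol(Z))
    M <- sweep(M, 2, sqrt(colSums(M^2)), "/")
    S <- stats::cov(Z %*% M)
    sum(diag(S))^2 / (d * sum(S^2))
  }
  Z_a <- apply(Y, c(1, 2), mean)
  Z_b <- apply(Y, c(1, 3), mean)
  Z_ab <- matrix(aperm(Y, c(1, 3, 2)), nrow = n)  # n x (q*p), b fastest
  Ma <- contr.helmert(p); Ma <- sweep(Ma, 2, sqrt(colSums(Ma^2)), "/")
  Mb <- contr.helmert(q); Mb <- sweep(Mb, 2, sqrt(colSums(Mb^2)), "/")
  Mab <- kronecker(Ma, Mb)  # matches b-fastest cell layout
  S_ab <- stats::cov(Z_ab %*% Mab)
  eps <- c(
    a = gg_eps(Z_a, p - 1),
    b = gg_eps(Z_b, q - 1),
    ab = sum(diag(S_ab))^2 / ((p - 1) * (q - 1) * sum(S_ab^2))
  )

  err_all <- ss_s + ss_as + ss_bs + ss_abs
  effect_row <- function(name, ss, df1, ss_err, df2, e) {
    # an exactly null effect (zero effect SS) is reported as F = 0, p = 1
    # even when its error stratum is also degenerate
    if (ss <= 1e-12 * ss_tot) {
      return(tibble::tibble(effect = name, df1 = df1 * e, df2 = df2 * e,
                            epsilon = e, F = 0, p = 1, eta_g2 = 0))
    }
    Fv <- (ss / df1) / (ss_err / df2)
    adj1 <- df1 * e
    adj2 <- df2 * e
    tibble::tibble(
      effect = name, df1 = adj1, df2 = adj2, epsilon = e,
      F = Fv, p = pf(Fv, adj1, adj2, lower.tail = FALSE),
      eta_g2 = ss / (ss + err_all)
    )
  }
  dplyr::bind_rows(
    effect_row("factor_a", ss_a, p - 1, ss_as, (p - 1) * (n - 1), eps[["a"]]),
    effect_row("factor_b", ss_b, q - 1, ss_bs, (q - 1) * (n - 1), eps[["b"]]),
    effect_row("factor_a:factor_b", ss_ab, (p - 1) * (q - 1), ss_abs,
               (p - 1) * (q - 1) * (n - 1), eps[["ab"]])
  )
}

#' Paired simple-effect test of factor A at one level of factor B
#'
#' Paired t-test (across units) of the difference between the two factor A
#' levels, restricted to one factor B level, with the 95% confidence
#' interval of the mean difference.
#'
#' @param cells Output of [cell_means()]; factor A must have two levels.
#' @param at The factor B level at which to test.
#' @return A one-row tibble `level`, `mean_diff`, `t`, `df`, `ci_lower`,
#'   `ci_upper`, `p`. The difference is first level minus second level of
#'   factor A (alphabetical).
#' @export
paired_simple_effects <- function(cells, at) {
  sub <- cells[as.character(cells$factor_b) == as.character(at), ]
  a_lev <- levels(factor(sub$factor_a))
  if (length(a_lev) != 2L) abort("factor A must have exactly two levels.")
  wide <- tidyr::pivot_wider(sub[, c("unit", "factor_a", "value")],
                             names_from = "factor_a",
                             values_from = "value")
  x <- wide[[a_lev[1]]]; y <- wide[[a_lev[2]]]
  if (sum(complete.cases(x, y)) < 2L) {
    abort("need at least two units with both factor A levels.")
  }
  tt <- t.test(x, y, paired = TRUE)
  tibble::tibble(
    level = as.character(at),
    mean_diff = unname(tt$estimate),
    t = unname(tt$statistic),
    df = unname(tt$parameter),
    ci_lower = tt$conf.int[1],
    ci_upper = tt$conf.int[2],
    p = tt$p.value
  )
}
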