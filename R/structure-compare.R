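#' Cue-by-cue similarity from binarized response profiles
#'
#' Binarizes the cue-by-response counts (any nonzero count becomes 1, so
#' response frequency does not dominate) and correlates each pair of cue
#' profiles with Pearson's r over the full response vocabulary.
#'
#' @param crosstab A `cue_response_matrix`.
#' @return A `similarity_matrix`: list with `cues` and the symmetric
#'   unit-diagonal correlation matrix `r`. Cues with empty profiles give
#'   `NA` correlations, with a warning.
#' @export
cue_similarity <- function(crosstab) {
  stopifnot(inherits(crosstab, "cue_response_matrix"))
  if (length(crosstab$cues) < 2L) abort("need at least two cues.")
  B <- crosstab$counts > 0
  r <- binary_cor(B)
  if (any(colSums(B) == 0L)) {
    warn("some cues have no responses; their correlations are NA")
  }
  structure(list(cues = crosstab$cues, r = r), class = "similarity_matrix")
}

# Pearson correlation between columns of a logical matrix via cross-counts;
# equivalent to stats::cor on the 0/1 matrix but much faster for the
# permutation null. Columns with zero variance give NA.
binary_cor <- function(B) {
  n <- nrow(B)
  s <- colSums(B)
  C <- crossprod(B)
  num <- n * C - outer(s, s)
  v <- n * s - s^2
  den <- sqrt(outer(v, v))
  r <- ifelse(den > 0, num / den, NA_real_)
  diag(r) <- ifelse(v > 0, 1, NA_real_)
  r
}

#' Representational similarity between two cue similarity matrices
#'
#' Spearman rank correlation between the strictly-lower-triangle entries
#' (diagonal excluded) of two similarity matrices over the same cues in the
#' same order. High values mean the two data sources imply similar
#' relational structure among the cues.
#'
#' @param simA,simB `similarity_matrix` objects with identical cue lists.
#' @return Spearman's rho (scalar).
#' @export
rsa <- function(simA, simB) {
  stopifnot(inherits(simA, "similarity_matrix"),
            inherits(simB, "similarity_matrix"))
  if (!identical(simA$cues, simB$cues)) {
    abort("cue sets/order differ between the two similarity matrices.")
  }
  lt <- lower.tri(simA$r)
  cor(simA$r[lt], simB$r[lt], method = "spearman", use = "complete.obs")
}

#' Split-half permutation null for representational similarity
#'
#' Pools both conditions' (cleaned) responses by cue, then repeatedly
#' splits each cue's participant sessions into random halves and recomputes
#' the full representational similarity analysis between the halves. The
#' resulting null distribution describes the similarity expected from an
#' arbitrary split of one homogeneous dataset; an observed cross-condition
#' similarity below it indicates the conditions carry genuinely different
#' relational structure. Sessions (participant triples), not individual
#' responses, are the splitting unit, preserving the response-set structure
#' within participants.
#'
#' @param tableA,tableB Response tables for the two conditions, sharing the
#'   cue list.
#' @param n_splits Number of random splits.
#' @param seed Optional integer seed.
#' @return An `rsa_result`: list with `rho_observed`, `null_values`,
#'   `null_mean`, `null_sd`, and `p_empirical` (proportion of null values
#'   at or below the observed).
#' @export
rsa_null <- function(tableA, tableB, n_splits = 1000, seed = NULL) {
  n_splits <- assert_count(n_splits, "n_splits", min = 1L)
  prep <- function(tbl) {
    tibble::tibble(
      session = session_col(tbl),
      cue = tbl$cue,
      response = resp_clean_col(tbl)
    )
  }
  a <- prep(tableA)
  b <- prep(tableB)
  cues <- sort(unique(a$cue))
  if (!setequal(cues, unique(b$cue))) {
    abort("the two tables must share the same cue list.")
  }
  pooled <- dplyr::bind_rows(
    dplyr::mutate(a, session = paste0("A_", .data$session)),
    dplyr::mutate(b, session = paste0("B_", .data$session))
  )
  vocab <- sort(unique(pooled$response))
  pooled$ridx <- match(pooled$response, vocab)

  # per cue: one response-index set per session
  by_cue <- lapply(cues, function(cu) {
    sub <- pooled[pooled$cue == cu, ]
    sets <- split(sub$ridx, sub$session)
    if (length(sets) < 2L) {
      abort(sprintf("cue '%s' has fewer than two sessions; cannot split", cu))
    }
    lapply(sets, unique)
  })

  profile_matrix <- function(sets_per_cue, pick) {
    B <- matrix(FALSE, length(vocab), length(cues))
    for (ci in seq_along(sets_per_cue)) {
      idx <- unlist(sets_per_cue[[ci]][pick[[ci]]], use.names = FALSE)
      B[unique(idx), ci] <- TRUE
    }
    B
  }
  rsa_between <- function(B1, B2) {
    r1 <- binary_cor(B1)
    r2 <- binary_cor(B2)
    lt <- lower.tri(r1)
    cor(r1[lt], r2[lt], method = "spearman", use = "complete.obs")
  }

  obs_pick_a <- lapply(by_cue, function(s) grepl("^A_", names(s)))
  rho_observed <- rsa_between(
    profile_matrix(by_cue, obs_pick_a),
    profile_matrix(by_cue, lapply(obs_pick_a, `!`))
  )

  null_values <- with_seed_if(seed, {
    vapply(seq_len(n_splits), function(i) {
      pick <- lapply(by_cue, function(s) {
        n <- length(s)
        half <- logical(n)
        half[sample.int(n, n %/% 2L)] <- TRUE
        half
      })
      rsa_between(profile_matrix(by_cue, pick),
                  profile_matrix(by_cue, lapply(pick, `!`)))
    }, numeric(1))
  })

  structure(
    list(rho_observed = rho_observed,
         null_values = null_values,
         null_mean = mean(null_values),
         null_sd = sd(null_values),
         p_empirical = mean(null_values <= rho_observed)),
    class = "rsa_result"
  )
}

#' @export
print.rsa_result <- function(x, ...) {
  cat(sprintf(
    "<rsa_result> observed rho = %.3f; null mean = %.3f (sd %.3f, %d splits); empirical p = %.3f\n",
    x$rho_observed, x$null_mean, x$null_sd, length(x$null_values),
    x$p_empirical
  ))
  invisible(x)
}

#' Taxonomic within/between distance ratio of a network
#'
#' Computes directed shortest-path distances between all ordered node
#' pairs, partitions pairs by whether the two words share a category, and
#' reports the ratio of the mean within-category distance to the mean
#' between-category distance. Ratios below 1 indicate taxonomic structure
#' (same-category words are closer). Unreachable pairs are excluded from
#' the means, with the excluded fraction reported.
#'
#' @param net A `semantic_network`.
#' @param categories Named vector (or word -> label function of a data
#'   frame with `word`, `category`) giving each node's category.
#' @return A `taxonomic_result` list: `within_mean`, `between_mean`,
#'   `ratio`, `excluded_fraction`, `n_within`, `n_between`.
#' @export
taxonomic_ratio <- function(net, categories) {
  stopifnot(inherits(net, "semantic_network"))
  if (is.data.frame(categories)) {
    categories <- setNames(categories$category, categories$word)
  }
  labels <- categories[net$nodes]
  if (anyNA(labels)) abort("every node needs a category label.")
  if (length(unique(labels)) < 2L) {
    abort("need at least two categories among the nodes.")
  }
  D <- igraph::distances(as_igraph(net), mode = "out")
  same <- outer(labels, labels, "==")
  off <- !diag(TRUE, length(net$nodes))
  w <- D[same & off]
  b <- D[!same & off]
  excluded <- (sum(!is.finite(w)) + sum(!is.finite(b))) / (length(w) + length(b))
  w <- w[is.finite(w)]
  b <- b[is.finite(b)]
  structure(
    list(within_mean = mean(w), between_mean = mean(b),
         ratio = mean(w) / mean(b), excluded_fraction = excluded,
         n_within = length(w), n_between = length(b)),
    class = "taxonomic_result"
  )
}

#' BCa bootstrap confidence interval for a statistic
#'
#' Nonparametric bias-corrected and accelerated interval via
#' [boot::boot()] and [boot::boot.ci()]: the bias correction comes from the
#' bootstrap distribution's position relative to the point estimate and the
#' acceleration from jackknife skewness. A degenerate (constant) bootstrap
#' distribution collapses to a zero-width interval with a warning.
#'
#' @param data Vector or data frame of resampling units.
#' @param statistic Function of a resample of `data` returning a scalar.
#' @param n_boot Number of bootstrap replicates.
#' @param conf Confidence level.
#' @param seed Optional integer seed.
#' @return A tibble with `estimate`, `lower`, `upper`.
#' @export
bca_interval <- function(data, statistic, n_boot = 1000, conf = 0.95,
                         seed = NULL) {
  n_boot <- assert_count(n_boot, "n_boot", min = 1L)
  take <- if (is.data.frame(data)) {
    function(d, i) statistic(d[i, , drop = FALSE])
  } else {
    function(d, i) statistic(d[i])
  }
  with_seed_if(seed, {
    bt <- boot::boot(data, take, R = n_boot)
    est <- bt$t0
    if (sd(bt$t) == 0) {
      warn("degenerate bootstrap distribution; interval collapses to a point")
      return(tibble::tibble(estimate = est, lower = est, upper = est))
    }
    ci <- boot::boot.ci(bt, conf = conf, type = "bca")
    tibble::tibble(estimate = est,
                   lower = ci$bca[1, 4], upper = ci$bca[1, 5])
  })
}
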