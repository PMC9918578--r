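#' Simulate a child-directed-speech corpus with planted co-occurrence
#' structure
#'
#' Generates utterances as token sequences over the lexicon words. Token
#' sampling follows word frequency; after the first token of an utterance,
#' words sharing the semantic category of the previous token are favoured by
#' `within_category_boost`, planting elevated within-category co-occurrence
#' that windowed co-occurrence networks should recover.
#'
#' @param lexicon A lexicon from [gen_lexicon()].
#' @param n_utterances Number of utterances.
#' @param within_category_boost Multiplier (>= 1) on the sampling weight of
#'   words in the same category as the preceding token; 1 plants no
#'   structure.
#' @param seed Optional integer seed.
#' @param mean_length Mean utterance length in tokens (lengths are
#'   `1 + Poisson(mean_length - 1)`); the default reflects the short
#'   utterances typical of speech to toddlers.
#' @param freq_exponent Exponent applied to lexicon frequencies before
#'   normalizing into token sampling weights. Checklist words are all
#'   common in speech to children, so their usage distribution is flatter
#'   than raw corpus frequencies; the default dampens the skew.
#' @return A character vector of utterances (tokens separated by single
#'   spaces), one element per utterance.
#' @export
gen_corpus <- function(lexicon, n_utterances, within_category_boost = 2,
                       seed = NULL, mean_length = 5, freq_exponent = 0.5) {
  n_utterances <- assert_count(n_utterances, "n_utterances")
  if (within_category_boost < 1) {
    abort("`within_category_boost` must be >= 1.")
  }
  if (n_utterances == 0L) return(character())

  with_seed_if(seed, {
    n <- nrow(lexicon)
    base_w <- lexicon$frequency^freq_exponent
    base_w <- base_w / sum(base_w)
    cats <- sort(unique(lexicon$category))
    # next-token weights depend only on the previous token's category,
    # so token positions are sampled in category-grouped batches
    w_after <- lapply(cats, function(cc) {
      w <- base_w
      same <- lexicon$category == cc
      w[same] <- w[same] * within_category_boost
      w
    })
    names(w_after) <- as.character(cats)
    lens <- 1L + rpois(n_utterances, max(0, mean_length - 1))
    max_len <- max(lens)
    toks <- matrix(0L, n_utterances, max_len)
    toks[, 1L] <- sample.int(n, n_utterances, replace = TRUE, prob = base_w)
    if (max_len > 1L) {
      for (t in seq.int(2L, max_len)) {
        alive <- which(lens >= t)
        if (length(alive) == 0L) break
        prev_cat <- lexicon$category[toks[alive, t - 1L]]
        for (cc in unique(prev_cat)) {
          idx <- alive[prev_cat == cc]
          toks[idx, t] <- sample.int(n, length(idx), replace = TRUE,
                                     prob = w_after[[as.character(cc)]])
        }
      }
    }
    words <- lexicon$word
    vapply(seq_len(n_utterances), function(u) {
      paste(words[toks[u, seq_len(lens[u])]], collapse = " ")
    }, character(1))
  })
}

#' Simulate an acquisition trajectory from a known softmax model
#'
#' The generative inverse of the softmax acquisition model fitted by
#' [fit_acquisition()]: starting from an initial vocabulary, at each month a
#' configured number of still-unknown words is drawn without replacement
#' with probability proportional to `exp(beta_true . x)`, and each drawn
#' word is bucketed as acquired in the following month. With
#' `beta_true = 0` the acquisition order is uniformly random; with one very
#' large coefficient the order sorts by that predictor.
#'
#' @param predictors A data frame with a `word` column and one numeric
#'   column per name in `beta_true`, covering every word.
#' @param beta_true Named numeric coefficient vector.
#' @param initial_known Character vector of words known at the first month.
#' @param month_range Integer vector of months (default 16:30); draws happen
#'   at each month except the last, and words drawn at month m are bucketed
#'   at month m + 1.
#' @param words_per_month Integer vector (recycled) of how many words are
#'   acquired into each month after the first; `NULL` uses a ramp that grows
#'   linearly across months (few words early, many late, echoing CDI norm
#'   trajectories) and consumes all words by the final month.
#' @param seed Optional integer seed.
#' @return A `vocab_trajectory` object (see [build_trajectory()]); words
#'   never drawn (possible with an explicit `words_per_month`) get bucket
#'   `NA` and are treated as never acquired.
#' @export
simulate_acquisition <- function(predictors, beta_true, initial_known,
                                 month_range = 16:30,
                                 words_per_month = NULL, seed = NULL) {
  stopifnot(is.data.frame(predictors), "word" %in% names(predictors))
  if (length(initial_known) == 0L) {
    abort("`initial_known` must be nonempty.")
  }
  if (!all(initial_known %in% predictors$word)) {
    abort("`initial_known` contains words absent from `predictors`.")
  }
  if (is.null(names(beta_true)) ||
      !all(names(beta_true) %in% names(predictors))) {
    abort("`beta_true` must be named after columns of `predictors`.")
  }
  months <- sort(as.integer(month_range))
  learn_months <- months[-1L]

  words <- predictors$word
  X <- as.matrix(predictors[, names(beta_true), drop = FALSE])
  if (any(!is.finite(X))) abort("predictor values must be finite.")
  eta <- drop(X %*% beta_true)

  n_free <- length(words) - length(initial_known)
  if (is.null(words_per_month)) {
    ramp <- seq_along(learn_months)
    wpm <- floor(n_free * ramp / sum(ramp))
    rem <- n_free - sum(wpm)
    if (rem > 0) {
      top <- order(ramp, decreasing = TRUE)[seq_len(rem)]
      wpm[top] <- wpm[top] + 1L
    }
  } else {
    wpm <- rep_len(as.integer(words_per_month), length(learn_months))
  }

  with_seed_if(seed, {
    bucket <- setNames(rep(NA_integer_, length(words)), words)
    bucket[initial_known] <- months[1L]
    unknown <- setdiff(words, initial_known)
    for (k in seq_along(learn_months)) {
      n_draw <- wpm[k]
      if (n_draw > length(unknown)) {
        abort(sprintf(
          "month %d requests %d words but only %d remain unknown",
          learn_months[k], n_draw, length(unknown)
        ))
      }
      if (n_draw > 0L) {
        idx <- match(unknown, words)
        w <- exp(eta[idx] - max(eta[idx]))
        drawn <- unknown[sample.int(length(unknown), n_draw, prob = w)]
        bucket[drawn] <- learn_months[k]
        unknown <- setdiff(unknown, drawn)
      }
    }
    new_trajectory(tibble::tibble(word = words, bucket = unname(bucket[words])),
                   months = months)
  })
}
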