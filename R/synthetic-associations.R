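#' Ground truth settings for the synthetic study
#'
#' Bundles the quantities the synthetic generators condition on, so that
#' every downstream estimate has a known recovery target: the coefficient
#' vector of the softmax acquisition model, the size of the child-oriented
#' context effect on association responses, the cue-by-word sampling kernel,
#' and the rates at which contaminated (screenable) participants are planted.
#'
#' @param beta_true Named numeric vector of true softmax coefficients over
#'   predictor columns (used by [simulate_acquisition()]).
#' @param condition_effect Nonnegative real; the child-oriented condition
#'   tilts response sampling weights by `exp(-condition_effect * z(true_aoa))`,
#'   shifting responses toward earlier-acquired (and, through the covariate
#'   correlations, higher-frequency) words. 0 means the two conditions are
#'   sampled identically.
#' @param similarity_kernel Optional cue x word nonnegative weight matrix
#'   (dimnames = lexicon words). `NULL` builds a default kernel at sampling
#'   time: within-category words are favoured and weights scale with log
#'   frequency.
#' @param contamination_rates Named rates in `[0, 1]` for planted violator
#'   participants: `multiword`, `non_english`, `nonunique`, `attention`.
#' @param seed Integer seed used by generators that take this object.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(beta_true = c(acquisition = 1),
                         condition_effect = 1,
                         similarity_kernel = NULL,
                         contamination_rates = c(multiword = 0,
                                                 non_english = 0,
                                                 nonunique = 0,
                                                 attention = 0),
                         seed = 1L) {
  stopifnot(is.numeric(beta_true), is.numeric(condition_effect),
            condition_effect >= 0)
  rates <- c(multiword = 0, non_english = 0, nonunique = 0, attention = 0)
  rates[names(contamination_rates)] <- contamination_rates
  assert_prob(rates, "contamination_rates")
  structure(
    list(beta_true = beta_true,
         condition_effect = condition_effect,
         similarity_kernel = similarity_kernel,
         contamination_rates = rates,
         seed = as.integer(seed)),
    class = "ground_truth"
  )
}

#' Default cue-by-word association sampling kernel
#'
#' Word-association responses are heavily concentrated: a handful of strong
#' associates attract most responses, with a long Zipf-like tail. The
#' default kernel reproduces this: each cue gets `n_strong` strong
#' associates (drawn preferentially from its own semantic category and from
#' frequent words) holding `concentration` of the sampling mass with
#' 1/rank weights, over a weak frequency-scaled background. This keeps
#' association networks sparse, the way empirical association networks are
#' sparse relative to co-occurrence networks.
#'
#' @param lexicon A lexicon from [gen_lexicon()].
#' @param category_boost Preference for same-category words when drawing
#'   the strong-associate sets and in the background weights.
#' @param n_strong Strong associates per cue.
#' @param concentration Share of sampling mass on the strong associates.
#' @param seed Integer seed for drawing the strong-associate sets.
#' @return A cue x word weight matrix with zero diagonal.
#' @export
default_similarity_kernel <- function(lexicon, category_boost = 3,
                                      n_strong = 12, concentration = 0.9,
                                      seed = 1L) {
  n <- nrow(lexicon)
  freq_w <- exp(0.4 * zscore(log10(lexicon$frequency)))
  same_cat <- outer(lexicon$category, lexicon$category, "==")
  base <- (1 + (category_boost - 1) * same_cat) *
    matrix(freq_w, n, n, byrow = TRUE)
  diag(base) <- 0
  ns <- min(n_strong, n - 1L)
  kernel <- with_seed_if(seed, {
    K <- matrix(0, n, n)
    for (ci in seq_len(n)) {
      bg <- base[ci, ] / sum(base[ci, ])
      strong <- sample.int(n, ns, prob = base[ci, ])
      row <- (1 - concentration) * bg
      row[strong] <- row[strong] + concentration *
        (1 / seq_len(ns)) / sum(1 / seq_len(ns))
      K[ci, ] <- row
    }
    K
  })
  dimnames(kernel) <- list(lexicon$word, lexicon$word)
  kernel
}

#' Simulate a multi-response word-association study
#'
#' Cues (all lexicon words) are partitioned into lists of at most
#' `cues_per_participant`, and each list is answered by
#' `n_participants_per_cue` participants, three responses per cue, mirroring
#' the list design of large multi-response norming studies. Responses are
#' sampled without replacement from a cue-specific weight distribution over
#' the lexicon plus an out-of-lexicon response pool; clean participants do
#' not reuse a response within their session (so with all contamination
#' rates at zero no participant crosses a screening threshold, provided the
#' response pool is at least three times the list length). In the `"child"`
#' condition the sampling weights are exponentially tilted toward
#' earlier-acquired words by `ground_truth$condition_effect`, emulating the
#' simpler responses adults give once a child-oriented context is
#' established.
#'
#' Planted violators deterministically cross their screening thresholds:
#' multi-word violators get 40% two-word responses (threshold 30%),
#' non-English violators 50% junk-token responses (threshold 40%),
#' non-unique violators repeat their first response in 30% of later slots
#' (threshold 20%), and attention violators answer the engagement question
#' with colours other than red/white/blue. The planted violation is
#' recorded in the `planted` column so screening can be verified.
#'
#' @param lexicon A lexicon from [gen_lexicon()]; its words are the cues.
#' @param n_participants_per_cue Participants responding to each cue.
#' @param condition `"adult"` or `"child"`.
#' @param ground_truth A [ground_truth()] object.
#' @param out_of_lexicon Probability that a response slot is drawn from the
#'   out-of-lexicon pool rather than the lexicon.
#' @param n_out_pool Size of the out-of-lexicon response pool.
#' @param cues_per_participant Maximum cue-list length per participant.
#' @return A tibble (one row per participant x cue x position) with columns
#'   `participant`, `session`, `condition`, `cue`, `position`,
#'   `response_raw`, `attention_answer`, `planted`.
#' @export
gen_association_study <- function(lexicon, n_participants_per_cue = 100,
                                  condition = c("adult", "child"),
                                  ground_truth = lexnetgrow::ground_truth(),
                                  out_of_lexicon = 0.15,
                                  n_out_pool = 50,
                                  cues_per_participant = 33) {
  condition <- match.arg(condition)
  n_pp <- assert_count(n_participants_per_cue, "n_participants_per_cue",
                       min = 1L)
  stopifnot(inherits(ground_truth, "ground_truth"))
  n_words <- nrow(lexicon)

  # the two conditions must share one kernel, so its construction is seeded
  # by the ground truth alone, independent of condition
  kernel <- ground_truth$similarity_kernel %||%
    default_similarity_kernel(lexicon, seed = ground_truth$seed)
  if (condition == "child" && ground_truth$condition_effect > 0) {
    tilt <- exp(-ground_truth$condition_effect * zscore(lexicon$true_aoa))
    kernel <- sweep(kernel, 2, tilt, "*")
  }

  # Condition-specific sub-stream so the two conditions are independent.
  seed <- ground_truth$seed + ifelse(condition == "child", 1000L, 0L)

  with_seed_if(seed, {
    out_pool <- sprintf("xeno%03d", seq_len(n_out_pool))
    junk_pool <- sprintf("zqxv%03d", seq_len(n_out_pool))

    n_lists <- ceiling(n_words / cues_per_participant)
    list_of_cue <- rep_len(seq_len(n_lists), n_words)[sample.int(n_words)]

    rates <- ground_truth$contamination_rates
    resp_cols <- list()
    cue_cols <- list()
    id_vec <- character()
    planted_vec <- character()
    attention_vec <- character()
    n_rows_per <- integer()
    p_counter <- 0L
    for (li in seq_len(n_lists)) {
      cue_idx <- which(list_of_cue == li)
      n_cues <- length(cue_idx)
      for (pp in seq_len(n_pp)) {
        p_counter <- p_counter + 1L
        id <- sprintf("%s%04d", substr(condition, 1, 1), p_counter)
        planted <- "none"
        for (type in names(rates)) {
          if (planted == "none" && runif(1) < rates[[type]]) planted <- type
        }

        resp <- character(3L * n_cues)
        used <- character(0)
        for (k in seq_along(cue_idx)) {
          ci <- cue_idx[k]
          w <- kernel[ci, ]
          w[match(used, lexicon$word, nomatch = 0L)] <- 0
          n_avail <- sum(w > 0)
          out <- runif(3L) < out_of_lexicon
          avail_out <- setdiff(out_pool, used)
          # lexicon nearly exhausted: route the deficit through the
          # out-of-lexicon pool rather than repeating earlier responses
          short <- max(0L, 3L - sum(out) - n_avail)
          if (short > 0L) out[!out][seq_len(short)] <- TRUE
          n_out <- min(sum(out), length(avail_out))
          out[out][seq_len(sum(out) - n_out)] <- FALSE
          r <- character(3L)
          if (sum(!out) > 0L) {
            if (sum(w > 0) < sum(!out)) w <- kernel[ci, ]  # full fallback
            picks <- sample.int(n_words, sum(!out), prob = w + 1e-12)
            r[!out] <- lexicon$word[picks]
          }
          if (n_out > 0L) {
            r[out] <- sample(avail_out, n_out)
          }
          resp[(3L * (k - 1L) + 1L):(3L * k)] <- r
          used <- c(used, r)
        }

        n_resp <- length(resp)
        attention <- "red white blue"
        if (planted == "multiword") {
          idx <- sample.int(n_resp, ceiling(0.4 * n_resp))
          resp[idx] <- paste(resp[idx],
                             sample(lexicon$word, length(idx), replace = TRUE))
        } else if (planted == "non_english") {
          k <- ceiling(0.5 * n_resp)
          idx <- sample.int(n_resp, k)
          resp[idx] <- sample(junk_pool, k, replace = k > length(junk_pool))
        } else if (planted == "nonunique") {
          k <- ceiling(0.3 * n_resp)
          idx <- sample(seq.int(2L, n_resp), k)
          resp[idx] <- resp[1L]
        } else if (planted == "attention") {
          attention <- "green yellow"
        }

        resp_cols[[p_counter]] <- resp
        cue_cols[[p_counter]] <- rep(lexicon$word[cue_idx], each = 3L)
        id_vec[p_counter] <- id
        planted_vec[p_counter] <- planted
        attention_vec[p_counter] <- attention
        n_rows_per[p_counter] <- n_resp
      }
    }
    tibble::tibble(
      participant = rep(id_vec, times = n_rows_per),
      session = paste0(rep(id_vec, times = n_rows_per), "_s1"),
      condition = condition,
      cue = unlist(cue_cols, use.names = FALSE),
      position = rep.int(rep(1:3, length.out = 3L), sum(n_rows_per) %/% 3L),
      response_raw = unlist(resp_cols, use.names = FALSE),
      attention_answer = rep(attention_vec, times = n_rows_per),
      planted = rep(planted_vec, times = n_rows_per)
    )
  })
}
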