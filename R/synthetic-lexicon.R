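#' Generate a synthetic CDI-style lexicon with psycholinguistic covariates
#'
#' Creates a table of pseudo-words standing in for a toddler vocabulary
#' checklist (one row per word), each assigned to a semantic category and
#' given a full set of word-level covariates: a true age of acquisition (in
#' months, the ground truth that production norms and acquisition
#' trajectories are generated from), corpus frequency, contextual diversity,
#' length measures (letters, phonemes, syllables), phonotactic probability,
#' phonological neighborhood density, and an adult age-of-acquisition rating
#' in years. Covariates are correlated the way their empirical counterparts
#' are (frequent words are shorter, earlier-acquired, higher in contextual
#' diversity and neighborhood density).
#'
#' The defaults (598 words in 22 categories) mirror the size of the CDI
#' Words and Sentences node set used throughout the package.
#'
#' @param n_words Number of words to generate.
#' @param n_categories Number of semantic categories; words are assigned in
#'   a roughly balanced way.
#' @param seed Optional integer seed; a fixed seed gives an identical table.
#' @param aoa_range Numeric length-2 vector, the range (months) the true
#'   ages of acquisition are drawn from. The default extends slightly beyond
#'   the 16-30 month assessment window so that some words are already known
#'   at 16 months and some are not yet acquired by 30.
#' @return A tibble with one row per word and columns `word`, `category`,
#'   `true_aoa`, `frequency`, `contextual_diversity`, `letters`, `phonemes`,
#'   `syllables`, `phonotactic_probability`, `neighborhood_density`,
#'   `adult_aoa_rating`.
#' @export
#' @examples
#' lex <- gen_lexicon(30, 4, seed = 1)
#' table(lex$category)
gen_lexicon <- function(n_words, n_categories, seed = NULL,
                        aoa_range = c(14, 31)) {
  n_words <- assert_count(n_words, "n_words", min = 1L)
  n_categories <- assert_count(n_categories, "n_categories", min = 1L)
  if (n_words < n_categories) {
    abort("`n_words` must be at least `n_categories`.")
  }
  stopifnot(length(aoa_range) == 2L, aoa_range[1] < aoa_range[2])

  with_seed_if(seed, {
    word <- make_pseudowords(n_words)
    syllables <- pmax(1L, nchar(word) %/% 3L + (nchar(word) %% 3L > 1L))
    category <- sample(rep_len(seq_len(n_categories), n_words))
    true_aoa <- runif(n_words, aoa_range[1], aoa_range[2])

    # log10 frequency declines with AoA and length, with noise
    aoa_z <- zscore(true_aoa)
    len_z <- zscore(nchar(word))
    log_freq <- 3.5 - 0.4 * aoa_z - 0.3 * len_z + rnorm(n_words, sd = 0.5)
    frequency <- 10^log_freq
    contextual_diversity <- 10^(0.9 * log_freq - 0.3 + rnorm(n_words, sd = 0.2))

    letters <- nchar(word)
    phonemes <- pmax(1L, letters - rbinom(n_words, size = 2, prob = 0.4))
    phonotactic_probability <-
      plogis(rnorm(n_words, mean = -3 + 0.2 * len_z, sd = 0.5))
    neighborhood_density <-
      rpois(n_words, lambda = pmax(0.5, 18 * exp(-0.45 * (letters - 3))))
    adult_aoa_rating <- pmax(1, true_aoa / 12 + 2 + rnorm(n_words, sd = 0.8))

    tibble::tibble(
      word = word,
      category = category,
      true_aoa = true_aoa,
      frequency = frequency,
      contextual_diversity = contextual_diversity,
      letters = letters,
      phonemes = phonemes,
      syllables = syllables,
      phonotactic_probability = phonotactic_probability,
      neighborhood_density = neighborhood_density,
      adult_aoa_rating = adult_aoa_rating
    )
  })
}

# Deterministic pool of pronounceable CV(C) tokens, sampled without
# replacement so word tokens are always unique.
make_pseudowords <- function(n) {
  consonants <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t")
  vowels <- c("a", "e", "i", "o", "u")
  syl <- as.vector(outer(consonants, vowels, paste0))
  one <- syl
  two <- as.vector(outer(syl, syl, paste0))
  pool <- c(one, two)
  if (n > length(pool)) {
    three <- as.vector(outer(syl, two[seq_len(min(length(two), 200))], paste0))
    pool <- c(pool, three)
  }
  if (n > length(pool)) {
    abort(sprintf("cannot generate more than %d unique words", length(pool)))
  }
  sample(pool, n)
}

#' Generate synthetic CDI production norms
#'
#' Simulates a cross-sectional parent-report study: each child is assessed
#' once at a random age and for every word the parent reports whether the
#' child produces it. Production is Bernoulli with probability
#' `plogis(slope * (age - true_aoa))`, so the word's true age of acquisition
#' is exactly the age at which the probability of production crosses 0.5 --
#' the quantity [fit_word_aoa()] estimates.
#'
#' @param lexicon A lexicon from [gen_lexicon()] (needs `word`, `true_aoa`).
#' @param n_children Number of children in the norming sample.
#' @param age_range Integer months, inclusive assessment window.
#' @param slope Positive logistic slope per month; larger values give
#'   sharper production curves (`slope = Inf`-like behaviour can be
#'   approximated with a very large value, where each child produces
#'   exactly the words with `true_aoa <= age`).
#' @param seed Optional integer seed.
#' @return A tibble with columns `child`, `age`, `word`, `produces` and one
#'   row per child x word.
#' @export
gen_production_norms <- function(lexicon, n_children, age_range = c(16, 30),
                                 slope = 0.5, seed = NULL) {
  if (!is.data.frame(lexicon) || nrow(lexicon) == 0L) {
    abort("`lexicon` must be a non-empty lexicon table.")
  }
  n_children <- assert_count(n_children, "n_children")
  if (!is.numeric(slope) || slope <= 0) abort("`slope` must be > 0.")

  if (n_children == 0L) {
    return(tibble::tibble(
      child = character(), age = integer(),
      word = character(), produces = integer()
    ))
  }

  with_seed_if(seed, {
    ages <- sample(seq.int(age_range[1], age_range[2]), n_children,
                   replace = TRUE)
    grid <- tidyr::expand_grid(
      child = sprintf("c%05d", seq_len(n_children)),
      word = lexicon$word
    )
    grid$age <- rep(ages, each = nrow(lexicon))
    grid$true_aoa <- rep(lexicon$true_aoa, times = n_children)
    p <- plogis(slope * (grid$age - grid$true_aoa))
    grid$produces <- rbinom(nrow(grid), 1L, p)
    grid[, c("child", "age", "word", "produces")]
  })
}
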