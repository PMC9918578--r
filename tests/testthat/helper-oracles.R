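# Brute-force oracles and fixture builders shared across test files.
# Oracles deliberately use plain loops / direct definitions, independent of
# the package's vectorized implementations.

random_directed_network <- function(n, p, seed) {
  withr::with_seed(seed, {
    nodes <- sprintf("n%02d", seq_len(n))
    pairs <- expand.grid(source = nodes, target = nodes,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$source != pairs$target, ]
    keep <- runif(nrow(pairs)) < p
    semantic_network(nodes, pairs[keep, ])
  })
}

oracle_indegree <- function(net, node, within = net$nodes) {
  sum(vapply(seq_len(nrow(net$edges)), function(i) {
    net$edges$target[i] == node && net$edges$source[i] %in% within &&
      node %in% within
  }, logical(1)))
}

oracle_growth_value <- function(net, known, candidate, model) {
  e <- net$edges
  if (model == "acquisition") {
    return(sum(e$target == candidate))
  }
  if (model == "lure") {
    return(length(unique(e$source[e$target == candidate &
                                    e$source %in% known])))
  }
  # attachment: known neighbours in either direction, averaged indegree
  # within the known-induced subgraph
  nbrs <- unique(c(e$source[e$target == candidate & e$source %in% known],
                   e$target[e$source == candidate & e$target %in% known]))
  if (length(nbrs) == 0L) return(0)
  mean(vapply(nbrs, function(w) {
    sum(e$target == w & e$source %in% known & e$source != w)
  }, numeric(1)))
}

oracle_softmax_loglik <- function(beta, X_by_month, learners_by_month,
                                  unknown_by_month) {
  ll <- 0
  for (m in names(learners_by_month)) {
    X <- X_by_month[[m]]
    for (i in learners_by_month[[m]]) {
      num <- exp(sum(beta * X[i, ]))
      den <- 0
      for (j in unknown_by_month[[m]]) den <- den + exp(sum(beta * X[j, ]))
      ll <- ll + log(num / den)
    }
  }
  ll
}

oracle_crosstab_count <- function(records, cue, response) {
  n <- 0L
  for (i in seq_len(nrow(records))) {
    if (records$cue[i] == cue && records$response[i] == response) n <- n + 1L
  }
  n
}

oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

oracle_spearman <- function(x, y) {
  oracle_pearson(rank(x), rank(y))
}

# A 598-word trajectory with 18 initial words and 33 final-month learners,
# remaining acquisitions spread over months 17-29.
study_scale_trajectory <- function(seed = 1) {
  withr::with_seed(seed, {
    words <- sprintf("w%03d", 1:598)
    aoa <- c(runif(18, 14, 16),
             runif(547, 16.01, 29),
             runif(33, 29.01, 30))
    build_trajectory(tibble::tibble(word = words, aoa = aoa, status = "ok"))
  })
}

crosstab_from_counts <- function(counts) {
  lexnetgrow:::new_crosstab(counts, colnames(counts), rownames(counts),
                            "adult")
}
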