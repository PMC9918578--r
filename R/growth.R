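#' Growth value of a candidate word under a network growth model
#'
#' Quantifies how strongly a network growth model expects a currently
#' unknown word to be acquired next, given the vocabulary `known`:
#'
#' * `"attachment"` (preferential attachment): the average indegree, within
#'   the subgraph induced by the known words, of the known words the
#'   candidate shares an edge with in either direction; 0 when the
#'   candidate has no known neighbours. Growth is driven by the centrality
#'   of the words the new word would attach to.
#' * `"lure"` (lure of the associates): the number of known words with a
#'   directed edge into the candidate. Growth is driven by how many known
#'   words point at the unknown word.
#' * `"acquisition"` (preferential acquisition): the candidate's indegree
#'   in the full network, regardless of what is currently known. Growth is
#'   driven by centrality in the whole semantic environment.
#'
#' @param net A `semantic_network`.
#' @param known Character vector of known words (must not contain
#'   `candidate`).
#' @param candidate The unknown word to evaluate.
#' @param model One of `"attachment"`, `"acquisition"`, `"lure"`.
#' @return A single numeric growth value.
#' @export
#' @examples
#' ex <- toy_growth_example()
#' growth_value(ex$network, ex$known, ex$candidates[["acquisition"]],
#'              "acquisition")
growth_value <- function(net, known, candidate,
                         model = c("attachment", "acquisition", "lure")) {
  model <- match.arg(model)
  stopifnot(inherits(net, "semantic_network"))
  if (!candidate %in% net$nodes) {
    abort(sprintf("candidate '%s' is not a node", candidate))
  }
  if (!all(known %in% net$nodes)) abort("`known` contains non-nodes.")
  if (candidate %in% known) abort("`candidate` must not be in `known`.")

  A <- adjacency_matrix(net)
  growth_value_impl(A, match(known, net$nodes),
                    match(candidate, net$nodes), model)
}

# Matrix-indexed core shared with monthly_growth_table().
growth_value_impl <- function(A, known_idx, cand_idx, model) {
  switch(model,
    acquisition = sum(A[, cand_idx]),
    lure = sum(A[known_idx, cand_idx]),
    attachment = {
      nbr <- known_idx[A[known_idx, cand_idx] + A[cand_idx, known_idx] > 0]
      if (length(nbr) == 0L) return(0)
      indeg_known <- colSums(A[known_idx, known_idx, drop = FALSE])
      mean(indeg_known[match(nbr, known_idx)])
    }
  )
}

#' Worked example network for the three growth models
#'
#' A small undirected environment (encoded as a directed network with
#' reciprocal edges) with a six-word vocabulary and three candidate words,
#' constructed so that each growth model singles out a different candidate:
#' the attachment candidate connects to a vocabulary hub of
#' within-vocabulary degree 5, the lure candidate receives edges from three
#' known words, and the acquisition candidate has degree 5 in the full
#' environment (one known neighbour plus four unknown ones).
#'
#' @return A list with `network` (a `semantic_network`), `known` (the
#'   vocabulary), and `candidates` (named by the model each illustrates).
#' @export
toy_growth_example <- function() {
  known <- paste0("k", 1:6)
  candidates <- c(attachment = "red", lure = "blue", acquisition = "green")
  grey <- paste0("g", 1:4)
  und <- rbind(
    cbind("k1", c("k2", "k3", "k4", "k5", "k6")),  # hub: degree 5 in vocab
    c("k2", "k3"),
    cbind("red", "k1"),
    cbind("blue", c("k2", "k4", "k5")),
    cbind("green", c("k6", grey))
  )
  edges <- tibble::tibble(
    source = c(und[, 1], und[, 2]),
    target = c(und[, 2], und[, 1])
  )
  net <- semantic_network(c(known, candidates, grey), edges,
                          provenance = "manual")
  list(network = net, known = known, candidates = candidates)
}

#' Monthly growth values for all unknown words
#'
#' For each month, computes the raw growth value of every word still
#' unknown at that month under all three growth models, then standardizes
#' values to mean 0 and standard deviation 1 within each month-by-model
#' cell. Attachment and lure values change as the vocabulary grows;
#' preferential-acquisition raw values are constant across months by
#' definition.
#'
#' @param net A `semantic_network` whose nodes cover the trajectory words.
#' @param traj A `vocab_trajectory`.
#' @param months Months to evaluate (default: every trajectory month
#'   except the last, since growth values predict the next month's
#'   acquisitions).
#' @return A tibble `word`, `month`, `model`, `raw`, `z`.
#' @export
monthly_growth_table <- function(net, traj, months = NULL) {
  stopifnot(inherits(net, "semantic_network"),
            inherits(traj, "vocab_trajectory"))
  all_months <- attr(traj, "months")
  months <- months %||% all_months[-length(all_months)]
  if (!all(traj$word %in% net$nodes)) {
    abort("trajectory contains words that are not network nodes.")
  }

  A <- adjacency_matrix(net)
  node_idx <- match(traj$word, net$nodes)
  indeg_full <- colSums(A)

  out <- vector("list", length(months))
  for (mi in seq_along(months)) {
    m <- months[mi]
    known <- known_at(traj, m)
    unknown <- unknown_at(traj, m)
    if (length(unknown) == 0L) next
    k <- match(known, net$nodes)
    u <- match(unknown, net$nodes)

    acq <- indeg_full[u]
    if (length(k) == 0L) {
      lure <- rep(0, length(u))
      att <- rep(0, length(u))
    } else {
      Ak_u <- A[k, u, drop = FALSE]
      lure <- colSums(Ak_u)
      nbr <- (Ak_u + t(A[u, k, drop = FALSE])) > 0
      indeg_known <- colSums(A[k, k, drop = FALSE])
      n_nbr <- colSums(nbr)
      att <- ifelse(n_nbr == 0, 0, colSums(nbr * indeg_known) / n_nbr)
    }

    cell <- tibble::tibble(
      word = rep(unknown, 3L),
      month = m,
      model = rep(c("attachment", "acquisition", "lure"),
                  each = length(unknown)),
      raw = as.numeric(c(att, acq, lure))
    )
    out[[mi]] <- cell
  }
  res <- dplyr::bind_rows(out)
  res <- res |>
    dplyr::group_by(.data$month, .data$model) |>
    dplyr::mutate(z = {
      s <- sd(.data$raw)
      if (!is.finite(s) || s == 0) {
        warn(sprintf("constant growth values in month %d, model %s; z = 0",
                     .data$month[1], .data$model[1]))
        rep(0, dplyr::n())
      } else {
        (.data$raw - mean(.data$raw)) / s
      }
    }) |>
    dplyr::ungroup()
  res
}

#' Growth values at the month of acquisition
#'
#' Selects, for each word acquired after the initial month, its
#' standardized growth value in the month immediately preceding its
#' acquisition bucket -- the month at which the growth models should rank
#' it highest. Words acquired in the final month are excluded unless
#' `include_final_month = TRUE` (their preceding-month values exist, but
#' every remaining unknown word is acquired then, which some analyses
#' exclude); never-acquired words are always excluded.
#'
#' @param values A growth value table from [monthly_growth_table()].
#' @param traj The matching `vocab_trajectory`.
#' @param include_final_month Keep words acquired in the last month?
#' @return A tibble `word`, `model`, `month`, `z_at_acquisition`.
#' @export
at_acquisition <- function(values, traj, include_final_month = FALSE) {
  stopifnot(inherits(traj, "vocab_trajectory"))
  months <- attr(traj, "months")
  m0 <- months[1L]
  m_last <- months[length(months)]

  sel <- traj[!is.na(traj$bucket) & traj$bucket > m0, c("word", "bucket")]
  if (!include_final_month) sel <- sel[sel$bucket < m_last, ]
  sel$month <- sel$bucket - 1L

  out <- dplyr::inner_join(values, sel, by = c("word", "month"))
  if (nrow(out) != 3L * nrow(sel)) {
    abort("growth value table is missing rows for some acquired words.")
  }
  out |>
    dplyr::transmute(.data$word, .data$model, .data$month,
                     z_at_acquisition = .data$z)
}

#' One-sample t-tests of mean at-acquisition growth values
#'
#' Tests, per growth model, whether the mean standardized at-acquisition
#' value differs from zero -- zero being the expectation if the model were
#' uninformative about which words are learned next.
#'
#' @param values Output of [at_acquisition()].
#' @return A tibble per model: `n`, `mean`, `se`, `t`, `df`, `p`.
#' @export
at_acquisition_tests <- function(values) {
  values |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$z_at_acquisition),
      se = sd(.data$z_at_acquisition) / sqrt(dplyr::n()),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      t = .data$mean / .data$se,
      df = .data$n - 1L,
      p = 2 * pt(abs(.data$t), .data$df, lower.tail = FALSE)
    )
}
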