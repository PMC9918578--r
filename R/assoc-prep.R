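#' Normalize a raw association response
#'
#' Lower-cases, strips outer whitespace, collapses internal whitespace runs
#' to single spaces, and collapses any character repeated more than twice
#' consecutively down to two (`"loook"` becomes `"look"`), the standard
#' cleanup applied to typed free-association responses. Idempotent.
#'
#' @param raw Character vector of raw responses.
#' @return Character vector of cleaned responses (empty strings pass
#'   through; emptiness is handled by screening).
#' @export
#' @examples
#' normalize_response(c("loook", "  Dog ", "baaaa"))
normalize_response <- function(raw) {
  x <- tolower(trimws(raw))
  x <- stringr::str_squish(x)
  gsub("(.)\\1{2,}", "\\1\\1", x, perl = TRUE)
}

#' Screen association participants
#'
#' Applies per-session exclusion rules to cleaned responses: a session is
#' excluded when strictly more than `thresholds$multiword` of its responses
#' contain internal whitespace, strictly more than `thresholds$non_english`
#' contain a token absent from `english_wordlist`, strictly more than
#' `thresholds$nonunique` duplicate one of the participant's own earlier
#' responses in the session, or the attention-check answer is not a
#' combination of the expected colour words. Sessions with zero responses
#' are excluded with reason `"empty"`. Decisions depend only on the
#' multiset of responses per session, never on row order.
#'
#' @param table A response table with `participant`, `session`, `cue`,
#'   `position`, and `response_raw` (or `response_clean`) columns;
#'   optionally `attention_answer`.
#' @param english_wordlist Character vector of known-English word forms
#'   (compared after normalization).
#' @param thresholds Named list of exclusion proportions.
#' @param attention_key Acceptable attention-answer tokens; the answer
#'   passes iff its token set is a nonempty subset of this key.
#' @return A tibble with one row per session: the measured fractions,
#'   `attention_pass`, `excluded`, and `reason` (`"ok"`, `"empty"`,
#'   `"multiword"`, `"non_english"`, `"nonunique"`, `"attention"`).
#' @export
screen_participants <- function(table, english_wordlist,
                                thresholds = list(multiword = 0.30,
                                                  non_english = 0.40,
                                                  nonunique = 0.20),
                                attention_key = c("red", "white", "blue")) {
  stopifnot(all(unlist(thresholds) > 0), all(unlist(thresholds) < 1))
  resp <- resp_clean_col(table)
  wl <- unique(normalize_response(english_wordlist))

  # session order must not matter: sort responses within session by
  # (cue, position) before the duplicate scan
  df <- tibble::tibble(
    participant = table$participant,
    session = session_col(table),
    cue = table$cue,
    position = table$position,
    response = resp
  )
  att <- if ("attention_answer" %in% names(table)) {
    tibble::tibble(session = df$session, answer = table$attention_answer) |>
      dplyr::distinct(.data$session, .keep_all = TRUE)
  } else {
    NULL
  }

  df <- dplyr::arrange(df, .data$session, .data$cue, .data$position)
  reports <- df |>
    dplyr::group_by(.data$participant, .data$session) |>
    dplyr::summarise(
      n_responses = dplyr::n(),
      fraction_multiword = mean(grepl("\\s", .data$response)),
      fraction_non_english = mean(vapply(
        strsplit(.data$response, "\\s+"),
        function(tok) length(tok) == 0L || !all(tok %in% wl),
        logical(1)
      )),
      fraction_nonunique = mean(duplicated(.data$response)),
      .groups = "drop"
    )

  if (!is.null(att)) {
    reports <- dplyr::left_join(reports, att, by = "session")
    reports$attention_pass <- vapply(reports$answer, function(a) {
      tok <- strsplit(normalize_response(gsub("[,;]|\\band\\b", " ", a)),
                      "\\s+")[[1]]
      tok <- tok[nzchar(tok)]
      length(tok) > 0L && all(tok %in% attention_key)
    }, logical(1))
    reports$answer <- NULL
  } else {
    reports$attention_pass <- TRUE
  }

  reports$reason <- with(reports, dplyr::case_when(
    n_responses == 0L ~ "empty",
    fraction_multiword > thresholds$multiword ~ "multiword",
    fraction_non_english > thresholds$non_english ~ "non_english",
    fraction_nonunique > thresholds$nonunique ~ "nonunique",
    !attention_pass ~ "attention",
    TRUE ~ "ok"
  ))
  reports$excluded <- reports$reason != "ok"
  reports
}

#' Cap participants per cue and cross-tabulate cues by responses
#'
#' Drops excluded sessions, retains at most `max_per_cue` sessions per cue
#' (by a `timestamp` column when present, otherwise by order of first
#' appearance in the table), and counts how often each cleaned response was
#' given to each cue. The result is the raw material both for association
#' networks ([build_association_network()]) and for cue similarity
#' ([cue_similarity()]).
#'
#' @param table A response table (see [screen_participants()]).
#' @param reports Screening reports; sessions with `excluded == TRUE` are
#'   dropped. `NULL` retains everything.
#' @param max_per_cue Maximum retained sessions per cue.
#' @param condition Label stored on the result (defaults to the table's
#'   condition when unique).
#' @return A `cue_response_matrix`: list with `cues`, `responses`, integer
#'   `counts` (responses x cues), and `condition`.
#' @export
cap_and_crosstab <- function(table, reports = NULL, max_per_cue = 100,
                             condition = NULL) {
  resp <- resp_clean_col(table)
  df <- tibble::tibble(
    session = session_col(table),
    cue = table$cue,
    response = resp
  )
  if ("timestamp" %in% names(table)) {
    df$order_key <- xtfrm(table$timestamp)
  } else {
    df$order_key <- seq_len(nrow(df))
  }
  if (!is.null(reports)) {
    keep <- reports$session[!reports$excluded]
    df <- df[df$session %in% keep, ]
  }
  condition <- condition %||%
    (if ("condition" %in% names(table) &&
         dplyr::n_distinct(table$condition) == 1L) table$condition[1]
     else NA_character_)
  if (nrow(df) == 0L) {
    warn("no retained participants; returning an empty crosstab")
    return(new_crosstab(matrix(0L, 0, 0), character(), character(),
                        condition))
  }

  first_seen <- df |>
    dplyr::group_by(.data$cue, .data$session) |>
    dplyr::summarise(order_key = min(.data$order_key), .groups = "drop") |>
    dplyr::arrange(.data$cue, .data$order_key) |>
    dplyr::group_by(.data$cue) |>
    dplyr::slice_head(n = max_per_cue) |>
    dplyr::ungroup()
  df <- dplyr::semi_join(df, first_seen, by = c("cue", "session"))

  cues <- sort(unique(df$cue))
  responses <- sort(unique(df$response))
  counts <- matrix(0L, length(responses), length(cues),
                   dimnames = list(responses, cues))
  tab <- table(factor(df$response, levels = responses),
               factor(df$cue, levels = cues))
  counts[] <- as.integer(tab)
  new_crosstab(counts, cues, responses, condition)
}

new_crosstab <- function(counts, cues, responses, condition) {
  structure(
    list(cues = cues, responses = responses, counts = counts,
         condition = condition),
    class = "cue_response_matrix"
  )
}

#' @export
print.cue_response_matrix <- function(x, ...) {
  cat(sprintf(
    "<cue_response_matrix> %d cues x %d unique responses (%s), %d tokens\n",
    length(x$cues), length(x$responses),
    x$condition %||% "condition unset", sum(x$counts)
  ))
  invisible(x)
}
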