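#' Extract adult-speaker utterances from a CHAT (.cha) transcript
#'
#' A thin adapter over the CHAT transcript format: speaker roles are read
#' from `@ID` header lines (field 8 of the pipe-separated record), and main
#' tier lines (`*CODE:`) whose speaker's role matches `roles` are kept,
#' including tab-indented continuation lines. Dependent tiers (`%`) and
#' other headers are ignored. Tokens are lightly cleaned: bracketed and
#' angle-bracketed annotation groups, utterance terminators, `&`-prefixed
#' fragments and `@`-suffixed special forms are removed, the rest
#' lower-cased.
#'
#' Regularization (spelling variants, phrase merging such as `thank_you`,
#' special-token replacement) is the caller's responsibility via
#' `replace_map`, applied token-wise after cleaning.
#'
#' @param path Path to a `.cha` file.
#' @param roles Adult caretaker roles whose utterances to keep.
#' @param replace_map Optional named character vector mapping token ->
#'   replacement, applied after cleaning.
#' @return Character vector of utterances (space-separated tokens).
#' @export
read_chat_utterances <- function(path,
                                 roles = c("Adult", "Father", "Mother",
                                           "Aunt", "Uncle", "Grandmother",
                                           "Grandfather", "Teacher",
                                           "Babysitter", "Nurse", "Doctor",
                                           "Clinician", "Therapist"),
                                 replace_map = NULL) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")

  # speaker code -> role from @ID headers
  id_lines <- grep("^@ID:", lines, value = TRUE)
  role_of <- character()
  for (l in id_lines) {
    fields <- strsplit(sub("^@ID:\\s*", "", l), "\\|")[[1]]
    if (length(fields) >= 8L) role_of[fields[3L]] <- fields[8L]
  }
  keep_codes <- names(role_of)[role_of %in% roles]

  utterances <- character()
  current <- NULL
  keeping <- FALSE
  for (l in lines) {
    if (grepl("^\\*", l)) {
      if (keeping && !is.null(current)) {
        utterances <- c(utterances, current)
      }
      code <- sub("^\\*([^:]+):.*$", "\\1", l)
      keeping <- code %in% keep_codes
      current <- sub("^\\*[^:]+:\\s*", "", l)
    } else if (grepl("^\\t", l) && !grepl("^%", l) && !is.null(current)) {
      current <- paste(current, trimws(l))
    } else {
      if (keeping && !is.null(current)) {
        utterances <- c(utterances, current)
      }
      current <- NULL
      keeping <- FALSE
    }
  }
  if (keeping && !is.null(current)) utterances <- c(utterances, current)

  cleaned <- vapply(utterances, clean_chat_utterance, character(1),
                    USE.NAMES = FALSE)
  if (!is.null(replace_map)) {
    cleaned <- vapply(strsplit(cleaned, " "), function(tok) {
      hit <- tok %in% names(replace_map)
      tok[hit] <- unname(replace_map[tok[hit]])
      paste(tok[nzchar(tok)], collapse = " ")
    }, character(1))
  }
  cleaned[nzchar(cleaned)]
}

clean_chat_utterance <- function(x) {
  x <- gsub("\\[[^]]*\\]", " ", x)        # [...] annotation groups
  x <- gsub("[<>]", " ", x)               # retrace marks, keep content
  x <- gsub("\\x15[^\\x15]*\\x15", " ", x) # time alignment bullets
  toks <- strsplit(tolower(x), "\\s+")[[1]]
  toks <- toks[!grepl("^&", toks)]        # fillers/fragments
  toks <- sub("@.*$", "", toks)           # special-form markers
  toks <- gsub("[^a-z'_+-]", "", toks)
  toks <- toks[nzchar(toks)]
  paste(toks, collapse = " ")
}
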