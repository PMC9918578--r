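#' Write a semantic network as an edge-list CSV with a JSON sidecar
#'
#' The edge list (`source`, `target`) goes to `path`; nodes, provenance,
#' and construction parameters go to `<path>.json` so isolated nodes
#' survive the round trip.
#'
#' @param net A `semantic_network`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "semantic_network"))
  utils::write.csv(net$edges, path, row.names = FALSE)
  jsonlite::write_json(
    list(nodes = net$nodes, provenance = net$provenance,
         params = net$params),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' Read a semantic network written by [write_network()]
#' @param path CSV path previously passed to [write_network()].
#' @return A `semantic_network`.
#' @export
read_network <- function(path) {
  edges <- utils::read.csv(path, colClasses = "character")
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  semantic_network(meta$nodes, edges, provenance = meta$provenance,
                   params = as.list(meta$params))
}

#' Write a cue-by-response crosstab as sparse triplets
#'
#' One row per nonzero cell: `cue`, `response`, `count`.
#'
#' @param crosstab A `cue_response_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_crosstab <- function(crosstab, path) {
  stopifnot(inherits(crosstab, "cue_response_matrix"))
  hit <- which(crosstab$counts > 0L, arr.ind = TRUE)
  trip <- data.frame(
    cue = crosstab$cues[hit[, 2L]],
    response = crosstab$responses[hit[, 1L]],
    count = crosstab$counts[hit]
  )
  trip <- trip[order(trip$cue, trip$response), ]
  utils::write.csv(trip, path, row.names = FALSE)
  invisible(path)
}

#' Read a sparse-triplet crosstab written by [write_crosstab()]
#' @param path Triplet CSV path.
#' @param condition Optional condition label to attach.
#' @return A `cue_response_matrix`.
#' @export
read_crosstab <- function(path, condition = NA_character_) {
  trip <- utils::read.csv(path)
  cues <- sort(unique(trip$cue))
  responses <- sort(unique(trip$response))
  counts <- matrix(0L, length(responses), length(cues),
                   dimnames = list(responses, cues))
  counts[cbind(match(trip$response, responses), match(trip$cue, cues))] <-
    as.integer(trip$count)
  new_crosstab(counts, cues, responses, condition)
}

#' Write ground-truth settings as JSON
#' @param gt A [ground_truth()] object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(gt, path) {
  stopifnot(inherits(gt, "ground_truth"))
  jsonlite::write_json(unclass(gt), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
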