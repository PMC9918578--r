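#' Construct a directed semantic network object
#'
#' Networks are directed and unweighted over a fixed node (word) set.
#' Self-loops and duplicate edges are dropped; edges referencing unlisted
#' nodes are an error.
#'
#' @param nodes Character vector of node words (order is preserved).
#' @param edges Data frame with character columns `source`, `target`.
#' @param provenance `"association"`, `"cooccurrence"`, or `"manual"`.
#' @param params List of construction settings (stored, not interpreted).
#' @return An object of class `semantic_network`.
#' @export
semantic_network <- function(nodes, edges,
                             provenance = c("manual", "association",
                                            "cooccurrence"),
                             params = list()) {
  provenance <- match.arg(provenance)
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) abort("`nodes` must be unique.")
  edges <- tibble::tibble(source = as.character(edges$source),
                          target = as.character(edges$target))
  if (!all(edges$source %in% nodes) || !all(edges$target %in% nodes)) {
    abort("edges reference words absent from `nodes`.")
  }
  edges <- dplyr::distinct(edges[edges$source != edges$target, ])
  structure(
    list(nodes = nodes, edges = edges, provenance = provenance,
         params = params),
    class = "semantic_network"
  )
}

#' @export
print.semantic_network <- function(x, ...) {
  cat(sprintf("<semantic_network/%s> %d nodes, %d directed edges\n",
              x$provenance, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

# Dense 0/1 adjacency matrix A[i, j] = 1 iff edge i -> j.
adjacency_matrix <- function(net) {
  n <- length(net$nodes)
  A <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  A[cbind(match(net$edges$source, net$nodes),
          match(net$edges$target, net$nodes))] <- 1
  A
}

#' Convert a semantic network to an igraph graph
#' @param net A `semantic_network`.
#' @return An igraph directed graph with the same nodes and edges.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "semantic_network"))
  igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                vertices = net$nodes)
}

#' Collapse disambiguating sense labels on cue words
#'
#' Cue inventories may disambiguate homographs with a bracketed sense
#' (`"chicken [food]"`). For matching cues against free-text responses the
#' default collapse strips the bracketed qualifier, leaving the base token.
#'
#' @param x Character vector of cue labels.
#' @param map Optional named character vector of explicit replacements,
#'   applied after the bracket strip.
#' @return Character vector of collapsed labels.
#' @export
collapse_senses <- function(x, map = NULL) {
  out <- trimws(gsub("\\s*\\[[^]]*\\]", "", x))
  if (!is.null(map)) {
    hit <- out %in% names(map)
    out[hit] <- unname(map[out[hit]])
  }
  out
}

#' Build a directed association network from a cue-by-response crosstab
#'
#' Draws the edge `B -> A` whenever cue `A`'s (sense-collapsed) label was
#' given at least once as a response to cue `B`. Responses outside the node
#' set contribute no edges; the network is unweighted, so response counts
#' beyond the first do not matter.
#'
#' @param crosstab A `cue_response_matrix` from [cap_and_crosstab()].
#' @param node_set Character vector of words to retain as nodes (cues
#'   lacking any data become isolated nodes, with a warning).
#' @param sense_map Optional sense-collapse map (see [collapse_senses()]).
#' @return A `semantic_network` with provenance `"association"`.
#' @export
build_association_network <- function(crosstab, node_set, sense_map = NULL) {
  stopifnot(inherits(crosstab, "cue_response_matrix"))
  if (length(node_set) == 0L) abort("`node_set` must be nonempty.")
  node_set <- as.character(node_set)
  base_of_cue <- collapse_senses(crosstab$cues, sense_map)
  base_of_node <- collapse_senses(node_set, sense_map)

  missing_cues <- setdiff(base_of_node, base_of_cue)
  if (length(missing_cues) > 0L) {
    warn(sprintf("%d node(s) have no cue data and will be isolated",
                 length(missing_cues)))
  }

  edges <- list(source = character(), target = character())
  hit <- which(crosstab$counts >= 1L, arr.ind = TRUE)
  if (length(hit) > 0L) {
    resp_base <- collapse_senses(crosstab$responses[hit[, 1L]], sense_map)
    cue_node <- node_set[match(base_of_cue[hit[, 2L]], base_of_node)]
    resp_node <- node_set[match(resp_base, base_of_node)]
    ok <- !is.na(cue_node) & !is.na(resp_node)
    edges <- list(source = cue_node[ok], target = resp_node[ok])
  }
  semantic_network(node_set, tibble::tibble(source = edges$source,
                                            target = edges$target),
                   provenance = "association",
                   params = list(condition = crosstab$condition))
}

#' Build a directed co-occurrence network from an utterance corpus
#'
#' Slides a forward-looking window of `window` tokens over each utterance,
#' accruing evidence for a connection from the first token of the window to
#' each of the `window - 1` tokens that follow it. Windows are truncated at
#' utterance ends and never span utterance boundaries. A directed edge is
#' drawn when the accumulated tally reaches `min_count` and both endpoints
#' belong to `node_set`.
#'
#' @param corpus Character vector of utterances (whitespace-separated
#'   tokens) or a list of token vectors.
#' @param node_set Words to retain as nodes.
#' @param window Window length in tokens (>= 2); the default of five gives
#'   four forward neighbours per position.
#' @param min_count Minimum tally for an edge (>= 1). The default of 1
#'   draws an edge on any evidence of co-occurrence.
#' @return A `semantic_network` with provenance `"cooccurrence"`.
#' @export
build_cooccurrence_network <- function(corpus, node_set, window = 5,
                                       min_count = 1) {
  window <- assert_count(window, "window", min = 2L)
  if (!is.numeric(min_count) || min_count < 1) {
    abort("`min_count` must be >= 1.")
  }
  if (length(node_set) == 0L) abort("`node_set` must be nonempty.")
  toks <- if (is.list(corpus)) corpus else strsplit(corpus, "\\s+")

  tally <- cooccurrence_tally(toks, window)
  keep <- tally$source %in% node_set & tally$target %in% node_set &
    tally$n >= min_count
  semantic_network(node_set, tally[keep, c("source", "target")],
                   provenance = "cooccurrence",
                   params = list(window = window, min_count = min_count))
}

# Tally ordered co-occurrence pairs within forward windows, per utterance.
cooccurrence_tally <- function(token_lists, window) {
  vocab <- unique(unlist(token_lists, use.names = FALSE))
  if (length(vocab) == 0L) {
    return(tibble::tibble(source = character(), target = character(),
                          n = integer()))
  }
  src <- list()
  tgt <- list()
  i <- 0L
  for (toks in token_lists) {
    idx <- match(toks, vocab)
    len <- length(idx)
    if (len < 2L) next
    for (k in seq_len(window - 1L)) {
      if (len <= k) break
      i <- i + 1L
      src[[i]] <- idx[seq_len(len - k)]
      tgt[[i]] <- idx[seq.int(k + 1L, len)]
    }
  }
  if (i == 0L) {
    return(tibble::tibble(source = character(), target = character(),
                          n = integer()))
  }
  pair <- (unlist(src) - 1) * length(vocab) + unlist(tgt)
  cnt <- table(pair)
  code <- as.numeric(names(cnt))
  tibble::tibble(
    source = vocab[(code - 1) %/% length(vocab) + 1],
    target = vocab[(code - 1) %% length(vocab) + 1],
    n = as.integer(cnt)
  )
}

#' Degree table for a semantic network
#'
#' Indegree counts directed edges terminating on a node; outdegree counts
#' edges leaving it. With `restrict_to`, degrees are computed on the
#' subgraph induced by that node subset.
#'
#' @param net A `semantic_network`.
#' @param restrict_to Optional character vector of nodes inducing a
#'   subgraph; unknown nodes are an error.
#' @return A tibble `word`, `indegree`, `outdegree`, `scope`.
#' @export
degrees <- function(net, restrict_to = NULL) {
  stopifnot(inherits(net, "semantic_network"))
  scope <- "full"
  nodes <- net$nodes
  edges <- net$edges
  if (!is.null(restrict_to)) {
    if (!all(restrict_to %in% net$nodes)) {
      abort("`restrict_to` contains unknown nodes.")
    }
    scope <- "induced"
    nodes <- restrict_to
    edges <- edges[edges$source %in% nodes & edges$target %in% nodes, ]
  }
  tibble::tibble(
    word = nodes,
    indegree = as.integer(table(factor(edges$target, levels = nodes))),
    outdegree = as.integer(table(factor(edges$source, levels = nodes))),
    scope = scope
  )
}
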