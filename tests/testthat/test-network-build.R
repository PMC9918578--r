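test_that("semantic_network validates and deduplicates edges", {
  net <- semantic_network(
    c("a", "b"),
    data.frame(source = c("a", "a", "b", "a"), target = c("b", "b", "b", "a"))
  )
  expect_equal(nrow(net$edges), 1)  # duplicate dropped, self-loops dropped
  expect_error(semantic_network("a", data.frame(source = "a", target = "x")),
               "absent")
  expect_error(semantic_network(c("a", "a"), data.frame(source = character(),
                                                        target = character())),
               "unique")
})

test_that("association networks follow the cue -> response edge rule", {
  # response "dog" (a cue) given to cue "bone" yields edge bone -> dog
  tab <- tibble::tibble(
    participant = "p1", session = "p1",
    cue = c("bone", "bone", "bone"),
    position = 1:3,
    response_raw = c("dog", "fluffy", "bone")
  )
  ct <- cap_and_crosstab(tab, NULL)
  net <- suppressWarnings(
    build_association_network(ct, node_set = c("bone", "dog"))
  )
  expect_equal(net$edges, tibble::tibble(source = "bone", target = "dog"))
  # "fluffy" outside the node set contributes nothing; self response dropped

  # duplicating every record leaves the (unweighted) edge set unchanged
  ct2 <- cap_and_crosstab(dplyr::bind_rows(tab, tab), NULL)
  net2 <- suppressWarnings(
    build_association_network(ct2, node_set = c("bone", "dog"))
  )
  expect_equal(net2$edges, net$edges)
  expect_error(build_association_network(ct, character()), "nonempty")
})

test_that("sense-collapsed cue labels match base-form responses", {
  tab <- tibble::tibble(
    participant = "p1", session = "p1",
    cue = c("chicken [animal]", "chicken [animal]", "chicken [animal]"),
    position = 1:3,
    response_raw = c("egg", "farm", "water")
  )
  ct <- cap_and_crosstab(tab, NULL)
  net <- suppressWarnings(
    build_association_network(ct, node_set = c("chicken [animal]", "egg"))
  )
  expect_equal(net$edges$source, "chicken [animal]")
  expect_equal(net$edges$target, "egg")
  expect_equal(collapse_senses("chicken [food]"), "chicken")
})

test_that("co-occurrence windows look forward and stop at utterance ends", {
  nodes <- letters[1:6]
  net <- build_cooccurrence_network("a b c d e f", nodes, window = 5)
  # source `a` reaches exactly the 4 tokens after it
  expect_setequal(net$edges$target[net$edges$source == "a"],
                  c("b", "c", "d", "e"))
  # truncated window at the end: `e` only reaches `f`
  expect_setequal(net$edges$target[net$edges$source == "e"], "f")

  net2 <- build_cooccurrence_network("a b", nodes)
  expect_equal(net2$edges, tibble::tibble(source = "a", target = "b"))

  # single co-occurrence fails min_count = 2
  net3 <- build_cooccurrence_network("a b", nodes, min_count = 2)
  expect_equal(nrow(net3$edges), 0)
  expect_error(build_cooccurrence_network("a b", nodes, min_count = 0),
               ">= 1")

  # windows never cross utterance boundaries
  net4 <- build_cooccurrence_network(c("a b", "c d"), nodes)
  expect_false(any(net4$edges$source %in% c("a", "b") &
                     net4$edges$target %in% c("c", "d")))
  expect_false(any(net4$edges$source %in% c("c", "d") &
                     net4$edges$target %in% c("a", "b")))
})

test_that("co-occurrence edges ignore utterance order and respect counts", {
  withr::with_seed(5, {
    lex <- gen_lexicon(15, 3, seed = 16)
    corp <- gen_corpus(lex, 100, seed = 17)
    n1 <- build_cooccurrence_network(corp, lex$word, min_count = 2)
    n2 <- build_cooccurrence_network(sample(corp), lex$word, min_count = 2)
    key <- function(n) sort(paste(n$edges$source, n$edges$target))
    expect_identical(key(n1), key(n2))
    # min_count = 2 edge set is a subset of min_count = 1
    n0 <- build_cooccurrence_network(corp, lex$word, min_count = 1)
    expect_true(all(key(n1) %in% key(n0)))
  })
})

test_that("degrees match a naive edge-scan oracle on random graphs", {
  # edgeless graph
  empty <- semantic_network(letters[1:4],
                            data.frame(source = character(),
                                       target = character()))
  d0 <- degrees(empty)
  expect_true(all(d0$indegree == 0) && all(d0$outdegree == 0))

  for (s in 1:50) {
    net <- random_directed_network(n = 8, p = 0.25, seed = 100 + s)
    d <- degrees(net)
    for (i in seq_len(nrow(d))) {
      expect_equal(d$indegree[i],
                   sum(net$edges$target == d$word[i]))
      expect_equal(d$outdegree[i],
                   sum(net$edges$source == d$word[i]))
    }
    expect_equal(sum(d$indegree), nrow(net$edges))
    expect_equal(sum(d$indegree), sum(d$outdegree))
  }

  # induced subgraph on a random subset, against the oracle
  net <- random_directed_network(12, 0.3, seed = 7)
  sub <- net$nodes[1:6]
  d <- degrees(net, restrict_to = sub)
  for (i in seq_len(nrow(d))) {
    expect_equal(d$indegree[i], oracle_indegree(net, d$word[i], sub))
  }
  expect_error(degrees(net, restrict_to = c("nope")), "unknown")
})

test_that("the worked-example hub has degree 5 within the vocabulary", {
  ex <- toy_growth_example()
  d <- degrees(ex$network, restrict_to = ex$known)
  expect_equal(d$indegree[d$word == "k1"], 5)
})

test_that("CHAT transcripts yield adult utterances only, lightly cleaned", {
  cha <- c(
    "@UTF8",
    "@Begin",
    "@Participants:\tMOT Mother, CHI Target_Child",
    "@ID:\teng|demo|MOT|32;|female|||Mother|||",
    "@ID:\teng|demo|CHI|2;6.|male|||Target_Child|||",
    "*MOT:\tlook at the doggie .",
    "*CHI:\tdoggie !",
    "*MOT:\tyes , a big <big> [/] doggie",
    "\tand a kitty too .",
    "%mor:\tignored tier",
    "*MOT:\t&um thank_you sweetie@d .",
    "@End"
  )
  path <- withr::local_tempfile(fileext = ".cha")
  writeLines(cha, path)
  utts <- read_chat_utterances(path)
  expect_equal(utts, c("look at the doggie",
                       "yes a big big doggie and a kitty too",
                       "thank_you sweetie"))
  # replacement map applied token-wise
  utts2 <- read_chat_utterances(path, replace_map = c(doggie = "dog"))
  expect_equal(utts2[1], "look at the dog")
})

test_that("networks survive a CSV round trip", {
  net <- random_directed_network(10, 0.2, seed = 12)
  path <- withr::local_tempfile(fileext = ".csv")
  write_network(net, path)
  back <- read_network(path)
  expect_equal(back$nodes, net$nodes)
  expect_equal(dplyr::arrange(back$edges, source, target),
               dplyr::arrange(net$edges, source, target))

  lex <- gen_lexicon(10, 2, seed = 30)
  tab <- gen_association_study(lex, 4, "adult", ground_truth(seed = 31))
  ct <- cap_and_crosstab(tab, NULL)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_crosstab(ct, p2)
  back2 <- read_crosstab(p2)
  expect_equal(back2$counts[back2$responses, back2$cues],
               ct$counts[back2$responses, back2$cues])
})
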