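test_that("the worked example separates the three growth models", {
  ex <- toy_growth_example()
  net <- ex$network
  expect_equal(growth_value(net, ex$known, "green", "acquisition"), 5)
  expect_equal(growth_value(net, ex$known, "blue", "lure"), 3)
  expect_equal(growth_value(net, ex$known, "red", "attachment"), 5)
  # the caption's also-ran values
  expect_equal(growth_value(net, ex$known, "blue", "attachment"), 4 / 3)
  expect_equal(growth_value(net, ex$known, "green", "attachment"), 1)
  expect_equal(growth_value(net, ex$known, "red", "acquisition"), 1)
  expect_equal(growth_value(net, ex$known, "blue", "acquisition"), 3)
  expect_equal(growth_value(net, ex$known, "red", "lure"), 1)
  expect_equal(growth_value(net, ex$known, "green", "lure"), 1)
})

test_that("an isolated candidate scores zero under every model", {
  net <- semantic_network(c("a", "b", "iso"),
                          data.frame(source = "a", target = "b"))
  for (m in c("attachment", "acquisition", "lure")) {
    expect_equal(growth_value(net, c("a", "b"), "iso", m), 0)
  }
  expect_error(growth_value(net, c("a"), "zz", "lure"), "not a node")
  expect_error(growth_value(net, c("a"), "a", "lure"), "must not")
})

test_that("growth values equal the brute-force oracle on random graphs", {
  for (s in 1:100) {
    net <- random_directed_network(20, 0.15, seed = 200 + s)
    withr::with_seed(300 + s, {
      known <- sample(net$nodes, sample(3:10, 1))
      cand <- sample(setdiff(net$nodes, known), 1)
    })
    for (m in c("attachment", "acquisition", "lure")) {
      expect_equal(growth_value(net, known, cand, m),
                   oracle_growth_value(net, known, cand, m),
                   info = sprintf("seed %d model %s", s, m))
    }
  }
})

test_that("monthly growth tables standardize within month and model", {
  lex <- gen_lexicon(30, 3, seed = 18)
  net <- build_cooccurrence_network(gen_corpus(lex, 300, seed = 19),
                                    lex$word)
  est <- tibble::tibble(word = lex$word,
                        aoa = pmin(lex$true_aoa, 29.9), status = "ok")
  traj <- build_trajectory(est)
  tab <- suppressWarnings(monthly_growth_table(net, traj))

  stats <- tab |>
    dplyr::group_by(month, model) |>
    dplyr::summarise(mz = mean(z), sz = sd(z), n = dplyr::n(),
                     .groups = "drop")
  nontrivial <- stats[stats$n > 1 & stats$sz > 0, ]
  expect_true(all(abs(nontrivial$mz) < 1e-10))
  expect_true(all(abs(nontrivial$sz - 1) < 1e-10))

  # acquisition raw values are constant across months for a fixed word
  acq <- tab[tab$model == "acquisition", ]
  spread <- tapply(acq$raw, acq$word, function(x) diff(range(x)))
  expect_true(all(spread == 0))

  # rows exist exactly for words unknown at each month
  for (m in c(16, 22, 29)) {
    expect_setequal(unique(tab$word[tab$month == m]), unknown_at(traj, m))
  }
})

test_that("monthly table values equal a naive per-month re-computation", {
  net <- random_directed_network(30, 0.12, seed = 21)
  withr::with_seed(22, {
    est <- tibble::tibble(word = net$nodes,
                          aoa = runif(30, 15, 30), status = "ok")
  })
  traj <- build_trajectory(est)
  tab <- suppressWarnings(monthly_growth_table(net, traj))
  for (m in c(16, 20, 27)) {
    known <- known_at(traj, m)
    for (w in utils::head(unknown_at(traj, m), 4)) {
      for (mod in c("attachment", "acquisition", "lure")) {
        expect_equal(
          tab$raw[tab$month == m & tab$word == w & tab$model == mod],
          oracle_growth_value(net, known, w, mod)
        )
      }
    }
  }
})

test_that("at-acquisition extraction applies the counting conventions", {
  traj <- study_scale_trajectory(seed = 23)
  net <- withr::with_seed(24, {
    pairs <- cbind(sample(traj$word, 3000, TRUE),
                   sample(traj$word, 3000, TRUE))
    semantic_network(traj$word,
                     data.frame(source = pairs[, 1], target = pairs[, 2]))
  })
  tab <- suppressWarnings(monthly_growth_table(net, traj))
  aa <- at_acquisition(tab, traj)
  expect_equal(nrow(aa), 547 * 3)
  aa_all <- at_acquisition(tab, traj, include_final_month = TRUE)
  expect_equal(nrow(aa_all), 580 * 3)
  # selected month is always the bucket preceding acquisition
  expect_true(all(aa$month ==
                    traj$bucket[match(aa$word, traj$word)] - 1L))

  # single-word trajectory learned at 17: one row per model
  net1 <- semantic_network(c("a", "b"),
                           data.frame(source = "a", target = "b"))
  traj1 <- build_trajectory(tibble::tibble(word = c("a", "b"),
                                           aoa = c(15, 16.5),
                                           status = "ok"))
  tab1 <- suppressWarnings(monthly_growth_table(net1, traj1))
  aa1 <- at_acquisition(tab1, traj1, include_final_month = TRUE)
  expect_equal(nrow(aa1), 3)
  expect_true(all(aa1$word == "b" & aa1$month == 16))
})

test_that("one-sample t on at-acquisition values matches hand calculation", {
  vals <- tibble::tibble(word = sprintf("w%d", 1:5), model = "lure",
                         month = 17,
                         z_at_acquisition = c(0.3, -0.1, 0.5, 0.2, 0.1))
  res <- at_acquisition_tests(vals)
  x <- vals$z_at_acquisition
  expect_equal(res$mean, mean(x))
  expect_equal(res$t, mean(x) / (sd(x) / sqrt(5)))
  expect_equal(res$df, 4L)
  expect_equal(res$p, t.test(x)$p.value)
})

test_that("editing known-incident edges moves lure/attachment, never acquisition", {
  net <- random_directed_network(20, 0.2, seed = 26)
  known <- net$nodes[1:8]
  cand <- net$nodes[10]
  before <- vapply(c("attachment", "acquisition", "lure"), function(m) {
    growth_value(net, known, cand, m)
  }, numeric(1))
  # delete every edge incident to a known word
  keep <- !(net$edges$source %in% known | net$edges$target %in% known)
  net2 <- semantic_network(net$nodes, net$edges[keep, ])
  after <- vapply(c("attachment", "acquisition", "lure"), function(m) {
    growth_value(net2, known, cand, m)
  }, numeric(1))
  expect_equal(after[["lure"]], 0)
  expect_equal(after[["attachment"]], 0)
  # acquisition only loses indegree coming *from* known words; on a graph
  # with no known->candidate edges it is untouched
  keep2 <- !(net$edges$target == cand & net$edges$source %in% known)
  net3 <- semantic_network(net$nodes, net$edges[keep2, ])
  same_sources <- sum(net3$edges$target == cand)
  expect_equal(growth_value(net3, known, cand, "acquisition"), same_sources)
})

test_that("planted preferential-acquisition trajectories score highest under
          the acquisition model", {
  lex <- gen_lexicon(80, 8, seed = 27)
  net <- build_cooccurrence_network(gen_corpus(lex, 1500, seed = 28),
                                    lex$word)
  deg <- degrees(net)
  preds <- tibble::tibble(word = deg$word,
                          indeg = as.numeric(scale(deg$indegree)))
  traj <- simulate_acquisition(preds, c(indeg = 2), lex$word[1:8],
                               words_per_month = 4, seed = 29)
  tab <- suppressWarnings(monthly_growth_table(net, traj))
  res <- at_acquisition_tests(at_acquisition(tab, traj))
  m <- setNames(res$mean, res$model)
  expect_gt(m[["acquisition"]], 0)
  expect_gt(m[["acquisition"]], m[["attachment"]])
})
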