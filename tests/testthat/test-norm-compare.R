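test_that("attach_norms joins covariates and applies its policy", {
  tab <- tibble::tibble(
    participant = "p1", session = "p1",
    cue = rep("dog", 10), position = rep(1:2, 5),
    response_raw = c(rep("cat", 9), "unknownword")
  )
  norms <- tibble::tibble(word = c("cat", "dog"), frequency = c(3.2, 3.9))
  expect_message(dropped <- attach_norms(tab, norms, policy = "drop"),
                 "1 of 10")
  expect_equal(nrow(dropped), 9)
  expect_true(all(dropped$frequency == 3.2))

  expect_message(flagged <- attach_norms(tab, norms, policy = "flag"))
  expect_equal(nrow(flagged), 10)
  expect_equal(sum(!flagged$norm_matched), 1)

  # full coverage: no message, zero drops
  expect_no_message(full <- attach_norms(tab[1:9, ], norms))
  expect_equal(nrow(full), 9)
  expect_error(attach_norms(tab, norms[0, ]), "non-empty")
})

test_that("cell means equal a group-by oracle and ignore row order", {
  withr::with_seed(17, {
    d <- tidyr::expand_grid(cue = paste0("c", 1:4),
                            condition = c("adult", "child"),
                            position = 1:3, rep = 1:5)
    d$aoa <- rnorm(nrow(d), 5)
  })
  cells <- cell_means(d, "aoa")
  expect_equal(nrow(cells), 4 * 2 * 3)
  oracle <- aggregate(aoa ~ cue + condition + position, d, mean)
  for (i in seq_len(nrow(oracle))) {
    got <- cells$value[cells$unit == oracle$cue[i] &
                         cells$factor_a == oracle$condition[i] &
                         cells$factor_b == oracle$position[i]]
    expect_equal(got, oracle$aoa[i])
  }
  withr::with_seed(18, shuffled <- d[sample(nrow(d)), ])
  expect_equal(dplyr::arrange(cell_means(shuffled, "aoa"),
                              unit, factor_a, factor_b),
               dplyr::arrange(cells, unit, factor_a, factor_b))

  # a unit missing a cell is dropped listwise, with a message
  d2 <- d[!(d$cue == "c1" & d$condition == "child" & d$position == 3), ]
  expect_message(cells2 <- cell_means(d2, "aoa"), "1 unit")
  expect_false("c1" %in% cells2$unit)

  # single observation per cell: the mean is that value
  d3 <- d[d$rep == 1, ]
  cells3 <- cell_means(d3, "aoa")
  expect_equal(sort(cells3$value), sort(d3$aoa))
})

test_that("repeated-measures ANOVA matches aov and an independent epsilon", {
  withr::with_seed(19, {
    n <- 10
    d <- tidyr::expand_grid(unit = sprintf("u%02d", 1:n),
                            factor_a = c("a1", "a2"),
                            factor_b = c("b1", "b2", "b3"))
    u <- rnorm(n)
    d$value <- u[match(d$unit, sprintf("u%02d", 1:n))] +
      0.5 * (d$factor_a == "a2") + 0.3 * as.integer(factor(d$factor_b)) +
      0.25 * (d$factor_a == "a2") * as.integer(factor(d$factor_b)) +
      rnorm(nrow(d), sd = 0.7)
  })
  res <- rm_anova_within(d)

  # F and uncorrected df against stats::aov error strata
  da <- transform(d, unit = factor(unit), factor_a = factor(factor_a),
                  factor_b = factor(factor_b))
  av <- summary(aov(value ~ factor_a * factor_b +
                      Error(unit / (factor_a * factor_b)), data = da))
  f_aov <- c(av[["Error: unit:factor_a"]][[1]]["factor_a", "F value"],
             av[["Error: unit:factor_b"]][[1]]["factor_b", "F value"],
             av[["Error: unit:factor_a:factor_b"]][[1]][
               "factor_a:factor_b", "F value"])
  expect_equal(res$F, f_aov, tolerance = 1e-6)

  # epsilon = 1 for the 2-level factor, by construction of sphericity
  expect_equal(res$epsilon[res$effect == "factor_a"], 1)

  # independent Greenhouse-Geisser epsilon for the 3-level factor from the
  # eigenvalues of the double-centered covariance of B-level scores
  Zb <- aggregate(value ~ unit + factor_b, d, mean)
  Zb <- matrix(Zb$value[order(Zb$factor_b, Zb$unit)], ncol = 3)
  S <- cov(Zb)
  k <- 3
  ctr <- diag(k) - 1 / k
  lam <- eigen(ctr %*% S %*% ctr, symmetric = TRUE)$values[1:(k - 1)]
  eps_oracle <- sum(lam)^2 / ((k - 1) * sum(lam^2))
  expect_equal(res$epsilon[res$effect == "factor_b"], eps_oracle,
               tolerance = 1e-6)

  # generalized eta^2 (fully-within convention): SS_eff over SS_eff plus
  # every unit-related SS, reconstructed from the aov strata
  ss <- function(stratum, row) av[[stratum]][[1]][row, "Sum Sq"]
  err_all <- ss("Error: unit", "Residuals") +
    ss("Error: unit:factor_a", "Residuals") +
    ss("Error: unit:factor_b", "Residuals") +
    ss("Error: unit:factor_a:factor_b", "Residuals")
  eta_b <- ss("Error: unit:factor_b", "factor_b") /
    (ss("Error: unit:factor_b", "factor_b") + err_all)
  expect_equal(res$eta_g2[res$effect == "factor_b"], eta_b,
               tolerance = 1e-6)
})

test_that("null factor A gives F near zero and scaling changes nothing", {
  withr::with_seed(20, {
    n <- 12
    base <- tidyr::expand_grid(unit = sprintf("u%02d", 1:n),
                               factor_b = c("b1", "b2", "b3"))
    base$half <- rnorm(nrow(base))
  })
  # factor A levels literally duplicated: zero A variance by construction
  d <- dplyr::bind_rows(
    transform(base, factor_a = "a1", value = half),
    transform(base, factor_a = "a2", value = half)
  )
  res <- rm_anova_within(d)
  expect_equal(res$F[res$effect == "factor_a"], 0, tolerance = 1e-20)
  expect_equal(res$p[res$effect == "factor_a"], 1, tolerance = 1e-12)

  # scale equivariance: c * value leaves F, p, epsilon, eta_g2 unchanged
  withr::with_seed(21, {
    d2 <- tidyr::expand_grid(unit = sprintf("u%02d", 1:8),
                             factor_a = c("a1", "a2"),
                             factor_b = c("b1", "b2", "b3"))
    d2$value <- rnorm(nrow(d2))
  })
  r1 <- rm_anova_within(d2)
  d3 <- d2; d3$value <- 17 * d3$value
  r2 <- rm_anova_within(d3)
  expect_equal(r2$F, r1$F, tolerance = 1e-9)
  expect_equal(r2$p, r1$p, tolerance = 1e-9)
  expect_equal(r2$epsilon, r1$epsilon, tolerance = 1e-9)
  expect_equal(r2$eta_g2, r1$eta_g2, tolerance = 1e-9)

  dconst <- d2; dconst$value <- 1
  expect_error(rm_anova_within(dconst), "constant")
})

test_that("the same ANOVA machinery runs on growth values (network x model)", {
  net <- random_directed_network(30, 0.15, seed = 22)
  withr::with_seed(23, {
    est <- tibble::tibble(word = net$nodes, aoa = runif(30, 15, 30),
                          status = "ok")
  })
  traj <- build_trajectory(est)
  g1 <- suppressWarnings(monthly_growth_table(net, traj))
  net2 <- random_directed_network(30, 0.15, seed = 24)  # same node names
  g2 <- suppressWarnings(monthly_growth_table(net2, traj))
  both <- dplyr::bind_rows(
    dplyr::mutate(at_acquisition(g1, traj), network = "adult"),
    dplyr::mutate(at_acquisition(g2, traj), network = "child")
  )
  cells <- cell_means(both, "z_at_acquisition", unit = "word",
                      factor_a = "network", factor_b = "model")
  res <- rm_anova_within(cells)
  expect_equal(res$effect,
               c("factor_a", "factor_b", "factor_a:factor_b"))
  expect_true(all(is.finite(res$F)))
  expect_equal(res$epsilon[1], 1)
})

test_that("paired simple effects match hand computation and df convention", {
  # identical conditions: t = 0, CI symmetric about 0
  d0 <- tidyr::expand_grid(unit = paste0("u", 1:6),
                           factor_a = c("a1", "a2"), factor_b = "b1")
  d0$value <- rep(1:6, each = 2)  # exactly equal within unit
  r0 <- paired_simple_effects(d0, at = "b1")
  expect_equal(r0$mean_diff, 0)
  expect_equal(r0$ci_lower, -r0$ci_upper)

  # hand-computed paired t on 5 units
  x <- c(5.1, 4.8, 5.6, 5.0, 5.3)
  y <- c(4.9, 4.9, 5.1, 4.7, 5.2)
  d5 <- tibble::tibble(unit = rep(paste0("u", 1:5), 2),
                       factor_a = rep(c("a1", "a2"), each = 5),
                       factor_b = "b2", value = c(x, y))
  r5 <- paired_simple_effects(d5, at = "b2")
  dd <- x - y
  expect_equal(r5$mean_diff, mean(dd))
  expect_equal(r5$t, mean(dd) / (sd(dd) / sqrt(5)), tolerance = 1e-12)
  expect_equal(r5$df, 4)

  # 598 units give the conventional 597 degrees of freedom
  withr::with_seed(25, {
    d598 <- tibble::tibble(unit = rep(sprintf("u%03d", 1:598), 2),
                           factor_a = rep(c("a1", "a2"), each = 598),
                           factor_b = "b1", value = rnorm(1196))
  })
  expect_equal(paired_simple_effects(d598, at = "b1")$df, 597)
})
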