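test_that("lrt is a pure function of the two log-likelihoods", {
  head <- lrt(-924.50, -932.13, df = 4)
  expect_equal(round(head$statistic, 1), 15.3)
  expect_lt(head$p.value, 0.01)
  row1 <- lrt(-924.50, -926.60, df = 1)
  expect_equal(round(row1$statistic, 2), 4.20)
  expect_equal(round(row1$p.value, 2), 0.04)
  zero <- lrt(-10, -10, df = 4)
  expect_equal(zero$statistic, 0)
  expect_equal(zero$p.value, 1)
  # marginally negative differences from optimizer noise are clamped
  expect_equal(lrt(-10 - 1e-9, -10, df = 1)$statistic, 0)
  expect_error(lrt(-1, -2, df = 0), "df")
})

test_that("fit_model recovers boundary behavior and respects nesting", {
  # two tips in the same state: no change observed, ML rate at the bound
  cherry <- ape::read.tree(text = "(A:1,B:1);")
  f <- fit_model(cherry, c(A = 1, B = 1), mk2_model(), attempts = 6, seed = 1)
  expect_lt(f$rates[["q10"]], 1e-6)
  expect_equal(nrow(f$attempt_results), 6)
  expect_equal(f$loglik, max(f$attempt_results$loglik))

  # dependent model can never fit worse than the independent model
  tr <- set_equal_branch_lengths(simulate_tree(80, seed = 2))
  Qi <- build_q(independent_model(),
                setNames(rep(0.15, 4), independent_model()$params))
  sim <- simulate_traits(tr, Qi, seed = 3)
  cmp <- dependent_vs_independent(tr, sim$tip_states, attempts = 6, seed = 4)
  expect_gte(cmp$fit_dependent$loglik, cmp$fit_independent$loglik - 1e-6)
  expect_equal(cmp$test$df, 4L)
  g <- glance(cmp)
  expect_equal(g$statistic,
               max(0, 2 * (g$ll_dependent - g$ll_independent)),
               tolerance = 1e-10)
  td <- tidy(cmp)
  expect_equal(nrow(td), 12)  # 8 dependent + 4 independent terms
})

test_that("fitted likelihoods match an independent reference implementation", {
  skip_if_not_installed("phytools")
  tr <- set_equal_branch_lengths(simulate_tree(60, seed = 11))
  Qt <- build_q(dependent_model(), dep_rates(q31 = 0.8))
  sim <- simulate_traits(tr, Qt, root_state = 0, seed = 12)
  dec <- decode_pair(unname(sim$tip_states))
  x <- setNames(dec$trait1, names(sim$tip_states))
  y <- setNames(dec$trait2, names(sim$tip_states))
  suppressWarnings(
    ref <- phytools::fitPagel(tr, factor(x), factor(y), pi = "equal"))
  cmp <- dependent_vs_independent(tr, sim$tip_states, attempts = 10, seed = 13)
  expect_equal(cmp$fit_independent$loglik, as.numeric(ref$independent.logL),
               tolerance = 1e-4)
  # multi-start must do at least as well as the reference's single start
  expect_gte(cmp$fit_dependent$loglik, ref$dependent.logL - 1e-4)
})

test_that("restricted_suite reproduces tied-rate fits against the full model", {
  tr <- set_equal_branch_lengths(simulate_tree(70, seed = 21))
  Qt <- build_q(dependent_model(), dep_rates(q31 = 1.0))
  sim <- simulate_traits(tr, Qt, root_state = 0, seed = 22)
  suite <- restricted_suite(tr, sim$tip_states, attempts = 5, seed = 23)
  expect_equal(nrow(suite), 4)
  expect_true(all(suite$df == 1))
  expect_true(all(suite$statistic >= 0))
  expect_true(all(suite$ll_restricted <= suite$ll_full + 1e-6))
  expect_equal(suite$p.value,
               pchisq(suite$statistic, 1, lower.tail = FALSE))
  # empty restriction list -> empty table
  empty <- restricted_suite(tr, sim$tip_states, restrictions = list())
  expect_equal(nrow(empty), 0)
  expect_error(
    restricted_suite(tr, sim$tip_states, restrictions = list(bad = c("qxx", "q12")),
                     attempts = 2, seed = 1, fit_full = NULL),
    "unknown rate")
})
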