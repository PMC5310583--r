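test_that("build_q honors structure, constraints and the Kronecker sum", {
  # dependent model, all rates 1: two exits per state -> diagonal -2
  Q <- build_q(dependent_model(), rep(1, 8))
  expect_equal(unname(diag(Q)), rep(-2, 4))
  expect_equal(rowSums(Q), rep(0, 4), ignore_attr = TRUE)
  # dual transitions are structural zeros
  expect_equal(Q["00", "11"], 0)
  expect_equal(Q["11", "00"], 0)
  expect_equal(Q["01", "10"], 0)
  expect_equal(Q["10", "01"], 0)

  # independent model is the Kronecker sum of the two 2-state generators
  set.seed(1)
  r <- random_rates(independent_model())
  Qi <- build_q(independent_model(), r)
  Qa <- build_q(mk2_model(), unname(r[c("q01_1", "q10_1")]))
  Qb <- build_q(mk2_model(), unname(r[c("q01_2", "q10_2")]))
  expect_equal(unname(Qi), kronecker(Qa, diag(2)) + kronecker(diag(2), Qb))

  # equality constraint ties exactly the two requested entries
  m <- constrain_equal(dependent_model(), c("q13", "q24"))
  expect_length(m$params, 7)
  for (i in 1:5) {
    Qc <- build_q(m, random_rates(m))
    expect_equal(Qc["00", "10"], Qc["01", "11"])
  }
  expect_error(constrain_equal(dependent_model(), c("q13", "nope")), "unknown rate")
  expect_error(build_q(dependent_model(), c(rep(1, 7), -1)), "nonnegative")
})

test_that("transition probabilities match closed forms and the eigen oracle", {
  Q <- build_q(mk2_model(), c(0.4, 0.4))
  expect_equal(transition_probabilities(Q, 0), diag(2), ignore_attr = TRUE)
  # symmetric binary chain: p(stay) = (1 + exp(-2qt)) / 2
  for (t in c(0.1, 1, 5))
    expect_equal(transition_probabilities(Q, t)[1, 1],
                 (1 + exp(-2 * 0.4 * t)) / 2, tolerance = 1e-10)

  set.seed(2)
  for (i in 1:10) {
    Qd <- build_q(dependent_model(), random_rates(dependent_model()))
    t <- runif(1, 0.1, 3)
    P <- transition_probabilities(Qd, t)
    expect_equal(rowSums(P), rep(1, 4), ignore_attr = TRUE, tolerance = 1e-10)
    expect_true(all(P >= 0))
    # eigendecomposition oracle
    ev <- eigen(Qd)
    Pe <- Re(ev$vectors %*% diag(exp(ev$values * t)) %*% solve(ev$vectors))
    expect_equal(unname(P), Pe, tolerance = 1e-8)
    # ergodic limit: rows approach the stationary distribution
    Pinf <- transition_probabilities(Qd, 500)
    pi <- stationary_distribution(Qd)
    expect_equal(unname(Pinf[sample(4, 1), ]), unname(pi), tolerance = 1e-6)
  }
})

test_that("pruning equals enumeration and respects invariances", {
  set.seed(3)
  tr <- random_tree(4)
  Q <- build_q(dependent_model(), random_rates(dependent_model()))
  st <- setNames(sample(0:3, 4, replace = TRUE), tr$tip.label)
  expect_equal(pruning_loglik(tr, st, Q),
               enum_loglik(tr, st, Q, rep(0.25, 4)), tolerance = 1e-8)

  # zero branch lengths, uniform root, all tips in one state -> log(1/4)
  tr0 <- tr
  tr0$edge.length[] <- 0
  expect_equal(pruning_loglik(tr0, setNames(rep(2, 4), tr$tip.label), Q),
               log(1 / 4))

  # rate-time confounding: Q*c with lengths/c leaves the likelihood unchanged
  trc <- tr
  trc$edge.length <- tr$edge.length / 3.7
  expect_equal(pruning_loglik(trc, st, Q * 3.7), pruning_loglik(tr, st, Q),
               tolerance = 1e-10)

  # invariance under child-order permutation
  rot <- ape::rotateConstr(tr, rev(tr$tip.label))
  expect_equal(pruning_loglik(rot, st, Q), pruning_loglik(tr, st, Q),
               tolerance = 1e-12)

  # missing data: NA tip integrates over states; dropping the tip must agree
  st_na <- st
  st_na[2] <- NA
  kept <- prune_to_taxa(tr, names(st)[-2])$tree
  expect_equal(pruning_loglik(tr, st_na, Q),
               pruning_loglik(kept, st[-2], Q), tolerance = 1e-10)

  expect_error(pruning_loglik(tr, st[-1], Q), "no state for tree tip")
})

test_that("dependent model collapses to the independent model at tied rates", {
  set.seed(4)
  tr <- random_tree(8)
  st <- setNames(sample(0:3, 8, replace = TRUE), tr$tip.label)
  ri <- random_rates(independent_model())
  dep_equiv <- c(q12 = ri[["q01_2"]], q13 = ri[["q01_1"]],
                 q21 = ri[["q10_2"]], q24 = ri[["q01_1"]],
                 q31 = ri[["q10_1"]], q34 = ri[["q01_2"]],
                 q42 = ri[["q10_1"]], q43 = ri[["q10_2"]])
  expect_equal(
    pruning_loglik(tr, st, build_q(dependent_model(), dep_equiv)),
    pruning_loglik(tr, st, build_q(independent_model(), ri)),
    tolerance = 1e-12)
})

test_that("root treatments reweight the same root partials", {
  set.seed(5)
  tr <- random_tree(6)
  Q <- build_q(dependent_model(), random_rates(dependent_model()))
  st <- setNames(sample(0:3, 6, replace = TRUE), tr$tip.label)
  ll_u <- pruning_loglik(tr, st, Q, root_treatment("uniform"))
  ll_s <- pruning_loglik(tr, st, Q, root_treatment("stationary"))
  ll_f <- pruning_loglik(tr, st, Q, root_treatment("fitzjohn"))
  expect_true(all(is.finite(c(ll_u, ll_s, ll_f))))
  # fixed-root likelihoods, averaged with uniform weights, give the uniform LL
  ll_fix <- vapply(0:3, function(s)
    pruning_loglik(tr, st, Q, root_treatment("fixed", state = s)), numeric(1))
  expect_equal(log(mean(exp(ll_fix))), ll_u, tolerance = 1e-10)
})
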