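test_that("marginal reconstruction matches the brute-force posterior", {
  set.seed(1)
  for (i in 1:10) {
    tr <- random_tree(3)
    Q <- build_q(dependent_model(), random_rates(dependent_model()))
    st <- setNames(sample(0:3, 3, replace = TRUE), tr$tip.label)
    rec <- marginal_asr(tr, st, Q)
    for (node in 4:5)  # both internal nodes of a rooted 3-tip tree
      expect_equal(unname(rec$prob[node, ]),
                   enum_node_posterior(tr, st, Q, rep(0.25, 4), node),
                   tolerance = 1e-8)
  }
})

test_that("reconstruction limits and symmetry behave as expected", {
  # all tips one state, low rates: root nearly certain
  tr <- set_equal_branch_lengths(simulate_tree(12, seed = 2))
  Q <- build_q(mk2_model(), c(0.01, 0.01))
  rec <- marginal_asr(tr, setNames(rep(0, 12), tr$tip.label), Q)
  expect_gt(rec$prob[13, 1], 0.99)

  # mirror-symmetric configuration: root exactly (1/2, 1/2)
  bal <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  Qs <- build_q(mk2_model(), c(0.3, 0.3))
  rec <- marginal_asr(bal, c(A = 0, B = 1, C = 0, D = 1), Qs)
  expect_equal(unname(rec$prob[5, ]), c(0.5, 0.5), tolerance = 1e-12)

  # tips carry all mass on the observed state
  expect_equal(unname(rec$prob[1, ]), c(1, 0))
  # every node's proportional likelihoods form a simplex
  expect_equal(rowSums(rec$prob), rep(1, 7), ignore_attr = TRUE,
               tolerance = 1e-10)
})

test_that("root marginals equal the normalized root partials from pruning", {
  set.seed(3)
  tr <- random_tree(8)
  Q <- build_q(dependent_model(), random_rates(dependent_model()))
  st <- setNames(sample(0:3, 8, replace = TRUE), tr$tip.label)
  rec <- marginal_asr(tr, st, Q, root = "uniform")
  pr <- corrtrait:::pruning_root_partial(tr, st, Q)
  expect_equal(unname(rec$prob[9, ]),
               pr$root_partial / sum(pr$root_partial), tolerance = 1e-10)
})

test_that("transition counting follows the assignment rules", {
  bal <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  Q <- build_q(mk2_model(), c(0.2, 0.2))
  # uniform states: no transitions anywhere
  rec0 <- marginal_asr(bal, c(A = 0, B = 0, C = 0, D = 0), Q)
  expect_true(all(count_transitions(rec0)$count == 0))

  # one cherry flipped: exactly one 0->1 edge under argmax
  rec1 <- marginal_asr(bal, c(A = 0, B = 0, C = 1, D = 1), Q)
  ct <- count_transitions(rec1)
  expect_equal(ct$count[ct$from == "0" & ct$to == "1"], 1L)
  expect_equal(sum(ct$count), 1L)

  # threshold rule is monotonically non-increasing in p and bounded by argmax
  tr <- set_equal_branch_lengths(simulate_tree(60, seed = 4))
  Q4 <- build_q(dependent_model(), dep_rates())
  sim <- simulate_traits(tr, Q4, seed = 5)
  rec <- marginal_asr(tr, sim$tip_states, Q4)
  n_arg <- sum(count_transitions(rec)$count)
  prev <- n_arg
  for (p in c(0.6, 0.75, 0.9, 0.99)) {
    n_p <- sum(count_transitions(rec, rule = "threshold", p = p)$count)
    expect_lte(n_p, prev)
    prev <- n_p
  }
  expect_error(count_transitions(rec, rule = "threshold", p = 0.4), "0.5")
})

test_that("pair reconstructions collapse consistently per trait", {
  tr <- set_equal_branch_lengths(simulate_tree(30, seed = 6))
  Q4 <- build_q(dependent_model(), dep_rates(q31 = 1.2))
  sim <- simulate_traits(tr, Q4, seed = 7)
  rec <- marginal_asr(tr, sim$tip_states, Q4)
  c1 <- collapse_trait(rec, 1)
  expect_equal(c1$p_1, unname(rec$prob[, "10"] + rec$prob[, "11"]),
               tolerance = 1e-12)
  expect_equal(c1$p_0 + c1$p_1, rep(1, nrow(c1)), tolerance = 1e-12)
  ct <- count_transitions(rec)
  cc <- collapse_transition_counts(ct, trait = 1)
  gain <- sum(ct$count[substr(ct$from, 1, 1) == "0" & substr(ct$to, 1, 1) == "1"])
  expect_equal(cc$count[cc$from == "0" & cc$to == "1"], gain)
})
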