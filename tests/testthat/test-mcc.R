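test_that("clade frequencies are exact relative frequencies", {
  # degenerate: identical trees -> every clade frequency 1
  same <- ape::read.tree(text = rep("((A:1,B:1):1,(C:1,D:1):1);", 10))
  cf <- clade_frequencies(same)
  expect_true(all(cf$frequency == 1))

  # hand-counted 6/4 mixed sample
  cf <- clade_frequencies(mixed_sample())
  freq <- setNames(cf$frequency, cf$clade)
  expect_equal(unname(freq["A|B"]), 0.6)
  expect_equal(unname(freq["A|C"]), 0.4)
  expect_equal(unname(freq["C|D"]), 0.6)
  expect_equal(unname(freq["A|B|C|D"]), 1)   # root clade
  expect_equal(unname(freq["A"]), 1)         # tip singleton

  # burn-in slices away leading trees
  cf2 <- clade_frequencies(mixed_sample(), burnin = 6)
  freq2 <- setNames(cf2$frequency, cf2$clade)
  expect_equal(unname(freq2["A|C"]), 1)
  expect_false("A|B" %in% cf2$clade)
  expect_error(clade_frequencies(mixed_sample(), burnin = 10), "burnin")
})

test_that("mcc_tree selects the sampled tree maximizing the clade score", {
  same <- ape::read.tree(text = rep("((A:1,B:1):1,(C:1,D:1):1);", 10))
  res <- mcc_tree(same, pp_limit = 0.5)
  expect_equal(res$index, 1)  # tie broken by lowest index
  expect_equal(res$scores[res$index], 3)  # 3 internal clades, all at freq 1
  expect_true(all(res$node_pp == 1))

  res <- mcc_tree(mixed_sample(), score = "sum", pp_limit = 0.5)
  # majority topology ((A,B),(C,D)) wins: clade-frequency sum 1+0.6+0.6 = 2.2
  expect_equal(res$index, 1)
  expect_equal(res$scores[res$index], 2.2)
  expect_true(all(res$scores[res$index] >= res$scores))  # exhaustive re-score
  expect_true("A|B" %in% internal_keys_of(res$tree))
  # only PP >= 0.5 annotated: {A,B} (0.6) and {C,D} (0.6) and root (1)
  annotated <- res$node_pp >= 0.5
  expect_equal(sum(res$tree$node.label != ""), sum(annotated))
  expect_equal(sum(annotated), 3)
})

test_that("mcc selection is invariant to tip-label storage order", {
  sam <- mixed_sample()
  rot <- lapply(sam, function(tr) ape::rotateConstr(tr, rev(sort(tr$tip.label))))
  class(rot) <- "multiPhylo"
  a <- mcc_tree(sam)
  b <- mcc_tree(rot)
  expect_equal(a$scores, b$scores, tolerance = 1e-12)
  expect_true(same_topology(a$tree, b$tree))
})

test_that("log-product scoring agrees with phangorn's maxCladeCred choice", {
  skip_if_not_installed("phangorn")
  set.seed(31)
  base <- ape::rmtree(12, 8)
  # build a sample with repeated topologies so clade frequencies differ
  sam <- base[c(1, 1, 1, 1, 2, 2, 2, 3, 3, 4, 5, 6)]
  class(sam) <- "multiPhylo"
  ours <- mcc_tree(sam, score = "log-product")
  ref <- phangorn::maxCladeCred(sam, rooted = TRUE)
  expect_true(same_topology(ours$tree, ref))
})

test_that("write_mcc emits NEXUS with posterior comments", {
  res <- mcc_tree(mixed_sample())
  f <- withr::local_tempfile(fileext = ".nex")
  ft <- withr::local_tempfile(fileext = ".tsv")
  write_mcc(res, f, clade_table_path = ft)
  txt <- readLines(f)
  expect_equal(txt[1], "#NEXUS")
  expect_true(any(grepl("\\[&posterior=0\\.6\\]", txt)))
  tab <- read.delim(ft)
  expect_equal(tab$frequency[tab$clade == "A|B"], 0.6)
})
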