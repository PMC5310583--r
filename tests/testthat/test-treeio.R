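test_that("read_trees parses newick and nexus and validates taxon sets", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,(C:1,D:1):1);", f)
  ts <- read_trees(f)
  expect_s3_class(ts, "multiPhylo")
  expect_length(ts, 1)
  expect_setequal(ts[[1]]$tip.label, c("A", "B", "C", "D"))

  # nexus round trip with translate block
  trees <- ape::rmtree(3, 5)
  fn <- withr::local_tempfile(fileext = ".nex")
  write_trees(trees, fn, format = "nexus")
  back <- read_trees(fn)
  expect_length(back, 3)
  for (i in 1:3) {
    expect_true(same_topology(back[[i]], trees[[i]]))
    # NEXUS writer prints ~10 significant digits
    expect_equal(patristic(back[[i]]), patristic(trees[[i]]), tolerance = 1e-8)
  }

  # duplicated tip labels
  fd <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,(A:1,C:1):1);", fd)
  expect_error(read_trees(fd), "duplicated tip labels")

  # mismatched taxon sets across trees
  fm <- withr::local_tempfile(fileext = ".nwk")
  writeLines(c("((A:1,B:1):1,C:1);", "((A:1,B:1):1,D:1);"), fm)
  expect_error(read_trees(fm), "symmetric difference.*[CD]")
})

test_that("newick read-write-read is idempotent on random trees", {
  set.seed(42)
  for (i in 1:5) {
    tr <- random_tree(12)
    f <- withr::local_tempfile(fileext = ".nwk")
    write_trees(tr, f)
    back <- read_trees(f)[[1]]
    expect_true(same_topology(tr, back))
    # Newick writer prints ~10 significant digits
    expect_equal(patristic(tr), patristic(back), tolerance = 1e-8)
  }
})

test_that("set_equal_branch_lengths overwrites every edge and is idempotent", {
  tr <- ape::read.tree(text = "((A:1,B:0):3,(C:2,D:2):1);")
  eq <- set_equal_branch_lengths(tr, 1)
  expect_true(all(eq$edge.length == 1))
  expect_identical(eq$edge, tr$edge)
  expect_equal(set_equal_branch_lengths(eq, 1), eq)
  expect_error(set_equal_branch_lengths(tr, 0), "positive")
  expect_error(set_equal_branch_lengths(tr, -2), "positive")

  # an ultrametric tree stops being ultrametric under the transform
  ut <- simulate_tree(10, seed = 5)
  expect_true(check_ultrametric(ut, 1e-9))
  expect_false(check_ultrametric(set_equal_branch_lengths(ut), 1e-9))
})

test_that("check_ultrametric reports the deviation", {
  ok <- check_ultrametric(ape::read.tree(text = "((A:1,B:1):1,C:2);"), 1e-9)
  expect_true(ok)
  expect_equal(attr(ok, "max_deviation"), 0)
  bad <- check_ultrametric(ape::read.tree(text = "((A:1,B:2):1,C:2);"), 1e-9)
  expect_false(bad)
  expect_gt(attr(bad, "max_deviation"), 0.3)
})

test_that("prune_to_taxa preserves patristic distances among kept tips", {
  set.seed(7)
  for (i in 1:5) {
    tr <- random_tree(10)
    keep <- sample(tr$tip.label, 6)
    res <- prune_to_taxa(tr, keep)
    expect_setequal(res$tree$tip.label, keep)
    expect_setequal(res$dropped, setdiff(tr$tip.label, keep))
    full <- patristic(tr)
    expect_equal(patristic(res$tree),
                 full[sort(keep), sort(keep)], tolerance = 1e-10)
  }
  tr <- random_tree(6)
  expect_equal(prune_to_taxa(tr, tr$tip.label)$tree, tr)
  expect_error(prune_to_taxa(tr, c("nope1", "nope2")), "no requested taxa")
  expect_error(prune_to_taxa(tr, tr$tip.label[1]), "single tip")
  one <- prune_to_taxa(tr, tr$tip.label[1], allow_single_tip = TRUE)
  expect_equal(ape::Ntip(one$tree), 1)
})

test_that("validate_tree rejects polytomies unless asked to resolve them", {
  poly <- ape::read.tree(text = "((A:1,B:1,C:1):1,D:2);")
  expect_error(validate_tree(poly), "polytomies")
  fixed <- validate_tree(poly, resolve_polytomies = TRUE, seed = 1)
  expect_true(ape::is.binary(fixed))
  expect_equal(sort(fixed$tip.label), sort(poly$tip.label))
  # resolution inserts zero-length edges: path lengths preserved
  expect_equal(patristic(fixed), patristic(poly), tolerance = 1e-12)
  neg <- ape::read.tree(text = "((A:1,B:-1):1,C:2);")
  expect_error(validate_tree(neg), "negative")
})
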