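test_that("read_trees parses single- and multi-tree Newick files", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:1,(B:1,C:1):1);", f)
  trees <- read_trees(f)
  expect_length(trees, 1)
  expect_setequal(trees[[1]]$tip.label, c("A", "B", "C"))

  writeLines(rep("(A:1,(B:1,C:1):1);", 4), f)
  expect_length(read_trees(f), 4)
})

test_that("read_trees reports malformed lines and heterogeneous tip sets", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines(c("(A:1,(B:1,C:1):1);", "(A:1,(B:1,D:1):1);"), f)
  expect_error(read_trees(f), "tip sets differ.*line 2")
  writeLines(c("(A:1,(B:1,C:1):1);", "(A:1,(B:1:1);"), f)
  expect_error(read_trees(f), "line 2")
})

test_that("subsample_posterior draws without replacement, order preserved", {
  tr <- simulate_tree(8, seed = 1)
  post <- simulate_posterior_sample(tr, 20, 0.1, 0.5, seed = 1)
  sub <- subsample_posterior(post, 7, seed = 3)
  expect_length(sub, 7)
  newick <- vapply(post, ape::write.tree, character(1))
  kept <- vapply(sub, ape::write.tree, character(1))
  expect_true(all(kept %in% newick))
  # original order preserved
  expect_identical(match(kept, newick), sort(match(kept, newick)))
  expect_identical(subsample_posterior(post, 20, seed = 1), post)
  expect_error(subsample_posterior(post, 0, seed = 1), "n_keep")
  expect_error(subsample_posterior(post, 21, seed = 1), "n_keep")
})

test_that("mcc_tree on identical trees returns that tree with its heights", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1.5,D:1.5):0.5);")
  m <- mcc_tree(rep(c(tr), 10))
  expect_identical(ape::write.tree(m), ape::write.tree(tr))
})

test_that("mcc_tree picks the majority topology", {
  t_a <- ape::read.tree(text = "((A:1,B:1):1,((C:0.5,D:0.5):0.5,E:1):1);")
  t_b <- ape::read.tree(text = "((A:1,C:1):1,((B:0.5,D:0.5):0.5,E:1):1);")
  trees <- c(rep(c(t_a), 8), rep(c(t_b), 2))
  m <- mcc_tree(trees)
  expect_equal(ape::dist.topo(ape::unroot(m), ape::unroot(t_a)), 0,
               ignore_attr = TRUE)
  # oracle: brute-force clade-frequency log product
  sc <- oracle_mcc_scores(trees)
  expect_equal(attr(m, "log_clade_credibility"), max(sc), tolerance = 1e-12)
  expect_equal(attr(m, "mcc_index"), which.max(sc))
})

test_that("mcc_tree matches the brute-force score oracle on random samples", {
  for (s in 1:10) {
    tr <- simulate_tree(7, seed = s)
    post <- simulate_posterior_sample(tr, 25, 0.1, 0.5, seed = s + 100)
    m <- mcc_tree(post)
    sc <- oracle_mcc_scores(post)
    expect_equal(attr(m, "log_clade_credibility"), max(sc),
                 tolerance = 1e-10)
    # selected topology must be a member of the sample (selects, never
    # synthesizes)
    expect_equal(ape::dist.topo(ape::unroot(m),
                                ape::unroot(post[[attr(m, "mcc_index")]])),
                 0, ignore_attr = TRUE)
  }
})

test_that("mcc_tree annotation keeps a valid tree and mean clade heights", {
  tr <- simulate_tree(10, seed = 9) # ultrametric reference
  post <- simulate_posterior_sample(tr, 40, 0.05, 0.3, seed = 10)
  m <- mcc_tree(post)
  expect_true(all(m$edge.length >= 0))
  expect_true(sum(m$edge.length > 0) == length(m$edge.length))
})

test_that("mcc_tree is invariant to sample order up to the tie-break", {
  tr <- simulate_tree(6, seed = 11)
  post <- simulate_posterior_sample(tr, 30, 0.1, 0.5, seed = 12)
  m1 <- mcc_tree(post)
  m2 <- mcc_tree(rev(post))
  expect_equal(attr(m1, "log_clade_credibility"),
               attr(m2, "log_clade_credibility"), tolerance = 1e-12)
  expect_identical(ape::write.tree(m1), ape::write.tree(m2))
})

test_that("patristic distances match hand sums and the path-walk oracle", {
  expect_equal(patristic_distances(tree_ab())["A", "B"], 2)
  D <- patristic_distances(tree_abc())
  expect_equal(D["A", "B"], 3)
  expect_equal(D["A", "C"], 3)
  expect_equal(D["B", "C"], 2)
  expect_equal(diag(D), stats::setNames(rep(0, 3), c("A", "B", "C")))

  tr <- simulate_tree(20, 1, 0.3, seed = 13)
  expect_equal(patristic_distances(tr), oracle_patristic(tr),
               tolerance = 1e-12)
})

test_that("ultrametric trees give root-equidistant tips", {
  tr <- simulate_tree(25, seed = 14) # rphylo trees are ultrametric
  D <- patristic_distances(tr)
  # pairwise ultrametric check: all tips equidistant from the root
  depths <- ape::node.depth.edgelength(tr)[seq_len(25)]
  expect_lt(max(depths) - min(depths), 1e-9 * max(depths))
})
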