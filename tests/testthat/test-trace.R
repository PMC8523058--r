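# hand-built graph: subalignment 1 has 2 columns (nodes 1,2), subalignment 2
# has 1 column (node 3); w(node1, node3) = 3, w(node2, node3) = 1
toy_graph <- function() {
  structure(list(
    adjacency = Matrix::sparseMatrix(i = c(1, 3, 2, 3), j = c(3, 1, 3, 2),
                                     x = c(3, 3, 1, 1), dims = c(3, 3)),
    n_cols = c(2L, 1L), offsets = c(0L, 2L),
    node_subset = c(1L, 1L, 2L), node_col = c(1L, 2L, 1L)),
    class = "alignment_graph")
}

test_that("valid clusters pass through validity enforcement unchanged", {
  g <- toy_graph()
  cl <- list(c(1L, 3L), 2L)
  expect_equal(enforce_cluster_validity(cl, g), list(c(1L, 3L), 2L))
})

test_that("conflicting clusters keep the best-supported column", {
  g <- toy_graph()
  out <- enforce_cluster_validity(list(c(1L, 2L, 3L)), g)
  expect_equal(out, list(c(1L, 3L), 2L))  # node 1 wins by weight; 2 evicted
  # tie in weights -> lower column index kept
  g$adjacency <- Matrix::sparseMatrix(i = c(1, 3, 2, 3), j = c(3, 1, 3, 2),
                                      x = c(2, 2, 2, 2), dims = c(3, 3))
  out <- enforce_cluster_validity(list(c(1L, 2L, 3L)), g)
  expect_equal(out, list(c(1L, 3L), 2L))
})

test_that("a consistent chain of clusters is ordered topologically", {
  # two subalignments, two columns each; clusters pair column i with column i
  g <- structure(list(
    adjacency = Matrix::sparseMatrix(i = 1, j = 1, x = 0, dims = c(4, 4)),
    n_cols = c(2L, 2L), offsets = c(0L, 2L),
    node_subset = c(1L, 1L, 2L, 2L), node_col = c(1L, 2L, 1L, 2L)),
    class = "alignment_graph")
  tr <- order_clusters(list(c(1L, 3L), c(2L, 4L)), g)
  expect_equal(unclass(tr), list(c(1L, 3L), c(2L, 4L)), ignore_attr = TRUE)
  expect_true(validate_trace(tr, g))
})

test_that("a 2-cycle is broken into 3 clusters satisfying the trace invariants", {
  g <- structure(list(
    adjacency = Matrix::sparseMatrix(i = 1, j = 1, x = 0, dims = c(4, 4)),
    n_cols = c(2L, 2L), offsets = c(0L, 2L),
    node_subset = c(1L, 1L, 2L, 2L), node_col = c(1L, 2L, 1L, 2L)),
    class = "alignment_graph")
  # X = {(1,1),(2,2)} = nodes {1,4}; Y = {(1,2),(2,1)} = nodes {2,3}
  tr <- order_clusters(list(c(1L, 4L), c(2L, 3L)), g)
  expect_length(tr, 3L)
  expect_true(validate_trace(tr, g))
  # determinism
  tr2 <- order_clusters(list(c(1L, 4L), c(2L, 3L)), g)
  expect_identical(unclass(tr), unclass(tr2))
  # invalid input clusters are rejected
  expect_error(order_clusters(list(c(1L, 2L), c(3L, 4L), 1L), g), "")
})

test_that("all-singleton clusters order validly", {
  g <- structure(list(
    adjacency = Matrix::sparseMatrix(i = 1, j = 1, x = 0, dims = c(5, 5)),
    n_cols = c(3L, 2L), offsets = c(0L, 3L),
    node_subset = c(1L, 1L, 1L, 2L, 2L), node_col = c(1L, 2L, 3L, 1L, 2L)),
    class = "alignment_graph")
  tr <- order_clusters(as.list(1:5), g)
  expect_true(validate_trace(tr, g))
  expect_length(tr, 5L)
})

test_that("assembling a trace over a single subalignment reproduces it", {
  a <- msa(c(x = "AC-g", z = "-CTG", w = "ACT-"))  # mixed case and gaps
  subs <- list(a)
  g <- build_graph(subs, list())
  tr <- order_clusters(as.list(seq_len(alignment_length(a))), g)
  out <- assemble(tr, subs, g)
  expect_identical(unclass(out), unclass(a))
})

test_that("consistent subalignments and backbones reassemble the reference exactly", {
  fix <- consistent_fixture(n_taxa = 24, n_subsets = 3, seed = 8,
                            n_backbones = 6, rows_per_subset = 3,
                            root_length = 60)
  res <- run_gcm(fix$subalignments, fix$backbones)
  expect_true(validate_trace(res$trace, res$graph))
  cmp <- compare_alignments(res$alignment, fix$reference)
  expect_equal(cmp$sp_error, 0)
  # letter conservation through the merge
  expect_identical(sort(ungapped_sequences(res$alignment)),
                   sort(ungapped_sequences(fix$reference)))
})
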