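test_that("estimate_size equals the written single-line FASTA size", {
  a <- msa(c(a = "ACGTACGTAC", b = "ACGTACGT-C"))
  expect_equal(estimate_size(a), (1 + 1 + 1) * 2 + 2 * 11)
  f <- withr::local_tempfile(fileext = ".fasta")
  for (seed in 1:5) {
    x <- random_msa(sample(1:6, 1), sample(4:25, 1), seed)
    write_fasta(x, f)
    expect_equal(estimate_size(x), file.size(f))
  }
})

test_that("a singleton column dissolves losslessly into a neighboring gap", {
  a <- msa(c(r1 = "A-C", r2 = "-AC"))
  # column 1 holds a single upper-case 'A' of r1; r1 has a gap at column 2
  res <- dissolve_column(a, 1)
  expect_true(res$moved)
  expect_equal(alignment_length(res$alignment), 2L)
  expect_equal(unname(msa_strings(res$alignment)), c("aC", "AC"))
  expect_setequal(homologous_pairs(res$alignment), homologous_pairs(a))
})

test_that("upper-case letters block the move; blocked moves change nothing", {
  a <- msa(c(r = "AG"))
  res <- dissolve_column(a, 1)  # no gap anywhere: blocked both ways
  expect_false(res$moved)
  expect_identical(unclass(res$alignment), unclass(a))
})

test_that("the domino effect shunts intervening lower-case letters along", {
  # row r1: lower-case 't' sits left of the dissolving column; the gap is
  # further left, so 't' must shift to make room
  a <- msa(c(r1 = "-tA", r2 = "C-A"))
  res <- dissolve_column(a, 3)
  expect_true(res$moved)
  expect_equal(unname(msa_strings(res$alignment)), c("ta", "Ca"))
  expect_identical(sort(ungapped_sequences(res$alignment)),
                   sort(ungapped_sequences(a)))
  # blocked on one side only: the move succeeds through the open side
  b <- msa(c(r1 = "GA-")) # left blocked by upper 'G', right gap open
  res2 <- dissolve_column(b, 2)
  expect_true(res2$moved)
  expect_equal(unname(msa_strings(res2$alignment)), "Ga")
})

test_that("dissolving a column with u upper-case letters loses C(u,2) pairs", {
  a <- msa(c(r1 = "A-G", r2 = "A-G", r3 = "--G"))
  before <- homologous_pairs(a)
  res <- dissolve_column(a, 1)  # u = 2, both rows have a gap at column 2
  expect_true(res$moved)
  after <- homologous_pairs(res$alignment)
  expect_equal(length(before) - length(after), choose(2, 2) * 1)
  expect_true(all(after %in% before))
})

test_that("compression is the identity when already under the threshold", {
  a <- random_msa(4, 10, 1)
  res <- compress_alignment(a, size_threshold_bytes = estimate_size(a))
  expect_identical(unclass(res$alignment), unclass(a))
  expect_equal(res$report$columns_dissolved, 0L)
  # idempotence at the fixpoint
  res2 <- compress_alignment(res$alignment, estimate_size(res$alignment))
  expect_identical(unclass(res2$alignment), unclass(res$alignment))
})

test_that("lossless mode never changes the homologous pair set", {
  for (seed in 1:10) {
    a <- random_msa(sample(3:10, 1), sample(10:40, 1), seed, p_gap = 0.4)
    res <- compress_alignment(a, size_threshold_bytes = 0, lossless_only = TRUE)
    expect_setequal(homologous_pairs(res$alignment), homologous_pairs(a))
    expect_true(res$report$lossless)
    expect_equal(res$report$pairs_lost, 0)
    expect_identical(sort(ungapped_sequences(res$alignment)),
                     sort(ungapped_sequences(a)))
  }
})

test_that("lossy accounting matches the brute-force pair-set difference", {
  for (seed in 11:22) {
    a <- random_msa(sample(3:10, 1), sample(10:40, 1), seed, p_gap = 0.4)
    res <- compress_alignment(a, size_threshold_bytes = 0)
    pb <- brute_pairs(a)
    pa <- brute_pairs(res$alignment)
    expect_true(all(pa %in% pb))
    expect_equal(res$report$pairs_lost, length(pb) - length(pa))
    expect_identical(sort(ungapped_sequences(res$alignment)),
                     sort(ungapped_sequences(a)))
    expect_equal(res$report$size_after, estimate_size(res$alignment))
  }
})

test_that("each successful dissolve shortens the alignment by exactly one", {
  a <- random_msa(5, 30, 33, p_gap = 0.5)
  L <- alignment_length(a)
  res <- compress_alignment(a, size_threshold_bytes = 0)
  expect_equal(alignment_length(res$alignment),
               L - res$report$columns_dissolved)
  expect_true(res$report$size_after <= res$report$size_before)
})
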