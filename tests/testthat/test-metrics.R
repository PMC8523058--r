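test_that("an alignment scores zero error against itself", {
  a <- random_msa(6, 20, 3)
  r <- compare_alignments(a, a)
  expect_equal(r$spfp, 0)
  expect_equal(r$spfn, 0)
  expect_equal(r$sp_error, 0)
  expect_equal(r$counts$shared, pair_count(a))
})

test_that("half-right pair sets give spfp = spfn = 1/2", {
  # reference pairs: p=(x0,y0), q=(x1,y1); estimate pairs: p, r=(x2,y1)
  est <- msa(c(x = "ACG-", y = "A-CG"))
  ref2 <- msa(c(x = "ACG-", y = "AC-G"))
  r <- compare_alignments(est, ref2)
  expect_equal(r$counts$reference, 2)
  expect_equal(r$counts$estimated, 2)
  expect_equal(r$counts$shared, 1)
  expect_equal(r$spfp, 0.5)
  expect_equal(r$spfn, 0.5)
  expect_equal(r$sp_error, 0.5)
})

test_that("counts agree with the brute-force pair oracle on random pairs", {
  for (seed in 1:10) {
    n <- sample(2:8, 1)
    base <- random_msa(n, sample(10:30, 1), seed, p_gap = 0.35)
    seqs <- ungapped_sequences(base)
    # second, different alignment over the same sequences: realign
    est <- builtin_progressive_align(seqs, seed = seed)
    pr <- brute_pairs(base)
    pe <- brute_pairs(est)
    r <- compare_alignments(est, base)
    expect_equal(r$counts$reference, length(pr))
    expect_equal(r$counts$estimated, length(pe))
    expect_equal(r$counts$shared, length(intersect(pe, pr)))
    expect_equal(r$spfp, if (length(pe)) length(setdiff(pe, pr)) / length(pe) else 0)
    expect_equal(r$spfn, if (length(pr)) length(setdiff(pr, pe)) / length(pr) else 0)
    expect_gte(r$sp_error, 0)
    expect_lte(r$sp_error, 1)
  }
})

test_that("swapping roles exchanges SPFP and SPFN", {
  a <- builtin_progressive_align(c(u = "ACGTACGGT", v = "ACTTACGT", w = "ACGTACG"))
  b <- builtin_progressive_align(c(u = "ACGTACGGT", v = "ACTTACGT", w = "ACGTACG"),
                                 gap_open = -1, gap_extend = -1)
  r_ab <- compare_alignments(a, b)
  r_ba <- compare_alignments(b, a)
  expect_equal(r_ab$spfp, r_ba$spfn)
  expect_equal(r_ab$spfn, r_ba$spfp)
})

test_that("the estimate is restricted to the reference ids before scoring", {
  est <- random_msa(6, 20, 7)
  ref <- restrict_alignment(est, paste0("s", 1:3))
  r <- compare_alignments(est, ref)
  expect_equal(r$sp_error, 0)  # induced restriction of itself
  # mismatching sequences are a data error
  bad <- msa(c(s1 = "TTTT"))
  expect_error(compare_alignments(est, bad), "differ")
  expect_error(compare_alignments(ref, est), "missing")
})

test_that("pair_count accumulates choose(u,2) per column", {
  a <- msa(c(r1 = "A-", r2 = "A-", r3 = "A-", r4 = "A-"))
  expect_equal(pair_count(a), 6)  # C(4,2), all-gap column contributes 0
  expect_equal(pair_count(msa(c(r1 = "-"))), 0)
})

test_that("lower-case letters are excluded on both sides", {
  ref <- msa(c(x = "AC", y = "AC"))
  est_l <- msa(c(x = "aC", y = "aC"))  # first column dissolved in estimate
  r <- compare_alignments(est_l, ref)
  expect_equal(r$counts$estimated, 1)
  expect_equal(r$spfn, 0.5)  # the reference pair in column 1 is now missed
  expect_equal(r$spfp, 0)
})
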