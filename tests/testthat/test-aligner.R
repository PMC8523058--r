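test_that("identical sequences align gaplessly", {
  a <- builtin_progressive_align(c(x = "ACGT", y = "ACGT"))
  expect_equal(alignment_length(a), 4L)
  expect_false(any(unclass(a) == "-"))
})

test_that("single sequence aligns to itself", {
  seqs <- c(only = "ACGTTACG")
  a <- builtin_progressive_align(seqs)
  expect_equal(unname(msa_strings(a)), unname(seqs))
})

test_that("pairwise alignment scores match an independent Gotoh oracle", {
  cases <- list(c("ACGT", "AGT"), c("AAAA", "AA"), c("ACGTACGT", "TACG"),
                c("GATTACA", "GCATGCT"))
  for (cs in cases) {
    a <- builtin_progressive_align(stats::setNames(cs, c("p", "q")))
    expect_equal(sort(unname(ungapped_sequences(a))), sort(toupper(cs)))
    # score of the produced alignment == optimal score by the oracle
    mat <- unclass(a)
    sc <- 0
    gap_state <- c(FALSE, FALSE)
    for (j in seq_len(ncol(mat))) {
      col <- mat[, j]
      if (all(col != "-")) {
        sc <- sc + if (col[1] == col[2]) 1 else -1
        gap_state[] <- FALSE
      } else {
        r <- which(col == "-")
        sc <- sc + if (gap_state[r]) -1 else -4
        gap_state[r] <- TRUE
        gap_state[-r] <- FALSE
      }
    }
    expect_equal(sc, nw_affine_score(cs[1], cs[2]))
  }
  # per-spec toy case: one indel gives exactly one gap column
  a <- builtin_progressive_align(c(x = "ACGT", y = "AGT"))
  expect_equal(sum(unclass(a) == "-"), 1L)
})

test_that("letters are conserved over random inputs, DNA and protein", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(2:12, 1)
    alpha <- if (seed %% 2 == 0) c("A", "C", "G", "T")
             else strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(alpha, sample(20:60, 1), replace = TRUE), collapse = ""),
      character(1))
    names(seqs) <- paste0("q", seq_len(n))
    a <- builtin_progressive_align(seqs, seed = seed)
    expect_setequal(msa_ids(a), names(seqs))
    expect_identical(ungapped_sequences(a)[names(seqs)], seqs)
  }
})

test_that("the aligner is deterministic", {
  set.seed(1)
  seqs <- stats::setNames(replicate(6, paste(sample(c("A", "C", "G", "T"), 40,
                                                    replace = TRUE),
                                             collapse = "")), paste0("d", 1:6))
  expect_identical(unclass(builtin_progressive_align(seqs, seed = 2)),
                   unclass(builtin_progressive_align(seqs, seed = 2)))
})

test_that("a failing external aligner falls back to the built-in one", {
  seqs <- c(a = "ACGTAC", b = "ACTTAC", c = "AGGTAC")
  subs <- list(msa(c(a = "ACGTAC", b = "ACTTAC")), msa(c(c = "AGGTAC")))
  sample <- data.frame(subset = c(1L, 1L, 2L), id = c("a", "b", "c"))
  broken <- function(sequences, seed = 0) stop("adapter unavailable")
  expect_warning(aln <- align_backbone(sample, subs, aligner = broken),
                 "falling back")
  expect_setequal(msa_ids(aln), names(seqs))
  expect_identical(ungapped_sequences(aln)[names(seqs)], seqs)
})
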