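test_that("zero rates reproduce the root everywhere, gaplessly", {
  cfg <- sim_config(8, root_length = 50, subst_rate = 0, ins_rate = 0,
                    del_rate = 0, seed = 3)
  sim <- simulate_evolution(cfg)
  expect_equal(length(unique(sim$sequences)), 1L)
  expect_equal(alignment_length(sim$true_alignment), 50L)
  expect_false(any(unclass(sim$true_alignment) == "-"))
  expect_equal(measure_pdistance(sim$true_alignment)$avg, 0)
})

test_that("without indels the true alignment has root length and no gaps", {
  cfg <- sim_config(10, root_length = 80, subst_rate = 1, ins_rate = 0,
                    del_rate = 0, seed = 4)
  sim <- simulate_evolution(cfg)
  expect_equal(alignment_length(sim$true_alignment), 80L)
  expect_false(any(unclass(sim$true_alignment) == "-"))
})

test_that("the true alignment conserves the leaf sequences exactly", {
  for (seed in 1:5) {
    sim <- simulate_evolution(sim_config(12, root_length = 60,
                                         expected_pdistance = 0.3,
                                         seed = seed))
    expect_identical(ungapped_sequences(sim$true_alignment)[names(sim$sequences)],
                     sim$sequences)
    expect_setequal(sim$tree$tip.label, names(sim$sequences))
  }
})

test_that("scaling substitution pressure increases p-distance (Monte Carlo)", {
  lo <- vapply(1:8, function(s) {
    sim <- simulate_evolution(sim_config(10, root_length = 60, subst_rate = 0.5,
                                         branch_scale = 0.3, seed = s))
    measure_pdistance(sim$true_alignment)$avg
  }, numeric(1))
  hi <- vapply(1:8, function(s) {
    sim <- simulate_evolution(sim_config(10, root_length = 60, subst_rate = 2,
                                         branch_scale = 0.3, seed = s))
    measure_pdistance(sim$true_alignment)$avg
  }, numeric(1))
  expect_gt(mean(hi), mean(lo))
})

test_that("presets hit their target divergence regimes (Monte Carlo)", {
  p16 <- vapply(1:6, function(s)
    measure_pdistance(simulate_evolution(
      sim_preset("16s-like", n_taxa = 30, seed = s))$true_alignment)$avg,
    numeric(1))
  prn <- vapply(1:6, function(s)
    measure_pdistance(simulate_evolution(
      sim_preset("rnasim-like", n_taxa = 30, seed = s))$true_alignment)$avg,
    numeric(1))
  expect_lt(abs(mean(p16) - 0.2), 0.1)
  expect_lt(abs(mean(prn) - 0.4), 0.1)
})

test_that("true-alignment pairs restricted to a subset equal the induced subalignment's", {
  sim <- simulate_evolution(sim_config(10, root_length = 40,
                                       expected_pdistance = 0.3, seed = 9))
  ref <- sim$true_alignment
  keep <- sample(msa_ids(ref), 4)
  sub <- restrict_alignment(ref, keep)
  all_pairs <- homologous_pairs(ref)
  want <- all_pairs[vapply(strsplit(all_pairs, "\r"), function(p)
    all(c(p[1], p[3]) %in% keep), logical(1))]
  expect_setequal(homologous_pairs(sub), want)
})

test_that("p-distance arithmetic and conventions", {
  expect_equal(measure_pdistance(msa(c(a = "AC", b = "AG")))$avg, 0.5)
  expect_equal(measure_pdistance(msa(c(a = "AC", b = "AC")))$max, 0)
  # pair with disjoint gap support is skipped
  m <- msa(c(a = "A--", b = "-C-", c = "ACG"))
  r <- measure_pdistance(m)
  expect_equal(r$avg, 0)  # only (a,c) and (b,c) comparable, both match
  expect_error(measure_pdistance(msa(c(a = "AC"))), "2 rows")
  expect_identical(simulate_evolution(sim_config(5, seed = 1))$sequences,
                   simulate_evolution(sim_config(5, seed = 1))$sequences)
})
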