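test_that("haplotypes obey Hardy-Weinberg and random-mating couples have uncorrelated scores", {
  par <- simulate_parents(L = 1, n = 2e4, freqs = 0.5, seed = 61)
  counts <- par$mother$hap1 + par$mother$hap2
  geno_freq <- tabulate(counts + 1, nbins = 3) / 2e4
  expect_equal(geno_freq, c(0.25, 0.5, 0.25), tolerance = 0.02)

  par2 <- simulate_parents(L = 200, n = 4e3, freqs = runif(200, 0.1, 0.9),
                           seed = 62)
  sm <- pgsbias:::pgs_from_counts(par2$mother$hap1 + par2$mother$hap2,
                                  par2$weights, par2$freqs)
  sf <- pgsbias:::pgs_from_counts(par2$father$hap1 + par2$father$hap2,
                                  par2$weights, par2$freqs)
  expect_lt(abs(cor(sm, sf)), 0.04)
  expect_error(simulate_parents(5, 100, 1.2, seed = 1), "frequencies")
})

test_that("assortative matching calibrates to the target spousal correlation and errors when unattainable", {
  par <- simulate_parents(L = 300, n = 5e3, freqs = runif(300, 0.1, 0.9),
                          spousal_corr = 0.4, seed = 63)
  expect_lt(abs(par$realized_spousal_corr - 0.4), 0.021)
  tr <- mate_and_transmit(par, seed = 64)
  expect_lt(abs(cor(tr$scores$G_M, tr$scores$G_F) - 0.4), 0.06)

  # two couples: the spousal correlation is forced to +/-1, so an
  # intermediate target cannot be reached by rank matching
  expect_error(simulate_parents(L = 50, n = 2, freqs = 0.5,
                                spousal_corr = 0.5, seed = 65,
                                max_iter = 10),
               "could not reach")
})

test_that("transmission is Mendelian at every locus and half-scores are exactly additive", {
  par <- simulate_parents(L = 50, n = 500, freqs = runif(50, 0.2, 0.8),
                          seed = 66)
  tr <- mate_and_transmit(par, seed = 67)
  # every transmitted maternal allele is one of the mother's two alleles
  expect_true(all(tr$child_mat == par$mother$hap1 |
                  tr$child_mat == par$mother$hap2))
  expect_true(all(tr$pat_nt == par$father$hap1 |
                  tr$pat_nt == par$father$hap2))
  # transmitted + non-transmitted = full parental genome
  expect_equal(tr$child_mat + tr$mat_nt, par$mother$hap1 + par$mother$hap2)
  sc <- tr$scores
  expect_equal(sc$G_Mt + sc$G_Mnt, sc$G_M, tolerance = 1e-12)
  expect_equal(sc$G_Ft + sc$G_Fnt, sc$G_F, tolerance = 1e-12)
})

test_that("random mating: parent-child score correlation is one half and genome halves are independent", {
  par <- simulate_parents(L = 800, n = 4e3, freqs = runif(800, 0.1, 0.9),
                          seed = 68)
  tr <- mate_and_transmit(par, seed = 69)
  sc <- tr$scores
  expect_lt(abs(cor(sc$G_M, sc$G_C) - 0.5), 0.03)
  expect_lt(abs(cor(sc$G_F, sc$G_C) - 0.5), 0.03)
  expect_lt(abs(cor(sc$G_Mt, sc$G_Mnt)), 0.05)
})

test_that("score computation: zero noise returns the true score, noise calibrates to the target reliability, weight-locus permutation is invariant", {
  par <- simulate_parents(L = 400, n = 1e4, freqs = runif(400, 0.1, 0.9),
                          seed = 70)
  counts <- par$mother$hap1 + par$mother$hap2
  exact <- compute_pgs(counts, par$weights, par$freqs, reliability = 1)
  expect_identical(exact$true, exact$observed)
  expect_equal(var(exact$true), 1, tolerance = 0.05)

  noisy <- compute_pgs(counts, par$weights, par$freqs, reliability = 0.10,
                       seed = 71)
  expect_lt(abs(noisy$reliability_hat - 0.10), 0.01)

  perm <- sample(400)
  permuted <- compute_pgs(counts[, perm], par$weights[perm], par$freqs[perm],
                          reliability = 1)
  expect_equal(permuted$true, exact$true, tolerance = 1e-12)
  expect_error(compute_pgs(counts, rep(0, 400), par$freqs), "zero-variance")
})

test_that("family phenotype signatures: nurture, passive rGE, and dynastic effects appear when and only when configured", {
  par <- simulate_parents(L = 400, n = 3e3, freqs = runif(400, 0.1, 0.9),
                          seed = 72)
  tr <- mate_and_transmit(par, seed = 73)
  se <- 1 / sqrt(3e3)

  # pure individual effect: non-transmitted scores carry no signal
  pure <- simulate_family_phenotypes(
    tr, family_effect_config(individual_effect = 0.5), seed = 74)
  expect_lt(abs(cor(pure$scores$G_Mnt, pure$scores$Y_C)), 3 * se)
  expect_lt(abs(cor(pure$scores$G_Fnt, pure$scores$Y_C)), 3 * se)

  # paternal nurture without an evocative path still correlates the child
  # score with the paternal environment (passive rGE via transmission)
  nurt <- simulate_family_phenotypes(
    tr, family_effect_config(individual_effect = 0, nurture_f = 0.5,
                             parent_env_f = 0.6), seed = 75)
  expect_gt(cor(nurt$scores$G_C, nurt$scores$E_F), 3 * se)

  # dynastic: child score correlates with the outcome despite no
  # individual effect
  expect_gt(cor(nurt$scores$G_C, nurt$scores$Y_C), 3 * se)

  # evocative path: child score correlates with the maternal environment
  # beyond the passive level
  evo <- simulate_family_phenotypes(
    tr, family_effect_config(evocative_m = 0.4, parent_env_m = 0),
    seed = 76)
  expect_lt(abs(cor(evo$scores$G_C, evo$scores$E_M) - 0.4), 0.06)

  expect_error(simulate_family_phenotypes(
    tr, family_effect_config(individual_effect = 0.9, nurture_m = 0.9),
    seed = 77), "variance decomposition")
})

test_that("nurture regressions separate individual from familial effects", {
  par <- simulate_parents(L = 400, n = 3e3, freqs = runif(400, 0.1, 0.9),
                          seed = 78)
  tr <- mate_and_transmit(par, seed = 79)
  cfg <- family_effect_config(individual_effect = 0.3, nurture_m = 0.4,
                              nurture_f = 0.4, parent_env_m = 0.6,
                              parent_env_f = 0.6)
  tr <- simulate_family_phenotypes(tr, cfg, seed = 80)
  est <- estimate_nurture(tr, n_boot = 100, seed = 81)

  # the marginal child-score coefficient absorbs familial effects, so it
  # exceeds the parental-score-adjusted one
  marg <- est$child_only$estimate[1]
  adj <- est$child_adjusted$estimate[est$child_adjusted$term == "G_C"]
  expect_gt(marg, adj)

  # non-transmitted coefficients are positive under nurture
  nt <- est$non_transmitted
  expect_gt(nt$estimate[nt$term == "G_Mnt"], 3 * nt$se[nt$term == "G_Mnt"])

  # and the adjusted child coefficient recovers the individual effect
  adj_se <- est$child_adjusted$se[est$child_adjusted$term == "G_C"]
  expect_lt(abs(adj - 0.3), 4 * adj_se)
})

test_that("stratification: spurious association without true effects, removed by the ancestry label, true effect preserved", {
  null <- stratification_scenario(delta_freq = 0.1, outcome_offset = 0.5,
                                  n_per_pop = 4e3, seed = 82)
  expect_gt(null$unadjusted, 0.05)
  expect_lt(abs(null$adjusted), 3 / sqrt(8e3))

  none <- stratification_scenario(delta_freq = 0, outcome_offset = 0.5,
                                  n_per_pop = 4e3, seed = 83)
  expect_lt(abs(none$unadjusted), 3 / sqrt(8e3))

  eff <- stratification_scenario(delta_freq = 0.1, outcome_offset = 0.5,
                                 n_per_pop = 4e3, seed = 84,
                                 true_effect = 0.25)
  expect_lt(abs(eff$adjusted - 0.25), 0.04)
})

test_that("trio score tables round-trip through TSV", {
  par <- simulate_parents(L = 20, n = 50, freqs = 0.5, seed = 85)
  tr <- mate_and_transmit(par, seed = 86)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_trios_tsv(tr, f)
  back <- read_cohort_tsv(f)
  expect_equal(back$G_C, tr$scores$G_C, tolerance = 1e-10)
})
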