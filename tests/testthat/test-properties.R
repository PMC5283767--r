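# Property-style checks of the recursion against independent oracles and
# closed-form limits.

test_that("engine agrees with the brute-force mating-table oracle on random states", {
  set.seed(101)
  for (i in 1:25) {
    F <- random_state()
    W <- random_fitness()
    r <- sample(c(0, 0.1, 0.25, 0.5), 1)
    engine <- unclass(step(F, W, r))["f", ]
    oracle <- oracle_next_generation(F, W, r)
    expect_lt(max(abs(engine - oracle)), 1e-10)
  }
})

test_that("frequencies are conserved through every operation", {
  set.seed(202)
  for (i in 1:20) {
    F <- random_state()
    W <- random_fitness()
    r <- runif(1, 0, 0.5)
    G <- gamete_frequencies(F, W, r)
    expect_equal(unname(rowSums(unclass(G))), c(1, 1))
    expect_true(all(unclass(G) >= 0))
    F2 <- next_generation(G)
    expect_equal(unname(rowSums(unclass(F2))), c(1, 1))
    expect_true(all(unclass(F2) >= 0))
  }
})

test_that("neutral limit: allele frequencies invariant, LD decays by (1 - r)", {
  neutral <- matrix(1, 2, 10, dimnames = list(c("m", "f"), geno_labels))
  set.seed(303)
  for (r in c(0.05, 0.2, 0.5)) {
    # build a state with deliberate linkage disequilibrium
    g <- matrix(0, 2, 4, dimnames = list(c("m", "f"), hap_labels))
    g[, "SS"] <- 0.4
    g[, "RR"] <- 0.4
    g[, "SR"] <- 0.1
    g[, "RS"] <- 0.1
    F <- next_generation(gamete_freq(g))
    af0 <- allele_frequencies(F)$avg
    D <- linkage_disequilibrium(gamete_freq(g))
    for (gen in 1:5) {
      G <- gamete_frequencies(F, neutral, r)
      # closed-form neutral decay of gametic LD
      expect_equal(linkage_disequilibrium(G), D * (1 - r), tolerance = 1e-12)
      D <- linkage_disequilibrium(G)
      F <- next_generation(G)
      expect_equal(allele_frequencies(F)$avg, af0, tolerance = 1e-12)
    }
  }
})

test_that("with one insecticide inert the model reduces to the one-locus recursion", {
  # insecticide 2 never deployed, no costs: locus 2 is neutral and locus 1
  # follows the scalar selection recursion exactly
  p1 <- insecticide_params(0.8, 0.3, rr_restoration = 0.6)
  p2 <- insecticide_params(0.9, 0.5, rr_restoration = 0.9)
  Wn <- two_locus_fitness_tables(single_locus_fitness_table(p1, p2))
  al <- matrix(0, 2, 9, dimnames = list(c("m", "f"), niche_labels))
  al["f", "A0"] <- 0.7
  al["f", "00"] <- 0.3
  al["m", "A0"] <- 0.42  # males less exposed: sexes must be tracked apart
  al["m", "00"] <- 0.58
  W <- marginal_fitness(Wn, exposure_profile(al))

  w_solo <- function(sex) {
    ex <- unclass(al)[sex, "A0"]
    c(
      ex * 0.2 + (1 - ex),
      ex * (0.2 + 0.3 * 0.48) + (1 - ex),
      ex * (0.2 + 0.48) + (1 - ex)
    )
  }
  geno <- c(SS = 0.98^2, RS = 2 * 0.02 * 0.98, RR = 0.02^2)
  F <- init_from_allele_freqs(0.02, 0.15)
  for (gen in 1:6) {
    F <- step(F, W, 0.5)
    geno <- oracle_single_locus_step(geno, w_solo("m"), w_solo("f"))
    q_hand <- geno[["RS"]] / 2 + geno[["RR"]]
    af <- allele_frequencies(F)
    expect_lt(abs(af$m[["locus1"]] - q_hand), 1e-12)
    expect_lt(abs(af$f[["locus1"]] - q_hand), 1e-12)
    # the undeployed locus keeps its starting frequency
    expect_lt(abs(af$avg[["locus2"]] - 0.15), 1e-12)
  }
})

test_that("swapping insecticide labels swaps outputs exactly", {
  p1 <- insecticide_params(0.9, 0.2, rr_restoration = 0.8)
  p2 <- insecticide_params(0.5, 0.7, rr_restoration = 0.4)
  mk_cal <- function(a, b, s1, s2) {
    resistance_calibration(a, b, start_freq = c(s1, s2), exposure = 0.8,
                           male_exposure_prop = 0.6, correct_mix_deploy = 0.9,
                           max_generations = 200)
  }
  cal <- mk_cal(p1, p2, 0.02, 0.005)
  cal_sw <- mk_cal(p2, p1, 0.005, 0.02)

  mx <- run_mixture(cal)
  mx_sw <- run_mixture(cal_sw)
  expect_equal(unname(mx$t_cross), unname(rev(mx_sw$t_cross)))
  expect_equal(mx$trajectory$freq_R1_f, mx_sw$trajectory$freq_R2_f)
  expect_equal(mx$trajectory$freq_R2_m, mx_sw$trajectory$freq_R1_m)
  expect_equal(mx$trajectory$LD, mx_sw$trajectory$LD)

  sq <- run_sequential(cal, first = 1L)
  sq_sw <- run_sequential(cal_sw, first = 2L)
  expect_equal(sq$t_both, sq_sw$t_both)
  expect_equal(unname(sq$t_cross), unname(rev(sq_sw$t_cross)))
})

test_that("equal exposure of the sexes keeps male and female frequencies identical", {
  cal <- curtis_idealised_calibration(0.05, 0.01)
  mx <- run_mixture(cal)
  expect_equal(mx$trajectory$freq_R1_m, mx$trajectory$freq_R1_f)
  expect_equal(mx$trajectory$freq_R2_m, mx$trajectory$freq_R2_f)
})

test_that("a neutral generation of random mating restores Hardy-Weinberg and, in two steps, linkage equilibrium structure", {
  neutral <- matrix(1, 2, 10, dimnames = list(c("m", "f"), geno_labels))
  set.seed(404)
  F <- random_state()
  af <- allele_frequencies(F)$avg
  # with unlinked loci the gamete pool reaches linkage equilibrium at the
  # rate (1 - r) = 0.5 per generation; after several neutral generations
  # the state converges to the Hardy-Weinberg / linkage-equilibrium state
  # of the same allele frequencies
  for (i in 1:40) F <- step(F, neutral, 0.5)
  expect_equal(unclass(F), unclass(init_from_allele_freqs(af[1], af[2])),
               tolerance = 1e-9)
})
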