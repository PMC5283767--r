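test_that("parameter sampling respects ranges, distributions and the seed", {
  sets <- sample_parameter_sets(500, seed = 9)
  expect_equal(nrow(sets), 500L)
  expect_true(all(sets$start_freq_allele1 >= 1e-4 & sets$start_freq_allele1 <= 0.1))
  expect_true(all(sets$start_freq_allele2 >= 1e-4 & sets$start_freq_allele2 <= 0.1))
  expect_true(all(sets$exposure >= 0.1 & sets$exposure <= 0.9))
  expect_true(all(sets$effectiveness_ins1 >= 0.3 & sets$effectiveness_ins1 <= 1))
  expect_true(all(sets$rr_restoration_ins2 >= 0.2 & sets$rr_restoration_ins2 <= 1))
  expect_true(all(sets$correct_mix_deploy >= 0.5 & sets$correct_mix_deploy <= 1))

  # log-uniform sampling spreads mass evenly across decades
  lg <- log10(sets$start_freq_allele1)
  expect_gt(mean(lg < -2), 0.55)  # two of the three decades lie below 1e-2

  # reproducibility and independence from the ambient RNG state
  again <- sample_parameter_sets(500, seed = 9)
  expect_identical(sets, again)
  expect_false(identical(sets, sample_parameter_sets(500, seed = 10)))

  # degenerate range collapses to a constant column
  rg <- parameter_ranges(exposure = list(dist = "uniform", lo = 0.4, hi = 0.4))
  expect_equal(unique(sample_parameter_sets(50, 1, rg)$exposure), 0.4)

  expect_error(parameter_ranges(exposure = list(dist = "uniform", lo = 1, hi = 0)),
               "invalid bounds")
  expect_error(
    parameter_ranges(start_freq_allele1 = list(dist = "log_uniform", lo = 0, hi = 1)),
    "positive"
  )
})

test_that("sensitivity records are consistent with the deployment module", {
  # inject the idealised parameters as one sampled set
  sets <- data.frame(
    start_freq_allele1 = 0.01, start_freq_allele2 = 0.001,
    exposure = 0.9, male_exposure_prop = 1,
    effectiveness_ins1 = 1, effectiveness_ins2 = 1,
    dominance_allele1 = 1, dominance_allele2 = 1,
    rr_restoration_ins1 = 1, rr_restoration_ins2 = 1,
    correct_mix_deploy = 1
  )
  rec <- run_sensitivity(sets)
  expect_identical(rec$t_seq, 8L)
  expect_identical(rec$t_solo1, 3L)
  expect_identical(rec$t_solo2, 4L)
  cal <- curtis_idealised_calibration()
  expect_identical(rec$t_mix_both, run_mixture(cal)$t_both)
  expect_identical(rec$t_adapt_both, run_adaptive(cal)$t_both)
  expect_equal(rec$resist_start_1_div_2, 10)
  expect_equal(rec$resist_start_hi_div_lo, 10)

  # low exposure and rare alleles: typically censored within 500 generations
  slow <- sets
  slow$exposure <- 0.1
  slow$start_freq_allele1 <- 1e-4
  slow$start_freq_allele2 <- 1e-4
  slow$effectiveness_ins1 <- 0.3
  slow$effectiveness_ins2 <- 0.3
  slow$dominance_allele1 <- 0
  slow$dominance_allele2 <- 0
  rec2 <- run_sensitivity(slow)
  expect_true(rec2$seq_censored & rec2$mix_censored)
})

test_that("PRCC behaves on independent, monotone and collinear inputs", {
  set.seed(55)
  n <- 400
  X <- data.frame(a = runif(n), b = runif(n), c = runif(n))
  y <- 3 * X$a + rnorm(n, sd = 1e-3)
  co <- prcc(X, y)
  expect_gt(co[["a"]], 0.99)
  expect_lt(abs(co[["b"]]), 3 / sqrt(n))
  expect_lt(abs(co[["c"]]), 3 / sqrt(n))

  # strictly decreasing dependence gives a coefficient near -1
  co2 <- prcc(X, -X$b + rnorm(n, sd = 1e-3))
  expect_lt(co2[["b"]], -0.99)

  # constant columns have no defined coefficient
  Xc <- cbind(X, k = 1)
  expect_true(is.na(prcc(Xc, y)[["k"]]))
  expect_error(prcc(X[1:2, ], y[1:2]), "at least 3")
})

test_that("PRCC matches the inverse-correlation-matrix oracle", {
  set.seed(77)
  n <- 50
  X <- data.frame(
    a = runif(n), b = runif(n), c = runif(n), d = runif(n)
  )
  y <- 2 * X$a - X$b + 0.5 * X$c * X$d + rnorm(n, sd = 0.2)
  expect_lt(max(abs(prcc(X, y) - oracle_prcc(X, y))), 1e-10)
})

test_that("strategy comparison applies strict inequality, margins and censoring", {
  base <- data.frame(
    exposure = 0.5, effectiveness_ins1 = 0.8, effectiveness_ins2 = 0.7,
    effectiveness_sum = 1.5,
    t_seq = c(7L, 10L, 10L, 400L, NA, 30L),
    t_mix_both = c(7L, 12L, 13L, NA, NA, NA),
    t_adapt_both = c(7L, 12L, 13L, NA, NA, 25L),
    seq_censored = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    mix_censored = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
    adapt_censored = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE)
  )
  lab0 <- compare_strategies(base, margin = 0, mixture_time = "mixture")
  # ties favour sequential; censored-mixture-only runs favour the mixture;
  # runs censored under both strategies are dropped
  expect_equal(nrow(lab0), 5L)
  expect_equal(as.character(lab0$label),
               c("sequential", "mixture", "mixture", "mixture", "mixture"))

  # a 20% margin: 12 vs 10 is no longer enough
  lab2 <- compare_strategies(base, margin = 0.2, mixture_time = "mixture")
  expect_equal(as.character(lab2$label)[2], "sequential")
  expect_equal(as.character(lab2$label)[3], "mixture")

  # the adaptive comparison reads the adaptive columns: the last run's
  # adaptive time (25) does not beat its sequential time (30)
  laba <- compare_strategies(base, margin = 0, mixture_time = "adaptive")
  expect_equal(nrow(laba), 5L)
  expect_equal(as.character(laba$label)[5], "sequential")
})

test_that("decision-line fitting recovers a planted linear boundary", {
  set.seed(88)
  n <- 4000
  exposure <- runif(n, 0.1, 0.9)
  eff_sum <- runif(n, 0.6, 2)
  # plant the boundary eff_sum = 1.1 + 0.5 * exposure with noisy integer
  # times on either side
  gap <- eff_sum - (1.1 + 0.5 * exposure)
  t_seq <- rep(100L, n)
  t_mix <- as.integer(100 + round(60 * gap))
  rec <- data.frame(
    exposure = exposure, effectiveness_sum = eff_sum,
    t_seq = t_seq, t_mix_both = t_mix, t_adapt_both = t_mix,
    seq_censored = FALSE, mix_censored = FALSE, adapt_censored = FALSE
  )
  dl <- fit_decision_line(rec, margin = 0, mixture_time = "mixture")
  expect_gt(dl$n_boundary, 30)
  expect_equal(dl$intercept, 1.1, tolerance = 0.05)
  expect_equal(dl$slope, 0.5, tolerance = 0.1)

  lab <- compare_strategies(rec, margin = 0, mixture_time = "mixture")
  rates <- classification_rates(lab, dl)
  expect_gt(rates[["tpr"]], 0.95)
  expect_gt(rates[["tnr"]], 0.95)

  # a line predicting all-sequential has zero true positive rate
  high_line <- dl
  high_line$intercept <- 100
  expect_equal(classification_rates(lab, high_line)[["tpr"]], 0)

  expect_error(fit_decision_line(rec[1:3, ], margin = 0.2),
               "fewer than 2 boundary")
})

test_that("classification trees split on the planted variable and prune sanely", {
  set.seed(99)
  n <- 2000
  dat <- data.frame(
    exposure = runif(n, 0.1, 0.9),
    effectiveness_ins1 = runif(n, 0.3, 1),
    effectiveness_ins2 = runif(n, 0.3, 1),
    dominance_allele1 = runif(n),
    dominance_allele2 = runif(n)
  )
  # plant an axis-aligned rule on one effectiveness variable
  dat$label <- factor(ifelse(dat$effectiveness_ins1 > 0.7, "mixture", "sequential"),
                      levels = c("sequential", "mixture"))
  tree <- build_classification_tree(dat)
  root_var <- as.character(tree$unpruned$frame$var[1])
  expect_equal(root_var, "effectiveness_ins1")
  split_val <- tree$unpruned$splits[1, "index"]
  expect_equal(unname(split_val), 0.7, tolerance = 0.05)
  # the pruned tree still classifies essentially perfectly
  pred <- predict(tree$pruned, dat, type = "class")
  expect_gt(mean(pred == dat$label), 0.98)

  # degenerate single-class input yields a single leaf
  one <- dat
  one$label <- factor("sequential", levels = c("sequential", "mixture"))
  t1 <- build_classification_tree(one)
  expect_equal(nrow(t1$pruned$frame), 1L)
})
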