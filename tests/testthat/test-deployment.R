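test_that("exposure profiles follow the operational mixture arithmetic", {
  # female exposure 0.8, correct mixture deployment 0.7
  spec <- deployment_spec("mixture", exposure = 0.8, correct_mix_deploy = 0.7,
                          male_exposure_prop = 0.6)
  al <- unclass(build_exposure_profile(spec))
  expect_equal(unname(al["f", c("AB", "A0", "0B", "00")]),
               c(0.56, 0.12, 0.12, 0.2))
  # males at 0.6 of female exposure; removed mass joins the unexposed niche
  expect_equal(unname(al["m", c("AB", "A0", "0B", "00")]),
               c(0.336, 0.072, 0.072, 0.52))
  expect_equal(unname(rowSums(al)), c(1, 1))

  # single-insecticide deployment puts all exposure in that niche
  al2 <- unclass(build_exposure_profile(
    deployment_spec("single", insecticide = 2, exposure = 0.9)
  ))
  expect_equal(unname(al2["f", "0B"]), 0.9)
  expect_equal(unname(al2["f", "00"]), 0.1)
  expect_equal(sum(al2[, c("a0", "A0", "0b", "ab", "Ab", "aB", "AB")]), 0)

  # zero exposure: everything unexposed for both sexes
  al3 <- unclass(build_exposure_profile(deployment_spec("mixture", exposure = 0)))
  expect_equal(unname(al3[, "00"]), c(1, 1))
})

test_that("restoration coefficients cap RR fitness at one", {
  expect_equal(selection_from_restoration(1, 0.9), 0.9)
  expect_equal(selection_from_restoration(0, 0.7), 0)
  expect_equal(selection_from_restoration(0.5, 0.6), 0.3)
  p <- insecticide_params(0.9, 1, rr_restoration = 1)
  w <- single_locus_fitness_table(p, p)
  expect_equal(unname(w["locus1", "RR", "A0"]), 1)
})

test_that("solo deployment reproduces the idealised crossing times", {
  # starts 1e-2 / 1e-3 / 1e-4 cross the 50% threshold at generations 3/4/5
  expected <- c(3L, 4L, 5L)
  starts <- c(1e-2, 1e-3, 1e-4)
  for (i in seq_along(starts)) {
    cal <- curtis_idealised_calibration(0.3, starts[i])
    out <- run_single(cal, insecticide = 2)
    expect_identical(out$t_cross[["insecticide2"]], expected[i])
    expect_false(out$censored)
    # trajectory includes generation 0 through the crossing generation
    expect_equal(out$trajectory$generation, 0:expected[i])
  }
})

test_that("sequential totals equal first crossing + one-generation lag + second crossing", {
  grid <- curtis_table3_grid()
  # published sequential totals for the idealised grid
  expected_total <- c(7L, 6L, 5L, 8L, 7L, 6L, 9L, 8L, 7L)
  for (i in seq_len(nrow(grid))) {
    cal <- curtis_idealised_calibration(grid$start_freq_1[i], grid$start_freq_2[i])
    sq <- run_sequential(cal, first = 1L)
    solo1 <- run_single(cal, insecticide = 1)
    solo2 <- run_single(cal, insecticide = 2)
    t1 <- solo1$t_cross[["insecticide1"]]
    t2 <- solo2$t_cross[["insecticide2"]]
    expect_identical(sq$t_both, t1 + 1L + t2)
    expect_identical(sq$t_both, expected_total[i])
    expect_identical(sq$t_cross[["insecticide1"]], t1)
  }
})

test_that("sequential handles degenerate and censored cases", {
  # first insecticide already above threshold: t1 = 0, lag still applied
  cal <- curtis_idealised_calibration(0.6, 0.001)
  sq <- run_sequential(cal, first = 1L)
  expect_identical(sq$t_cross[["insecticide1"]], 0L)
  expect_identical(sq$t_both, 0L + 1L + 4L)

  # an unreachable threshold censors the run
  cal2 <- curtis_idealised_calibration(0.01, 0.001, threshold = 1)
  sq2 <- run_sequential(cal2, first = 1L, max_generations = 50)
  expect_true(sq2$censored)
  expect_true(is.na(sq2$t_both))
  mx2 <- run_mixture(cal2, max_generations = 50)
  expect_true(mx2$censored)
})

test_that("mixture outcomes record first and both crossings", {
  cal <- curtis_idealised_calibration(0.01, 0.0001)
  mx <- run_mixture(cal)
  # rarer allele in the mixture crosses at generation 9 on this grid row
  expect_identical(mx$t_cross[["insecticide2"]], 9L)
  expect_true(mx$t_first <= mx$t_both)

  # symmetric calibration and equal starts: both alleles cross together
  cal_sym <- curtis_idealised_calibration(0.01, 0.01)
  mx_sym <- run_mixture(cal_sym)
  expect_identical(mx_sym$t_cross[["insecticide1"]],
                   mx_sym$t_cross[["insecticide2"]])
})

test_that("adaptive mixture interpolates between mixture and sequential", {
  cal <- curtis_idealised_calibration(0.01, 0.001)
  mx <- run_mixture(cal)
  ad <- derive_adaptive(mx, cal)
  expect_identical(ad$t_first, mx$t_first)
  expect_true(ad$t_both <= mx$t_both)

  # reconstruct the solo remainder by hand: a fresh equilibrium start at
  # the surviving allele's frequency when the first allele crossed
  row <- mx$trajectory[mx$trajectory$generation == mx$t_first, ]
  surviving <- if (mx$t_cross[[1]] == mx$t_first) 2L else 1L
  qs <- if (surviving == 2L) {
    mean(c(row$freq_R2_m, row$freq_R2_f))
  } else {
    mean(c(row$freq_R1_m, row$freq_R1_f))
  }
  solo <- run_single(cal, insecticide = surviving,
                     start = init_from_allele_freqs(
                       if (surviving == 1L) qs else 0,
                       if (surviving == 2L) qs else 0
                     ))
  expect_identical(ad$t_both,
                   mx$t_first + solo$t_cross[[paste0("insecticide", surviving)]])

  # when both alleles cross simultaneously the adaptive time equals the
  # mixture time
  cal_sym <- curtis_idealised_calibration(0.01, 0.01)
  mx_sym <- run_mixture(cal_sym)
  ad_sym <- derive_adaptive(mx_sym, cal_sym)
  expect_identical(ad_sym$t_both, mx_sym$t_both)

  # run_adaptive is the composition of the two steps
  ad2 <- run_adaptive(cal)
  expect_identical(ad2$t_both, ad$t_both)
})

test_that("increasing exposure never slows resistance under the idealised calibration", {
  times <- sapply(c(0.3, 0.5, 0.7, 0.9), function(ex) {
    cal <- resistance_calibration(
      insecticide_params(1, 1, rr_restoration = 1),
      insecticide_params(1, 1, rr_restoration = 1),
      start_freq = c(0.01, 0.001), exposure = ex
    )
    run_mixture(cal)$t_both
  })
  expect_true(all(diff(times) <= 0))
})

test_that("scheduled interruptions freeze the trajectory when selection is relaxed and costs are zero", {
  cfg <- fixture_calibration("curtis_fig1_relaxed")
  out <- run_schedule(cfg$calibration, cfg$schedule)
  tr <- out$trajectory
  relaxed <- tr[tr$deployment == "none", ]
  expect_equal(length(unique(round(relaxed$freq_R1_f, 15))), 1L)
  # the interruption delays crossing by exactly its length: 4 + 9
  expect_identical(out$t_cross[["insecticide1"]], 13L)
  # an all-relaxed schedule leaves the trajectory flat
  flat <- run_schedule(
    cfg$calibration,
    deployment_schedule(list(from = 1, to = 10, spec = deployment_spec("none")))
  )
  expect_equal(unique(flat$trajectory$freq_R1_f), cfg$calibration$start_freq[1])
})
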