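#' Deployment specification
#'
#' Operational description of how insecticide is deployed in one phase:
#' which strategy, the proportion of females encountering insecticide, the
#' male exposure as a proportion of female exposure, and (for mixtures) the
#' proportion of the nominally treated population that actually receives
#' both insecticides rather than one of the singles.
#'
#' @param strategy One of `"mixture"`, `"single"` or `"none"`. (Sequential
#'   and adaptive deployments are built by [run_sequential()] and
#'   [run_adaptive()] from `single` and `mixture` phases.)
#' @param insecticide For `strategy = "single"`: which insecticide (1 or 2)
#'   is deployed.
#' @param exposure Proportion of females encountering insecticide, in
#'   `[0, 1]`.
#' @param male_exposure_prop Male exposure as a proportion of female
#'   exposure, in `[0, 1]`.
#' @param correct_mix_deploy Proportion of exposed mosquitoes that receive
#'   the full mixture rather than a single insecticide, in `[0.5, 1]`;
#'   applies only to mixture phases. The incorrectly treated remainder is
#'   split equally between the two single-insecticide niches.
#' @param concentration `"high"` (default) or `"low"`: which concentration
#'   niches receive the exposure.
#' @return An object of class `deployment_spec`.
#' @export
deployment_spec <- function(strategy = c("mixture", "single", "none"),
                            insecticide = 1L,
                            exposure = 0.9,
                            male_exposure_prop = 1,
                            correct_mix_deploy = 1,
                            concentration = c("high", "low")) {
  strategy <- match.arg(strategy)
  concentration <- match.arg(concentration)
  chk <- function(x, name, lo = 0, hi = 1) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
      stop(sprintf("%s must be a number in [%g, %g]", name, lo, hi))
    }
    x
  }
  chk(exposure, "exposure")
  chk(male_exposure_prop, "male_exposure_prop")
  if (strategy == "mixture") {
    chk(correct_mix_deploy, "correct_mix_deploy", 0.5, 1)
  }
  if (strategy == "single" && !insecticide %in% c(1L, 2L)) {
    stop("insecticide must be 1 or 2")
  }
  structure(
    list(
      strategy = strategy, insecticide = as.integer(insecticide),
      exposure = exposure, male_exposure_prop = male_exposure_prop,
      correct_mix_deploy = correct_mix_deploy, concentration = concentration
    ),
    class = "deployment_spec"
  )
}

#' Build an exposure profile from a deployment specification
#'
#' Translates operational parameters into per-sex niche exposures. For a
#' mixture with female exposure `e` and correct deployment `c`, females
#' encounter the dual niche with probability `e * c`, each single niche
#' with `e * (1 - c) / 2`, and stay unexposed with probability `1 - e`.
#' For a single insecticide the whole exposure goes to its own niche. Male
#' exposure to every exposed niche is the female value times
#' `male_exposure_prop`, the removed mass returning to the unexposed niche.
#'
#' @param spec A [deployment_spec].
#' @return An [exposure_profile].
#' @examples
#' spec <- deployment_spec("mixture", exposure = 0.8,
#'                         male_exposure_prop = 0.6,
#'                         correct_mix_deploy = 0.7)
#' build_exposure_profile(spec)
#' @export
build_exposure_profile <- function(spec) {
  stopifnot(inherits(spec, "deployment_spec"))
  e <- spec$exposure
  hi <- spec$concentration == "high"
  f <- stats::setNames(numeric(9L), NICHES)
  if (spec$strategy == "mixture") {
    c_ok <- spec$correct_mix_deploy
    f[if (hi) "AB" else "ab"] <- e * c_ok
    f[if (hi) "A0" else "a0"] <- e * (1 - c_ok) / 2
    f[if (hi) "0B" else "0b"] <- e * (1 - c_ok) / 2
  } else if (spec$strategy == "single") {
    niche <- if (spec$insecticide == 1L) {
      if (hi) "A0" else "a0"
    } else {
      if (hi) "0B" else "0b"
    }
    f[niche] <- e
  }
  f["00"] <- 1 - sum(f)
  m <- f * spec$male_exposure_prop
  m["00"] <- 0
  m["00"] <- 1 - sum(m)
  alpha <- rbind(m = m, f = f)
  if (any(abs(rowSums(alpha) - 1) > 1e-12)) {
    stop("internal error: exposure profile does not sum to 1")  # nocov
  }
  exposure_profile(alpha)
}

#' Model calibration
#'
#' Bundles everything needed to run the simulator: the two insecticides'
#' fitness parameters, interaction factors for dual-insecticide niches,
#' the recombination rate between the two resistance loci, starting
#' R-allele frequencies (or an explicit genotype table), the operational
#' exposure parameters, and the stopping rule (resistance threshold and
#' generation cap).
#'
#' @param insecticide1,insecticide2 [insecticide_params] objects.
#' @param interaction Named vector from [interaction_factors()].
#' @param recombination Recombination rate in `[0, 0.5]`; the default 0.5
#'   treats the two loci as unlinked (different chromosomes).
#' @param start_freq Length-2 vector of starting R-allele frequencies
#'   (Hardy-Weinberg and linkage equilibrium assumed), or `NULL` if
#'   `start_geno` is given.
#' @param start_geno Optional explicit starting [genotype_freq] state.
#' @param exposure,male_exposure_prop,correct_mix_deploy Default
#'   operational parameters for deployments built from this calibration
#'   (see [deployment_spec()]).
#' @param threshold Resistance-allele frequency above which an insecticide
#'   is considered failed (strict inequality). Default 0.5.
#' @param max_generations Generation cap; runs not reaching the threshold
#'   by then are censored. Default 500.
#' @return An object of class `resistance_calibration`.
#' @export
resistance_calibration <- function(insecticide1, insecticide2,
                                   interaction = interaction_factors(),
                                   recombination = 0.5,
                                   start_freq = c(0.01, 0.001),
                                   start_geno = NULL,
                                   exposure = 0.9,
                                   male_exposure_prop = 1,
                                   correct_mix_deploy = 1,
                                   threshold = 0.5,
                                   max_generations = 500L) {
  stopifnot(
    inherits(insecticide1, "insecticide_params"),
    inherits(insecticide2, "insecticide_params"),
    is.numeric(recombination), recombination >= 0, recombination <= 0.5,
    is.numeric(threshold), threshold > 0, threshold <= 1,
    max_generations >= 1
  )
  chk <- function(x, name, lo = 0, hi = 1) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
      stop(sprintf("%s must be a number in [%g, %g]", name, lo, hi))
    }
  }
  chk(exposure, "exposure")
  chk(male_exposure_prop, "male_exposure_prop")
  chk(correct_mix_deploy, "correct_mix_deploy", 0.5, 1)
  if (is.null(start_geno)) {
    stopifnot(length(start_freq) == 2L, all(start_freq >= 0), all(start_freq <= 1))
  } else {
    start_geno <- genotype_freq(unclass(start_geno))
  }
  structure(
    list(
      insecticide1 = insecticide1, insecticide2 = insecticide2,
      interaction = interaction_factors(
        ab = interaction[["ab"]], Ab = interaction[["Ab"]],
        aB = interaction[["aB"]], AB = interaction[["AB"]]
      ),
      recombination = recombination,
      start_freq = start_freq, start_geno = start_geno,
      exposure = exposure, male_exposure_prop = male_exposure_prop,
      correct_mix_deploy = correct_mix_deploy,
      threshold = threshold, max_generations = as.integer(max_generations)
    ),
    class = "resistance_calibration"
  )
}

# marginal fitness matrix for a calibration under a deployment spec
calibration_fitness <- function(calibration, spec) {
  w <- single_locus_fitness_table(calibration$insecticide1,
                                  calibration$insecticide2)
  Wn <- two_locus_fitness_tables(w, calibration$interaction)
  marginal_fitness(Wn, build_exposure_profile(spec))
}

# default deployment_spec of a given strategy from calibration defaults
calibration_spec <- function(calibration, strategy, insecticide = 1L) {
  deployment_spec(
    strategy = strategy, insecticide = insecticide,
    exposure = calibration$exposure,
    male_exposure_prop = calibration$male_exposure_prop,
    correct_mix_deploy = calibration$correct_mix_deploy
  )
}

calibration_start <- function(calibration) {
  if (!is.null(calibration$start_geno)) {
    calibration$start_geno
  } else {
    init_from_allele_freqs(calibration$start_freq[1], calibration$start_freq[2])
  }
}

# generation-0 trajectory row: allele freqs of the start state, LD of its
# neutral (unselected) gamete pool, and mean fitness under the first
# phase's marginal fitnesses
trajectory_row0 <- function(F, W, r, label) {
  af <- allele_frequencies(F)
  G0 <- gamete_frequencies(F, matrix(1, 2, 10, dimnames = list(SEXES, GENOTYPES)), r)
  data.frame(
    generation = 0L,
    freq_R1_m = af$m[["locus1"]], freq_R1_f = af$f[["locus1"]],
    freq_R2_m = af$m[["locus2"]], freq_R2_f = af$f[["locus2"]],
    LD = linkage_disequilibrium(G0),
    mean_fitness = mean_population_fitness(F, W),
    deployment = label,
    stringsAsFactors = FALSE
  )
}

phase_trajectory <- function(traj, gen0, label) {
  if (is.null(traj) || nrow(traj) == 0L) {
    return(NULL)
  }
  data.frame(
    generation = gen0 + seq_len(nrow(traj)),
    freq_R1_m = traj[, "freq_R1_m"], freq_R1_f = traj[, "freq_R1_f"],
    freq_R2_m = traj[, "freq_R2_m"], freq_R2_f = traj[, "freq_R2_f"],
    LD = traj[, "LD"], mean_fitness = traj[, "mean_fitness"],
    deployment = label,
    stringsAsFactors = FALSE
  )
}

# `watched` marks the loci whose crossing defines the outcome: both for
# two-insecticide strategies, only the deployed one for solo runs (the
# other locus's crossing is reported opportunistically but does not drive
# censoring).
new_strategy_outcome <- function(strategy, trajectory, t_cross, threshold,
                                 max_generations, watched = c(TRUE, TRUE)) {
  t_cross <- as.integer(t_cross)
  tw <- t_cross[watched]
  censored <- any(is.na(tw))
  structure(
    list(
      strategy = strategy,
      trajectory = trajectory,
      t_cross = stats::setNames(t_cross, c("insecticide1", "insecticide2")),
      t_first = if (all(is.na(tw))) NA_integer_ else min(tw, na.rm = TRUE),
      t_both = if (censored) NA_integer_ else max(tw),
      censored = censored,
      threshold = threshold,
      max_generations = max_generations
    ),
    class = "strategy_outcome"
  )
}

#' @export
print.strategy_outcome <- function(x, ...) {
  cat(sprintf("<strategy_outcome: %s>\n", x$strategy))
  cat(sprintf("  threshold %.2f, cap %d generations\n",
              x$threshold, x$max_generations))
  cat(sprintf("  crossing generations: insecticide 1 = %s, insecticide 2 = %s\n",
              format(x$t_cross[[1]]), format(x$t_cross[[2]])))
  cat(sprintf("  t_first = %s, t_both = %s, censored = %s\n",
              format(x$t_first), format(x$t_both), x$censored))
  invisible(x)
}

#' Deploy a single insecticide until resistance
#'
#' Runs the recursion with one insecticide deployed alone until the
#' sex-averaged frequency of the resistance allele at its locus strictly
#' exceeds the threshold, or the generation cap is reached (censoring).
#'
#' @param calibration A [resistance_calibration].
#' @param insecticide Which insecticide (1 or 2) to deploy.
#' @param start Optional starting [genotype_freq]; defaults to the
#'   calibration's start state.
#' @param max_generations Optional cap override.
#' @return A `strategy_outcome`; the undeployed insecticide's crossing time
#'   is reported only if its allele happens to cross too.
#' @export
run_single <- function(calibration, insecticide = 1L, start = NULL,
                       max_generations = NULL) {
  spec <- calibration_spec(calibration, "single", insecticide)
  W <- calibration_fitness(calibration, spec)
  F0 <- if (is.null(start)) calibration_start(calibration) else start
  cap <- if (is.null(max_generations)) calibration$max_generations else max_generations
  watch <- c(insecticide == 1L, insecticide == 2L)
  ph <- run_phase(F0, W, calibration$recombination, calibration$threshold,
                  cap, watch = watch, record = TRUE)
  label <- paste0("insecticide", insecticide)
  traj <- rbind(
    trajectory_row0(F0, W, calibration$recombination, label),
    phase_trajectory(ph$traj, 0L, label)
  )
  new_strategy_outcome("single", traj, ifelse(watch, ph$cross, NA_integer_),
                       calibration$threshold, cap, watched = watch)
}

#' Sequential deployment of two insecticides
#'
#' The first insecticide is deployed alone until the sex-averaged frequency
#' of its resistance allele strictly exceeds the threshold (at generation
#' `t1`). Because the policy works in one-generation timesteps, the switch
#' is only triggered the generation after the threshold is crossed: the
#' first insecticide remains deployed for one further generation, then the
#' second is deployed alone until its own allele crosses, `t2` selective
#' generations later. The total time to resistance is `t1 + 1 + t2`.
#' Genotype frequencies (including any departures from Hardy-Weinberg or
#' linkage equilibrium) carry over across the switch. Runs are censored at
#' the generation cap.
#'
#' @inheritParams run_single
#' @param first Which insecticide is deployed first (1 or 2).
#' @return A `strategy_outcome` with per-insecticide crossing generations.
#' @export
run_sequential <- function(calibration, first = 1L, start = NULL,
                           max_generations = NULL) {
  second <- if (first == 1L) 2L else 1L
  cap <- if (is.null(max_generations)) calibration$max_generations else max_generations
  r <- calibration$recombination
  thr <- calibration$threshold
  F0 <- if (is.null(start)) calibration_start(calibration) else start

  W1 <- calibration_fitness(calibration, calibration_spec(calibration, "single", first))
  watch1 <- c(first == 1L, first == 2L)
  lab1 <- paste0("insecticide", first)
  ph1 <- run_phase(F0, W1, r, thr, cap, watch = watch1, record = TRUE)
  traj <- rbind(trajectory_row0(F0, W1, r, lab1),
                phase_trajectory(ph1$traj, 0L, lab1))
  t1 <- ph1$cross[first]
  cross <- c(NA_integer_, NA_integer_)
  cross[first] <- t1
  if (is.na(t1) || t1 + 1L >= cap) {
    # first insecticide never failed (or no room to switch): censored
    return(new_strategy_outcome("sequential", traj, cross, thr, cap))
  }
  # switch lag: one further generation of the exhausted insecticide
  lag <- run_phase(ph1$F, W1, r, thr, 1L, watch = c(FALSE, FALSE), record = TRUE)
  traj <- rbind(traj, phase_trajectory(lag$traj, t1, lab1))

  W2 <- calibration_fitness(calibration, calibration_spec(calibration, "single", second))
  watch2 <- c(second == 1L, second == 2L)
  lab2 <- paste0("insecticide", second)
  ph2 <- run_phase(lag$F, W2, r, thr, cap - t1 - 1L, watch = watch2,
                   gen0 = t1 + 1L, record = TRUE)
  traj <- rbind(traj, phase_trajectory(ph2$traj, t1 + 1L, lab2))
  cross[second] <- ph2$cross[second]
  new_strategy_outcome("sequential", traj, cross, thr, cap)
}

#' Mixture deployment of two insecticides
#'
#' Both insecticides are deployed together as a mixture for the whole run.
#' The time to resistance is the number of generations until both
#' resistance-allele frequencies strictly exceed the threshold (`t_both`);
#' the generation at which the first allele crosses is recorded as
#' `t_first`.
#'
#' @inheritParams run_single
#' @return A `strategy_outcome`.
#' @export
run_mixture <- function(calibration, start = NULL, max_generations = NULL) {
  spec <- calibration_spec(calibration, "mixture")
  W <- calibration_fitness(calibration, spec)
  F0 <- if (is.null(start)) calibration_start(calibration) else start
  cap <- if (is.null(max_generations)) calibration$max_generations else max_generations
  ph <- run_phase(F0, W, calibration$recombination, calibration$threshold,
                  cap, watch = c(TRUE, TRUE), record = TRUE)
  traj <- rbind(trajectory_row0(F0, W, calibration$recombination, "mixture"),
                phase_trajectory(ph$traj, 0L, "mixture"))
  new_strategy_outcome("mixture", traj, ph$cross, calibration$threshold, cap)
}

#' Adaptive-mixture time to resistance derived from a mixture run
#'
#' Under adaptive mixture deployment the mixture is used until one
#' resistance allele exceeds the threshold; the still-effective insecticide
#' is then deployed alone. The time to resistance is estimated from the
#' mixture run plus a solo run: the first crossing time is read from the
#' mixture outcome, and the remaining time is the solo time-to-threshold of
#' the surviving insecticide started from a fresh Hardy-Weinberg /
#' linkage-equilibrium population at the allele frequencies observed when
#' the first allele crossed. (Deviations from Hardy-Weinberg and linkage
#' equilibrium accrued during the mixture phase are deliberately ignored;
#' they decay within a few generations once the mixture is withdrawn.)
#'
#' @param mixture_out A `strategy_outcome` from [run_mixture()].
#' @inheritParams run_single
#' @return A `strategy_outcome` (with the mixture-phase trajectory up to
#'   the switch followed by the solo-phase trajectory).
#' @export
derive_adaptive <- function(mixture_out, calibration) {
  stopifnot(inherits(mixture_out, "strategy_outcome"))
  thr <- mixture_out$threshold
  cap <- mixture_out$max_generations
  t_first <- mixture_out$t_first
  if (is.na(t_first)) {
    out <- new_strategy_outcome("adaptive_mixture", mixture_out$trajectory,
                                c(NA_integer_, NA_integer_), thr, cap)
    return(out)
  }
  cross <- mixture_out$t_cross
  if (!any(is.na(cross)) && cross[1] == cross[2]) {
    # both alleles crossed in the same generation: nothing to withdraw
    return(new_strategy_outcome("adaptive_mixture", mixture_out$trajectory,
                                cross, thr, cap))
  }
  first_locus <- which.min(ifelse(is.na(cross), Inf, cross))
  surviving <- if (first_locus == 1L) 2L else 1L
  traj_mix <- mixture_out$trajectory
  row <- traj_mix[traj_mix$generation == t_first, , drop = FALSE]
  q1 <- mean(c(row$freq_R1_m, row$freq_R1_f))
  q2 <- mean(c(row$freq_R2_m, row$freq_R2_f))
  F_switch <- init_from_allele_freqs(q1, q2)
  solo <- run_single(calibration, insecticide = surviving, start = F_switch,
                     max_generations = cap - t_first)
  out_cross <- cross
  t_solo <- solo$t_cross[[surviving]]
  out_cross[surviving] <- if (is.na(t_solo)) NA_integer_ else t_first + t_solo
  solo_traj <- solo$trajectory
  solo_traj <- solo_traj[solo_traj$generation > 0L, , drop = FALSE]
  if (nrow(solo_traj)) solo_traj$generation <- solo_traj$generation + t_first
  traj <- rbind(traj_mix[traj_mix$generation <= t_first, , drop = FALSE],
                solo_traj)
  new_strategy_outcome("adaptive_mixture", traj, out_cross, thr, cap)
}

#' Run the adaptive-mixture strategy
#'
#' Convenience wrapper: runs the mixture ([run_mixture()]) and derives the
#' adaptive-mixture outcome from it ([derive_adaptive()]).
#'
#' @inheritParams run_single
#' @return A `strategy_outcome`.
#' @export
run_adaptive <- function(calibration, start = NULL, max_generations = NULL) {
  mix <- run_mixture(calibration, start = start, max_generations = max_generations)
  derive_adaptive(mix, calibration)
}

#' Deployment schedule
#'
#' An ordered list of generation spans, each with its own deployment
#' specification; spans must be contiguous, non-overlapping and start at
#' generation 1. Used to model scheduled interruptions such as relaxed
#' selection (a `"none"` span) between periods of deployment.
#'
#' @param ... Lists with elements `from`, `to` (generation span, inclusive)
#'   and `spec` (a [deployment_spec]).
#' @return An object of class `deployment_schedule`.
#' @examples
#' deployment_schedule(
#'   list(from = 1, to = 3, spec = deployment_spec("single", insecticide = 2)),
#'   list(from = 4, to = 12, spec = deployment_spec("none"))
#' )
#' @export
deployment_schedule <- function(...) {
  spans <- list(...)
  if (length(spans) == 1L && is.null(spans[[1]]$spec) && is.list(spans[[1]][[1]])) {
    spans <- spans[[1]]
  }
  stopifnot(length(spans) >= 1L)
  expected_from <- 1L
  for (sp in spans) {
    if (!all(c("from", "to", "spec") %in% names(sp))) {
      stop("each span needs 'from', 'to' and 'spec'")
    }
    if (sp$from != expected_from) {
      stop(sprintf("spans must be contiguous from generation 1; expected from = %d, got %d",
                   expected_from, sp$from))
    }
    if (sp$to < sp$from) stop("span 'to' must be >= 'from'")
    if (!inherits(sp$spec, "deployment_spec")) stop("span 'spec' must be a deployment_spec")
    expected_from <- sp$to + 1L
  }
  structure(spans, class = "deployment_schedule")
}

#' Run a deployment schedule
#'
#' Iterates the recursion through the schedule's spans, recomputing the
#' marginal fitnesses at each span boundary and carrying the full genotype
#' state (including any Hardy-Weinberg or linkage-equilibrium deviations)
#' across boundaries. Crossing times against the calibration's threshold
#' are recorded but do not stop the run.
#'
#' @param calibration A [resistance_calibration].
#' @param schedule A [deployment_schedule].
#' @return A `strategy_outcome` labelled `"schedule"` whose trajectory
#'   covers every scheduled generation.
#' @export
run_schedule <- function(calibration, schedule) {
  stopifnot(inherits(schedule, "deployment_schedule"))
  r <- calibration$recombination
  thr <- calibration$threshold
  F <- calibration_start(calibration)
  span_label <- function(spec) {
    switch(spec$strategy,
      none = "none",
      mixture = "mixture",
      single = paste0("insecticide", spec$insecticide)
    )
  }
  W1 <- calibration_fitness(calibration, schedule[[1]]$spec)
  traj <- trajectory_row0(F, W1, r, span_label(schedule[[1]]$spec))
  cross <- c(NA_integer_, NA_integer_)
  af0 <- allele_frequencies(F)$avg
  cross[af0 > thr] <- 0L
  for (sp in schedule) {
    W <- calibration_fitness(calibration, sp$spec)
    n <- sp$to - sp$from + 1L
    ph <- run_phase(F, W, r, thr, n, watch = c(FALSE, FALSE), record = TRUE)
    tr <- phase_trajectory(ph$traj, sp$from - 1L, span_label(sp$spec))
    traj <- rbind(traj, tr)
    for (l in 1:2) {
      col <- if (l == 1L) "freq_R1_m" else "freq_R2_m"
      colf <- if (l == 1L) "freq_R1_f" else "freq_R2_f"
      avg <- (tr[[col]] + tr[[colf]]) / 2
      if (is.na(cross[l]) && any(avg > thr)) {
        cross[l] <- tr$generation[which(avg > thr)[1]]
      }
    }
    F <- ph$F
  }
  out <- new_strategy_outcome("schedule", traj, cross, thr,
                              schedule[[length(schedule)]]$to)
  out$final_state <- F
  out
}
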