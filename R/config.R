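#' Load a calibration from a configuration file
#'
#' Calibrations are stored as plain-text YAML with five sections:
#' `locus1` and `locus2` (per-insecticide `effectiveness`, `dominance`,
#' `rr_restoration` or explicit `selection`, `cost`, `cost_dominance`, and
#' an optional `low` sub-section for low-concentration parameters),
#' `exposure` (`exposure`, `male_exposure_prop`, `correct_mix_deploy`),
#' `interaction` (`ab`, `Ab`, `aB`, `AB`), and `simulation`
#' (`start_freq_1`, `start_freq_2`, `recombination`, `threshold`,
#' `max_generations`). An optional `schedule` section holds a list of
#' spans, each with `from`, `to`, `strategy` and (for singles)
#' `insecticide`. Unknown sections or keys are rejected, and every type
#' invariant is checked on load with an error naming the offending
#' section/key.
#'
#' @param path Path to a YAML calibration file.
#' @return A list with elements `calibration` (a
#'   [resistance_calibration]) and `schedule` (a [deployment_schedule] or
#'   `NULL`).
#' @seealso [write_config()], [fixture_calibration()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  known_sections <- c("locus1", "locus2", "exposure", "interaction",
                      "simulation", "schedule", "description")
  extra <- setdiff(names(raw), known_sections)
  if (length(extra)) stop("unknown config section(s): ", paste(extra, collapse = ", "))
  for (sec in c("locus1", "locus2", "simulation")) {
    if (is.null(raw[[sec]])) stop("missing config section: ", sec)
  }

  parse_locus <- function(sec) {
    x <- raw[[sec]]
    keys <- c("effectiveness", "dominance", "rr_restoration", "selection",
              "cost", "cost_dominance", "low")
    extra <- setdiff(names(x), keys)
    if (length(extra)) {
      stop(sprintf("unknown key(s) in [%s]: %s", sec, paste(extra, collapse = ", ")))
    }
    tryCatch(
      insecticide_params(
        effectiveness = x$effectiveness,
        dominance = x$dominance,
        rr_restoration = x$rr_restoration,
        selection = x$selection,
        cost = if (is.null(x$cost)) 0 else x$cost,
        cost_dominance = if (is.null(x$cost_dominance)) 0 else x$cost_dominance,
        low = x$low
      ),
      error = function(e) stop(sprintf("[%s]: %s", sec, conditionMessage(e)),
                               call. = FALSE)
    )
  }
  ins1 <- parse_locus("locus1")
  ins2 <- parse_locus("locus2")

  ex <- raw$exposure
  if (!is.null(ex)) {
    extra <- setdiff(names(ex), c("exposure", "male_exposure_prop", "correct_mix_deploy"))
    if (length(extra)) {
      stop("unknown key(s) in [exposure]: ", paste(extra, collapse = ", "))
    }
  }
  getd <- function(lst, key, default) if (is.null(lst[[key]])) default else lst[[key]]

  lam <- raw$interaction
  if (!is.null(lam)) {
    extra <- setdiff(names(lam), c("ab", "Ab", "aB", "AB"))
    if (length(extra)) {
      stop("unknown key(s) in [interaction]: ", paste(extra, collapse = ", "))
    }
  }

  sim <- raw$simulation
  extra <- setdiff(names(sim), c("start_freq_1", "start_freq_2", "recombination",
                                 "threshold", "max_generations"))
  if (length(extra)) {
    stop("unknown key(s) in [simulation]: ", paste(extra, collapse = ", "))
  }

  calibration <- tryCatch(
    resistance_calibration(
      ins1, ins2,
      interaction = interaction_factors(
        ab = getd(lam, "ab", 1), Ab = getd(lam, "Ab", 1),
        aB = getd(lam, "aB", 1), AB = getd(lam, "AB", 1)
      ),
      recombination = getd(sim, "recombination", 0.5),
      start_freq = c(getd(sim, "start_freq_1", 0.01),
                     getd(sim, "start_freq_2", 0.001)),
      exposure = getd(ex, "exposure", 0.9),
      male_exposure_prop = getd(ex, "male_exposure_prop", 1),
      correct_mix_deploy = getd(ex, "correct_mix_deploy", 1),
      threshold = getd(sim, "threshold", 0.5),
      max_generations = getd(sim, "max_generations", 500L)
    ),
    error = function(e) stop("invalid calibration: ", conditionMessage(e),
                             call. = FALSE)
  )

  schedule <- NULL
  if (!is.null(raw$schedule)) {
    spans <- lapply(raw$schedule, function(sp) {
      extra <- setdiff(names(sp), c("from", "to", "strategy", "insecticide"))
      if (length(extra)) {
        stop("unknown key(s) in [schedule] span: ", paste(extra, collapse = ", "))
      }
      list(
        from = as.integer(sp$from), to = as.integer(sp$to),
        spec = deployment_spec(
          strategy = sp$strategy,
          insecticide = getd(sp, "insecticide", 1L),
          exposure = calibration$exposure,
          male_exposure_prop = calibration$male_exposure_prop,
          correct_mix_deploy = calibration$correct_mix_deploy
        )
      )
    })
    schedule <- deployment_schedule(spans)
  }
  list(calibration = calibration, schedule = schedule)
}

#' Write a calibration to a configuration file
#'
#' Inverse of [load_config()]: writes the calibration (and optional
#' schedule) in the YAML section layout that [load_config()] reads, so
#' `write_config(load_config(x)) `round-trips.
#'
#' @param config A list with `calibration` and optional `schedule`, as
#'   returned by [load_config()], or a bare [resistance_calibration].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  if (inherits(config, "resistance_calibration")) {
    config <- list(calibration = config, schedule = NULL)
  }
  cal <- config$calibration
  locus_block <- function(p) {
    blk <- list(
      effectiveness = p$high$phi,
      dominance = p$high$h,
      selection = p$high$s,
      cost = p$cost,
      cost_dominance = p$cost_dominance
    )
    if (!identical(p$low, p$high)) {
      blk$low <- list(effectiveness = p$low$phi, dominance = p$low$h,
                      selection = p$low$s)
    }
    blk
  }
  out <- list(
    locus1 = locus_block(cal$insecticide1),
    locus2 = locus_block(cal$insecticide2),
    exposure = list(
      exposure = cal$exposure,
      male_exposure_prop = cal$male_exposure_prop,
      correct_mix_deploy = cal$correct_mix_deploy
    ),
    interaction = as.list(cal$interaction),
    simulation = list(
      start_freq_1 = cal$start_freq[1],
      start_freq_2 = cal$start_freq[2],
      recombination = cal$recombination,
      threshold = cal$threshold,
      max_generations = cal$max_generations
    )
  )
  if (!is.null(config$schedule)) {
    out$schedule <- lapply(unclass(config$schedule), function(sp) {
      blk <- list(from = sp$from, to = sp$to, strategy = sp$spec$strategy)
      if (sp$spec$strategy == "single") blk$insecticide <- sp$spec$insecticide
      blk
    })
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Built-in calibration fixtures
#'
#' Named, ready-to-run scenarios shipped with the package:
#'
#' * `"curtis_idealised"`: the idealised two-insecticide scenario —
#'   effectiveness 1, dominance 1, full restoration, no fitness costs,
#'   equal exposure of the sexes at 0.9, unlinked loci, starts
#'   (0.01, 0.001). The exposure of 0.9 (escape 0.1) is the value that
#'   reproduces the classical one-generation updates (0.1% to 0.98% solo;
#'   rarer mixture allele 0.1% to 0.118%) and solo crossing times 3/4/5
#'   from starts 1e-2/1e-3/1e-4.
#' * `"curtis_fig1_relaxed"`: the idealised single-insecticide scenario
#'   with selection relaxed (no insecticide) between generations 4 and 12,
#'   then resumed to generation 20.
#' * `"hch_ddt_synthetic"`: a deliberately incomplete, partly synthetic
#'   sketch of the historical HCH/DDT field calibration: the DDT locus uses
#'   the published fitnesses of sensitive and resistant homozygotes
#'   surviving DDT exposure (0.27 and 0.50, i.e. effectiveness 0.73 and
#'   restoration 0.23/0.73); all other values are placeholders chosen for
#'   illustration only and are not field estimates.
#'
#' @param name Fixture name.
#' @return A list with `calibration` and `schedule` (possibly `NULL`), as
#'   from [load_config()].
#' @export
fixture_calibration <- function(name = c("curtis_idealised",
                                         "curtis_fig1_relaxed",
                                         "hch_ddt_synthetic")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".yaml"), package = "resistmix")
  if (!nzchar(path)) {
    # fall back for developer loads without installation
    path <- file.path("inst", "extdata", paste0(name, ".yaml"))
  }
  load_config(path)
}

#' Starting-frequency grid of the idealised two-insecticide comparison
#'
#' The grid of starting R-allele frequencies used to compare sequential
#' and mixture deployment under the idealised calibration: the first
#' (higher-resistance, "old") insecticide starts at 0.01, 0.1 or 0.3 and
#' the second ("new") at 1e-2, 1e-3 or 1e-4.
#'
#' @return A data frame with columns `start_freq_1` and `start_freq_2`
#'   (nine rows).
#' @export
curtis_table3_grid <- function() {
  g <- expand.grid(start_freq_1 = c(0.01, 0.1, 0.3),
                   start_freq_2 = c(1e-2, 1e-3, 1e-4))
  g[order(g$start_freq_2, decreasing = TRUE), , drop = FALSE][, 1:2]
}

#' Generations-to-years labelling helper
#'
#' Converts mosquito generations to approximate calendar years for axis
#' labels and reports, assuming 12 generations per year. Purely a
#' presentation aid: no model computation uses calendar time.
#'
#' @param generations Numeric vector of generation counts.
#' @param per_year Generations per year (default 12).
#' @return Years (numeric).
#' @export
generations_to_years <- function(generations, per_year = 12) {
  generations / per_year
}
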