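#' Parameter ranges for the global sensitivity analysis
#'
#' The default ranges span the operationally plausible parameter space:
#' log-uniform starting frequencies (so rare resistance alleles are well
#' represented), uniform exposure of females between 10% and 90%, male
#' exposure anywhere from none to equal to females, insecticide
#' effectiveness from 0.3 to 1, free dominance, restoration between 0.2
#' and 1, and mixture deployment at least half correct. Fitness costs are
#' fixed at zero throughout the sensitivity analysis.
#'
#' @param ... Named overrides, each a list with elements `dist`
#'   (`"uniform"` or `"log_uniform"`), `lo` and `hi`.
#' @return A named list of range definitions, class `parameter_ranges`.
#' @export
parameter_ranges <- function(...) {
  ranges <- list(
    start_freq_allele1 = list(dist = "log_uniform", lo = 0.0001, hi = 0.1),
    start_freq_allele2 = list(dist = "log_uniform", lo = 0.0001, hi = 0.1),
    exposure           = list(dist = "uniform", lo = 0.1, hi = 0.9),
    male_exposure_prop = list(dist = "uniform", lo = 0, hi = 1),
    effectiveness_ins1 = list(dist = "uniform", lo = 0.3, hi = 1),
    effectiveness_ins2 = list(dist = "uniform", lo = 0.3, hi = 1),
    dominance_allele1  = list(dist = "uniform", lo = 0, hi = 1),
    dominance_allele2  = list(dist = "uniform", lo = 0, hi = 1),
    rr_restoration_ins1 = list(dist = "uniform", lo = 0.2, hi = 1),
    rr_restoration_ins2 = list(dist = "uniform", lo = 0.2, hi = 1),
    correct_mix_deploy = list(dist = "uniform", lo = 0.5, hi = 1)
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (!nm %in% names(ranges)) stop("unknown sensitivity variable: ", nm)
    ov <- overrides[[nm]]
    stopifnot(all(c("dist", "lo", "hi") %in% names(ov)))
    ranges[[nm]] <- ov
  }
  for (nm in names(ranges)) {
    rg <- ranges[[nm]]
    if (!rg$dist %in% c("uniform", "log_uniform")) {
      stop("distribution of ", nm, " must be uniform or log_uniform")
    }
    if (!is.finite(rg$lo) || !is.finite(rg$hi) || rg$lo > rg$hi) {
      stop("invalid bounds for ", nm)
    }
    if (rg$dist == "log_uniform" && rg$lo <= 0) {
      stop("log-uniform bounds for ", nm, " must be positive")
    }
  }
  structure(ranges, class = "parameter_ranges")
}

#' Sample parameter sets for the sensitivity analysis
#'
#' Each variable is drawn independently from its range: uniform variables
#' directly, log-uniform variables as `10^U` with `U` uniform between the
#' log10 bounds. Sampling is deterministic given the seed.
#'
#' @param n Number of parameter sets.
#' @param seed Integer random seed.
#' @param ranges A [parameter_ranges()] object.
#' @return A data frame with `n` rows and one column per variable.
#' @export
sample_parameter_sets <- function(n, seed, ranges = parameter_ranges()) {
  stopifnot(n >= 1, inherits(ranges, "parameter_ranges"))
  set.seed(as.integer(seed))
  cols <- lapply(ranges, function(rg) {
    if (rg$dist == "log_uniform") {
      10^stats::runif(n, log10(rg$lo), log10(rg$hi))
    } else {
      stats::runif(n, rg$lo, rg$hi)
    }
  })
  as.data.frame(cols)
}

# build a calibration from one sampled parameter row (fitness costs zero)
calibration_from_params <- function(p, threshold = 0.5, max_generations = 500L) {
  resistance_calibration(
    insecticide_params(p$effectiveness_ins1, p$dominance_allele1,
                       rr_restoration = p$rr_restoration_ins1),
    insecticide_params(p$effectiveness_ins2, p$dominance_allele2,
                       rr_restoration = p$rr_restoration_ins2),
    start_freq = c(p$start_freq_allele1, p$start_freq_allele2),
    exposure = p$exposure,
    male_exposure_prop = p$male_exposure_prop,
    correct_mix_deploy = p$correct_mix_deploy,
    threshold = threshold,
    max_generations = max_generations
  )
}

#' Run the sensitivity batch
#'
#' For every sampled parameter set, runs the sequential strategy
#' (insecticide 1 first), the mixture strategy, and derives the adaptive
#' mixture; starts are in Hardy-Weinberg and linkage equilibrium, only the
#' deployed niches are present, and fitness costs are zero. Each strategy
#' is censored at `max_generations`. Per-insecticide solo times are also
#' recorded: the first sequential phase is exactly a solo deployment of
#' insecticide 1, and with zero fitness costs the second phase is exactly a
#' solo deployment of insecticide 2 from its starting frequency, so
#' `t_solo2 = t_seq - t_solo1 - 1` whenever the sequence completes.
#'
#' @param sets Data frame from [sample_parameter_sets()].
#' @param threshold Resistance threshold (default 0.5).
#' @param max_generations Generation cap (default 500).
#' @param progress_every Print a progress line every this many runs
#'   (0 = silent).
#' @return A data frame, one row per parameter set, with the sampled
#'   parameters, the derived starting-frequency ratios
#'   (`resist_start_1_div_2`, `resist_start_hi_div_lo`), strategy times
#'   (`t_seq`, `t_mix_first`, `t_mix_both`, `t_adapt_both`, `t_solo1`,
#'   `t_solo2`; `NA` when censored) and censoring flags.
#' @export
run_sensitivity <- function(sets, threshold = 0.5, max_generations = 500L,
                            progress_every = 0L) {
  n <- nrow(sets)
  out <- data.frame(
    t_seq = rep(NA_integer_, n), t_solo1 = NA_integer_, t_solo2 = NA_integer_,
    t_mix_first = NA_integer_, t_mix_both = NA_integer_,
    t_adapt_both = NA_integer_,
    seq_censored = NA, mix_censored = NA, adapt_censored = NA,
    error = NA_character_
  )
  for (i in seq_len(n)) {
    p <- sets[i, , drop = FALSE]
    res <- tryCatch({
      cal <- calibration_from_params(p, threshold, max_generations)
      sq <- run_sequential(cal, first = 1L)
      mx <- run_mixture(cal)
      ad <- derive_adaptive(mx, cal)
      t_solo1 <- sq$t_cross[[1]]
      t_solo2 <- if (!sq$censored) sq$t_both - t_solo1 - 1L else NA_integer_
      list(
        t_seq = sq$t_both, t_solo1 = t_solo1, t_solo2 = t_solo2,
        t_mix_first = mx$t_first, t_mix_both = mx$t_both,
        t_adapt_both = ad$t_both,
        seq_censored = sq$censored, mix_censored = mx$censored,
        adapt_censored = ad$censored, error = NA_character_
      )
    }, error = function(e) {
      list(
        t_seq = NA_integer_, t_solo1 = NA_integer_, t_solo2 = NA_integer_,
        t_mix_first = NA_integer_, t_mix_both = NA_integer_,
        t_adapt_both = NA_integer_,
        seq_censored = NA, mix_censored = NA, adapt_censored = NA,
        error = conditionMessage(e)
      )
    })
    out[i, names(res)] <- res
    if (progress_every > 0L && i %% progress_every == 0L) {
      message(sprintf("sensitivity run %d / %d", i, n))
    }
  }
  records <- cbind(sets, out)
  records$resist_start_1_div_2 <-
    records$start_freq_allele1 / records$start_freq_allele2
  records$resist_start_hi_div_lo <-
    pmax(records$start_freq_allele1, records$start_freq_allele2) /
    pmin(records$start_freq_allele1, records$start_freq_allele2)
  records$effectiveness_sum <-
    records$effectiveness_ins1 + records$effectiveness_ins2
  records
}

#' Label runs by the better strategy
#'
#' A run favours the mixture when its mixture time to resistance is more
#' than `(1 + margin)` times the sequential time (strict inequality, so
#' exact ties favour sequential use); a run where the mixture is censored
#' but the sequence completes favours the mixture, and vice versa. Runs
#' censored under both strategies are dropped: on that timescale the
#' strategies are operationally equivalent.
#'
#' @param records Data frame from [run_sensitivity()].
#' @param margin Required relative advantage of the mixture (0 or 0.2).
#' @param mixture_time Which mixture-type time to compare against the
#'   sequence: `"adaptive"` (default; the operational policy of withdrawing
#'   a failed insecticide from the mixture, the comparison used for the
#'   headline shares and the decision plane) or `"mixture"`.
#' @return `records` restricted to comparable runs, with added columns
#'   `label` (factor, `"mixture"`/`"sequential"`) and `time_diff`
#'   (mixture-type time minus sequential time; `NA` when either side is
#'   censored).
#' @export
compare_strategies <- function(records, margin = 0,
                               mixture_time = c("adaptive", "mixture")) {
  mixture_time <- match.arg(mixture_time)
  tcol <- if (mixture_time == "mixture") "t_mix_both" else "t_adapt_both"
  ccol <- if (mixture_time == "mixture") "mix_censored" else "adapt_censored"
  ok <- !is.na(records$seq_censored) & !is.na(records[[ccol]]) &
    !(records$seq_censored & records[[ccol]])
  rec <- records[ok, , drop = FALSE]
  t_mix <- ifelse(rec[[ccol]], Inf, rec[[tcol]])
  t_seq <- ifelse(rec$seq_censored, Inf, rec$t_seq)
  rec$label <- factor(
    ifelse(t_mix > (1 + margin) * t_seq, "mixture", "sequential"),
    levels = c("sequential", "mixture")
  )
  rec$time_diff <- ifelse(is.finite(t_mix) & is.finite(t_seq),
                          t_mix - t_seq, NA_real_)
  rec
}

#' Decision line in the effectiveness-exposure plane
#'
#' The two inputs that dominate strategy choice are the summed
#' effectiveness of the insecticides and the exposure. A linear decision
#' boundary is estimated by selecting the boundary runs — those where the
#' two strategies reach resistance at the same time (margin 0, exact
#' integer equality of generation counts) or where the mixture lasts 19-21%
#' longer (margin 0.2) — and regressing summed effectiveness on exposure by
#' ordinary least squares over them. The fitted rule predicts the mixture
#' to be superior when summed effectiveness exceeds
#' `intercept + slope * exposure`.
#'
#' @inheritParams compare_strategies
#' @param band For `margin > 0`: half-width of the relative-difference band
#'   around the margin that defines boundary runs (default 0.01, i.e.
#'   19-21% for margin 0.2).
#' @return A list of class `decision_line` with `intercept`, `slope`,
#'   `margin`, `n_boundary` and the fitted `lm` object.
#' @export
fit_decision_line <- function(records, margin = 0, band = 0.01,
                              mixture_time = c("adaptive", "mixture")) {
  mixture_time <- match.arg(mixture_time)
  tcol <- if (mixture_time == "mixture") "t_mix_both" else "t_adapt_both"
  ccol <- if (mixture_time == "mixture") "mix_censored" else "adapt_censored"
  ok <- !is.na(records$seq_censored) & !is.na(records[[ccol]]) &
    !records$seq_censored & !records[[ccol]]
  rec <- records[ok, , drop = FALSE]
  reldiff <- (rec[[tcol]] - rec$t_seq) / rec$t_seq
  boundary <- if (margin == 0) {
    rec[[tcol]] == rec$t_seq
  } else {
    reldiff >= margin - band & reldiff <= margin + band
  }
  bd <- rec[boundary, , drop = FALSE]
  if (nrow(bd) < 2L) stop("fewer than 2 boundary runs; cannot fit a decision line")
  fit <- stats::lm(effectiveness_sum ~ exposure, data = bd)
  structure(
    list(
      intercept = unname(stats::coef(fit)[1]),
      slope = unname(stats::coef(fit)[2]),
      margin = margin, mixture_time = mixture_time,
      n_boundary = nrow(bd), fit = fit
    ),
    class = "decision_line"
  )
}

#' @export
print.decision_line <- function(x, ...) {
  cat(sprintf(
    "<decision_line> effectiveness_sum = %.3f + %.3f * exposure (margin %.2g, %d boundary runs)\n",
    x$intercept, x$slope, x$margin, x$n_boundary
  ))
  invisible(x)
}

#' Classification performance of a decision line
#'
#' Applies the line's rule (predict mixture-superior when summed
#' effectiveness exceeds `intercept + slope * exposure`) to labelled runs
#' and reports the true positive rate (proportion of mixture-superior runs
#' predicted mixture) and true negative rate (proportion of
#' sequential-superior runs predicted sequential).
#'
#' @param labelled Data frame from [compare_strategies()] (must have
#'   `label`, `effectiveness_sum`, `exposure`).
#' @param line A `decision_line`.
#' @return Named vector with `tpr`, `tnr`, and the counts used.
#' @export
classification_rates <- function(labelled, line) {
  stopifnot(inherits(line, "decision_line"), "label" %in% names(labelled))
  pred_mix <- labelled$effectiveness_sum >
    line$intercept + line$slope * labelled$exposure
  pos <- labelled$label == "mixture"
  c(
    tpr = mean(pred_mix[pos]),
    tnr = mean(!pred_mix[!pos]),
    n_pos = sum(pos),
    n_neg = sum(!pos)
  )
}

#' Classification tree for strategy choice
#'
#' Grows a binary classification tree (recursive partitioning on Gini
#' impurity, via \pkg{rpart}) predicting the favoured strategy from the
#' sampled variables plus the two starting-frequency ratios. To avoid
#' overfitting the tree is pruned to the smallest size at which the
#' resubstitution error plus its cross-validation standard error falls
#' below the cross-validation error; the unpruned tree is returned as well
#' for inspection, since aggressive pruning tends to collapse the tree to
#' effectiveness-only splits.
#'
#' @param labelled Data frame from [compare_strategies()].
#' @param minbucket Minimum leaf size passed to \pkg{rpart}.
#' @param cp Complexity parameter for the initial (unpruned) fit.
#' @param seed Seed for the cross-validation folds.
#' @return A list of class `strategy_tree` with elements `pruned`,
#'   `unpruned` (rpart objects; `pruned` may equal `unpruned` when no
#'   candidate size satisfies the rule; single-class input yields a
#'   single-leaf summary instead) and `cptable`.
#' @export
build_classification_tree <- function(labelled, minbucket = 20, cp = 0.001,
                                      seed = 1L) {
  vars <- c(
    "start_freq_allele1", "start_freq_allele2", "exposure",
    "male_exposure_prop", "effectiveness_ins1", "effectiveness_ins2",
    "dominance_allele1", "dominance_allele2",
    "rr_restoration_ins1", "rr_restoration_ins2", "correct_mix_deploy",
    "resist_start_1_div_2", "resist_start_hi_div_lo"
  )
  vars <- intersect(vars, names(labelled))
  dat <- labelled[, c(vars, "label")]
  if (nlevels(droplevels(dat$label)) < 2L) {
    # degenerate single-class input: a single-leaf summary, no splitting
    cls <- as.character(unique(dat$label))
    leaf <- list(
      frame = data.frame(var = "<leaf>", n = nrow(dat), yval = cls,
                         stringsAsFactors = FALSE),
      single_class = cls
    )
    return(structure(list(pruned = leaf, unpruned = leaf, cptable = NULL),
                     class = "strategy_tree"))
  }
  set.seed(seed)
  fit <- rpart::rpart(label ~ ., data = dat, method = "class",
                      control = rpart::rpart.control(cp = cp, minbucket = minbucket,
                                                     xval = 10))
  cpt <- fit$cptable
  ok <- cpt[, "rel error"] + cpt[, "xstd"] < cpt[, "xerror"]
  pruned <- if (any(ok)) {
    rpart::prune(fit, cp = cpt[which(ok)[1], "CP"])
  } else {
    fit
  }
  structure(list(pruned = pruned, unpruned = fit, cptable = cpt),
            class = "strategy_tree")
}

#' @export
print.strategy_tree <- function(x, ...) {
  cat("<strategy_tree> pruned tree:\n")
  print(x$pruned)
  invisible(x)
}

#' PRCC of sensitivity inputs against an outcome
#'
#' Convenience wrapper computing [prcc()] of the sampled variables (plus
#' starting-frequency ratios) against a chosen outcome column of the
#' sensitivity records, using complete (uncensored for that outcome)
#' records only.
#'
#' @param records Data frame from [run_sensitivity()].
#' @param outcome Name of the outcome column (e.g. `"t_seq"`,
#'   `"t_mix_both"`, `"t_adapt_both"`) or a numeric vector such as a
#'   difference of times.
#' @return Named numeric vector of PRCC coefficients.
#' @export
sensitivity_prcc <- function(records, outcome = "t_mix_both") {
  vars <- c(
    "start_freq_allele1", "start_freq_allele2", "exposure",
    "male_exposure_prop", "effectiveness_ins1", "effectiveness_ins2",
    "dominance_allele1", "dominance_allele2",
    "rr_restoration_ins1", "rr_restoration_ins2", "correct_mix_deploy",
    "resist_start_1_div_2", "resist_start_hi_div_lo"
  )
  vars <- intersect(vars, names(records))
  y <- if (is.character(outcome)) records[[outcome]] else outcome
  keep <- !is.na(y)
  prcc(records[keep, vars, drop = FALSE], y[keep])
}
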