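#' Write and read a trajectory CSV
#'
#' Writes a strategy outcome's per-generation trajectory with a fixed
#' column order: `generation, freq_R1_m, freq_R1_f, freq_R2_m, freq_R2_f,
#' LD, mean_fitness, deployment_label`, one row per generation including
#' generation 0. Values round-trip through [read_trajectory()] to within
#' 1e-12 (full precision is written).
#'
#' @param outcome A `strategy_outcome` (or a trajectory data frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(outcome, path) {
  traj <- if (inherits(outcome, "strategy_outcome")) outcome$trajectory else outcome
  cols <- c("generation", "freq_R1_m", "freq_R1_f", "freq_R2_m", "freq_R2_f",
            "LD", "mean_fitness", "deployment")
  stopifnot(all(cols %in% names(traj)))
  out <- traj[, cols]
  names(out)[names(out) == "deployment"] <- "deployment_label"
  # write.table serialises doubles at 15 significant digits, comfortably
  # inside the 1e-12 round-trip guarantee
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df)[names(df) == "deployment_label"] <- "deployment"
  df
}

#' Write and read sensitivity records
#'
#' Writes the per-run records of a sensitivity batch (sampled parameters,
#' times, censoring flags and, when present, labels) with a deterministic
#' column order. An empty record set produces a header-only file.
#'
#' @param records Data frame from [run_sensitivity()] /
#'   [compare_strategies()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a strategy-outcome summary CSV
#'
#' One row per outcome: strategy, per-insecticide crossing generations,
#' `t_first`, `t_both` and the censoring flag.
#'
#' @param outcomes A `strategy_outcome` or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_outcome_summary <- function(outcomes, path) {
  if (inherits(outcomes, "strategy_outcome")) outcomes <- list(outcomes)
  rows <- lapply(outcomes, function(o) {
    data.frame(
      strategy = o$strategy,
      t_cross_ins1 = o$t_cross[[1]], t_cross_ins2 = o$t_cross[[2]],
      t_first = o$t_first, t_both = o$t_both,
      censored = o$censored,
      stringsAsFactors = FALSE
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
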