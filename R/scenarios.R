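#' Scenario configuration
#'
#' One cell of the experiment grid: a bed count, a theatre schedule, and
#' productivity multipliers on procedure lengths of stay and on the delayed
#' proportion. Multipliers of 1 are the baseline; the grid's "low" settings
#' use 0.25. Scenario vocabulary for labels: `high_los`/`low_los`,
#' `prop_high`/`prop_low`.
#'
#' @param n_beds Ward bed count (>= 0).
#' @param schedule A [schedule_config()]; default [baseline_schedule()].
#' @param los_multiplier Positive scale on procedure LOS mean and SD.
#' @param prop_multiplier Positive scale on the delayed proportion.
#' @param label Scenario label; autogenerated when `NULL`.
#' @return An object of class `scenario_config`.
#' @export
#' @examples
#' scenario_config(40, baseline_schedule(), los_multiplier = 0.25)
scenario_config <- function(n_beds, schedule = baseline_schedule(),
                            los_multiplier = 1, prop_multiplier = 1,
                            label = NULL) {
  if (!is.numeric(n_beds) || length(n_beds) != 1L || n_beds < 0 ||
      n_beds != round(n_beds)) {
    stop("`n_beds` must be a single non-negative integer", call. = FALSE)
  }
  stopifnot(inherits(schedule, "schedule_config"))
  if (los_multiplier <= 0 || prop_multiplier <= 0) {
    stop("multipliers must be strictly positive", call. = FALSE)
  }
  if (is.null(label)) {
    label <- paste0(
      "beds", n_beds, "_", schedule$label, "_",
      if (isTRUE(all.equal(los_multiplier, 1))) "high_los"
      else if (isTRUE(all.equal(los_multiplier, 0.25))) "low_los"
      else paste0("los", los_multiplier), "_",
      if (isTRUE(all.equal(prop_multiplier, 1))) "prop_high"
      else if (isTRUE(all.equal(prop_multiplier, 0.25))) "prop_low"
      else paste0("prop", prop_multiplier)
    )
  }
  structure(list(label = label, n_beds = as.integer(n_beds),
                 schedule = schedule,
                 los_multiplier = as.numeric(los_multiplier),
                 prop_multiplier = as.numeric(prop_multiplier)),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> %s\n  %d beds, schedule %s, los x%.3g, prop x%.3g\n",
              x$label, x$n_beds, x$schedule$label, x$los_multiplier,
              x$prop_multiplier))
  invisible(x)
}

#' Experiment grid specification
#'
#' Factor levels for a full-cross scenario sweep. The default is the study
#' grid: beds 30–70 in steps of 5 (9 values), the 5-day and 7-day schedules,
#' LOS multipliers \{1, 0.25\} and delayed-proportion multipliers \{1, 0.25\}
#' — 72 scenarios in all.
#'
#' @param bed_values Bed counts.
#' @param schedules List of [schedule_config()]s.
#' @param los_multipliers,prop_multipliers Positive multipliers.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(bed_values = seq(30, 70, by = 5),
                      schedules = list(baseline_schedule(), weekend_schedule()),
                      los_multipliers = c(1, 0.25),
                      prop_multipliers = c(1, 0.25)) {
  if (length(bed_values) == 0L || length(schedules) == 0L ||
      length(los_multipliers) == 0L || length(prop_multipliers) == 0L) {
    stop("every grid factor must have at least one level", call. = FALSE)
  }
  ok <- vapply(schedules, inherits, logical(1), what = "schedule_config")
  if (!all(ok)) stop("`schedules` must be a list of `schedule_config`s",
                     call. = FALSE)
  structure(list(bed_values = as.integer(bed_values), schedules = schedules,
                 los_multipliers = los_multipliers,
                 prop_multipliers = prop_multipliers),
            class = "grid_spec")
}

#' Build the scenario grid
#'
#' Full cross-product of the grid factors, deterministically ordered with beds
#' outermost, then schedule, then LOS multiplier, then delayed-proportion
#' multiplier. Labels encode all four factors.
#'
#' @param spec A [grid_spec()].
#' @return A list of [scenario_config()]s.
#' @export
#' @examples
#' length(build_scenario_grid(grid_spec()))  # 72
build_scenario_grid <- function(spec = grid_spec()) {
  stopifnot(inherits(spec, "grid_spec"))
  out <- list()
  for (beds in spec$bed_values) {
    for (sched in spec$schedules) {
      for (lm in spec$los_multipliers) {
        for (pm in spec$prop_multipliers) {
          out[[length(out) + 1L]] <- scenario_config(
            n_beds = beds, schedule = sched,
            los_multiplier = lm, prop_multiplier = pm
          )
        }
      }
    }
  }
  out
}

#' Apply productivity multipliers to model parameters
#'
#' Scales every procedure length-of-stay specification (mean and SD, so the
#' coefficient of variation is preserved) by `los_multiplier`, and the delayed
#' proportion by `prop_multiplier`. The delayed-stay distribution is never
#' altered: in all scenarios it remains at its baseline value.
#'
#' @param params A [model_params()].
#' @param los_multiplier,prop_multiplier Positive multipliers.
#' @return A new `model_params`; errors if the scaled proportion exceeds 1.
#' @export
#' @examples
#' apply_multipliers(baseline_params(), 0.25, 0.25)
apply_multipliers <- function(params, los_multiplier = 1, prop_multiplier = 1) {
  stopifnot(inherits(params, "model_params"))
  if (los_multiplier <= 0 || prop_multiplier <= 0) {
    stop("multipliers must be strictly positive", call. = FALSE)
  }
  new_prop <- params$prop_delayed * prop_multiplier
  if (new_prop > 1) {
    stop("scaled delayed proportion ", signif(new_prop, 4),
         " exceeds 1: infeasible scenario", call. = FALSE)
  }
  specs <- lapply(params$los_specs, function(s) {
    los_spec(s$mean_days * los_multiplier, s$sd_days * los_multiplier)
  })
  model_params(los_specs = specs, delayed_los = params$delayed_los,
               prop_delayed = new_prop, mix = params$case_mix)
}
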