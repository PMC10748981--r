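#' Run one scenario end to end
#'
#' Replications, per-replication summaries and cross-replication aggregation
#' in one call.
#'
#' @inheritParams run_replications
#' @return A list of class `scenario_result` with `scenario`, `stats`
#'   (a [aggregate_replications()] tibble) and `summaries` (per replication).
#' @export
#' @examples
#' rs <- run_scenario(scenario_config(40, los_multiplier = 0.25),
#'                    baseline_params(), n_reps = 3, base_seed = 1,
#'                    warmup_days = 14, collect_days = 28)
#' rs$stats
run_scenario <- function(scenario, params, n_reps = 30, base_seed = 1,
                         warmup_days = 42, collect_days = 182,
                         delayed_mode = c("replace", "add")) {
  delayed_mode <- match.arg(delayed_mode)
  reps <- run_replications(scenario, params, n_reps = n_reps,
                           base_seed = base_seed, warmup_days = warmup_days,
                           collect_days = collect_days,
                           delayed_mode = delayed_mode)
  summaries <- lapply(reps, summarise_replication)
  structure(list(scenario = scenario,
                 stats = aggregate_replications(summaries),
                 summaries = summaries),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %s\n", x$scenario$label))
  ov <- x$stats[x$stats$weekday == "overall", ]
  for (m in c("utilisation", "throughput", "lost_slots")) {
    r <- ov[ov$metric == m, ]
    cat(sprintf("  %-12s mean %.3f (IQR %.3f-%.3f)\n", m, r$mean, r$q25, r$q75))
  }
  invisible(x)
}

#' Default experiment configuration
#'
#' The configuration used when no file is supplied: baseline parameters, a
#' single 40-bed baseline-schedule scenario, the study grid factors, 30
#' replications, 42 warm-up days and 182 collection days.
#'
#' @return A nested list mirroring the YAML config layout.
#' @export
default_experiment_config <- function() {
  list(
    params = yaml::read_yaml(system.file("extdata", "baseline_params.yaml",
                                         package = "orthoflow")),
    scenario = list(beds = 40, schedule = "baseline",
                    los_multiplier = 1, prop_multiplier = 1),
    grid = list(bed_values = seq(30, 70, by = 5),
                schedules = c("baseline", "baseline_weekend"),
                los_multipliers = c(1, 0.25),
                prop_multipliers = c(1, 0.25)),
    run = list(n_reps = 30, warmup_days = 42, collect_days = 182, seed = 1),
    revision_share = 0.13
  )
}

#' Read an experiment configuration file
#'
#' YAML with top-level keys `params` (see [read_model_params()] for layout),
#' `scenario` (`beds`, `schedule`, `los_multiplier`, `prop_multiplier`),
#' `grid` (`bed_values`, `schedules`, `los_multipliers`, `prop_multipliers`),
#' `run` (`n_reps`, `warmup_days`, `collect_days`, `seed`) and optional
#' `revision_share`. Any key left out falls back to
#' [default_experiment_config()].
#'
#' @param path YAML file path.
#' @return A config list.
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop("malformed config ", path, ": ", conditionMessage(e), call. = FALSE)
  })
  config <- default_experiment_config()
  for (key in names(raw)) {
    if (is.list(raw[[key]]) && is.list(config[[key]])) {
      config[[key]] <- utils::modifyList(config[[key]], raw[[key]])
    } else {
      config[[key]] <- raw[[key]]
    }
  }
  config
}

.schedule_from_name <- function(name, revision_share = 0.13) {
  p <- revision_session_probability(revision_share)
  switch(name,
    baseline = baseline_schedule(revision_session_prob = p),
    "baseline_weekend" = weekend_schedule(revision_session_prob = p),
    "baseline-weekend" = weekend_schedule(revision_session_prob = p),
    stop("unknown schedule name: ", name, " (expected 'baseline' or ",
         "'baseline_weekend')", call. = FALSE)
  )
}

#' Run a configured experiment and write tabular outputs
#'
#' Orchestrates a full run from a configuration: builds the parameters and
#' scenario (or scenario grid), runs seeded replications, and writes to
#' `out_dir`:
#' \itemize{
#'   \item `scenario_summary.csv` — one row per scenario x metric x weekday
#'     with cross-replication mean, min, quartiles, median and max;
#'   \item `replications.csv` — per-replication metric values for audit;
#'   \item `manifest.json` — seed, package version, config echo and timestamp.
#' }
#' Scenarios that are individually infeasible (for example a scaled delayed
#' proportion above 1) are reported in the manifest under `failed_scenarios`
#' and the remainder still run.
#'
#' @param config_path Optional YAML config path (see
#'   [read_experiment_config()]).
#' @param config Optional config list overriding `config_path`.
#' @param grid If `TRUE`, run the configured scenario grid instead of the
#'   single configured scenario.
#' @param out_dir Output directory, created if needed.
#' @param overrides Named list applied on top of the config's `run`/`scenario`
#'   entries (used by the command-line interface).
#' @param quiet Suppress per-scenario progress messages.
#' @return Invisibly, a list with `summary` and `replications` tibbles,
#'   `manifest`, and the output paths.
#' @export
run_experiment <- function(config_path = NULL, config = NULL, grid = FALSE,
                           out_dir = "orthoflow-results", overrides = list(),
                           quiet = FALSE) {
  if (is.null(config)) {
    config <- if (is.null(config_path)) default_experiment_config()
              else read_experiment_config(config_path)
  }
  for (key in names(overrides)) {
    if (key %in% names(config$run)) config$run[[key]] <- overrides[[key]]
    else if (key %in% names(config$scenario)) {
      config$scenario[[key]] <- overrides[[key]]
    } else config[[key]] <- overrides[[key]]
  }
  params <- parse_model_params(config$params)
  rev_share <- config$revision_share %||% 0.13
  run <- config$run

  scenarios <- if (isTRUE(grid)) {
    build_scenario_grid(grid_spec(
      bed_values = config$grid$bed_values,
      schedules = lapply(config$grid$schedules, .schedule_from_name,
                         revision_share = rev_share),
      los_multipliers = config$grid$los_multipliers,
      prop_multipliers = config$grid$prop_multipliers
    ))
  } else {
    sc <- config$scenario
    list(scenario_config(
      n_beds = sc$beds,
      schedule = .schedule_from_name(sc$schedule, rev_share),
      los_multiplier = sc$los_multiplier,
      prop_multiplier = sc$prop_multiplier
    ))
  }

  summary_rows <- list()
  rep_rows <- list()
  failed <- list()
  for (i in seq_along(scenarios)) {
    sc <- scenarios[[i]]
    res <- tryCatch(
      run_scenario(sc, params, n_reps = run$n_reps, base_seed = run$seed,
                   warmup_days = run$warmup_days,
                   collect_days = run$collect_days),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failed[[sc$label]] <- conditionMessage(res)
      if (!quiet) message("scenario ", sc$label, " failed: ",
                          conditionMessage(res))
      next
    }
    if (!quiet) {
      ov <- res$stats[res$stats$weekday == "overall" &
                        res$stats$metric == "utilisation", ]
      message(sprintf("[%d/%d] %s: %d reps, mean utilisation %.1f%%",
                      i, length(scenarios), sc$label, run$n_reps,
                      100 * ov$mean))
    }
    st <- res$stats
    st <- tibble::add_column(st, scenario = sc$label, .before = 1)
    summary_rows[[length(summary_rows) + 1L]] <- st
    long <- do.call(rbind, lapply(seq_along(res$summaries), function(r) {
      d <- .summary_long(res$summaries[[r]])
      d$rep <- r
      d
    }))
    long$scenario <- sc$label
    rep_rows[[length(rep_rows) + 1L]] <-
      tibble::as_tibble(long[, c("scenario", "rep", "metric", "weekday",
                                 "value")])
  }
  if (length(summary_rows) == 0L) {
    stop("no scenario completed successfully", call. = FALSE)
  }
  summary_tbl <- dplyr::bind_rows(summary_rows)
  rep_tbl <- dplyr::bind_rows(rep_rows)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summary_path <- file.path(out_dir, "scenario_summary.csv")
  rep_path <- file.path(out_dir, "replications.csv")
  manifest_path <- file.path(out_dir, "manifest.json")
  write.csv(as.data.frame(summary_tbl), summary_path, row.names = FALSE,
            fileEncoding = "UTF-8")
  write.csv(as.data.frame(rep_tbl), rep_path, row.names = FALSE,
            fileEncoding = "UTF-8")
  manifest <- list(
    package = "orthoflow",
    version = as.character(utils::packageVersion("orthoflow")),
    seed = run$seed,
    n_reps = run$n_reps,
    warmup_days = run$warmup_days,
    collect_days = run$collect_days,
    grid = isTRUE(grid),
    n_scenarios = length(scenarios),
    failed_scenarios = failed,
    config = config,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(summary = summary_tbl, replications = rep_tbl,
                 manifest = manifest,
                 paths = c(summary = summary_path, replications = rep_path,
                           manifest = manifest_path)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
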