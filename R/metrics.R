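#' Summarise one replication
#'
#' Discards warm-up days and computes per-weekday and overall means of bed
#' utilisation (audited occupancy divided by beds), lost slots and total
#' admissions per day, plus mean daily throughput per procedure. Averaging is
#' day-level first: each collection day contributes one utilisation value,
#' then days are grouped by weekday.
#'
#' @param result A [run_replication()] result.
#' @param warmup_days Days to discard from the start; defaults to the value
#'   recorded in the replication. Must be smaller than the horizon.
#' @return A list of class `replication_summary` with elements `weekday`
#'   (tibble: `weekday`, `utilisation`, `lost_slots`, `throughput`), `overall`
#'   (one-row tibble of the same metrics over all collection days), and
#'   `by_procedure` (tibble: `procedure`, `throughput` — mean admissions/day).
#' @export
summarise_replication <- function(result, warmup_days = NULL) {
  stopifnot(inherits(result, "replication_result"))
  if (is.null(warmup_days)) warmup_days <- result$meta$warmup_days
  horizon <- nrow(result$daily)
  if (warmup_days >= horizon) {
    stop("`warmup_days` (", warmup_days, ") must be smaller than the horizon (",
         horizon, ")", call. = FALSE)
  }
  beds <- result$meta$n_beds
  daily <- result$daily[result$daily$day >= warmup_days, ]
  thr <- result$throughput[result$throughput$day >= warmup_days, ]
  util <- if (beds > 0) daily$occupancy / beds else rep(0, nrow(daily))

  df <- tibble::tibble(weekday = daily$weekday, utilisation = util,
                       lost_slots = daily$lost_slots,
                       throughput = daily$admissions)
  by_wd <- dplyr::summarise(
    dplyr::group_by(df, weekday = factor(weekday, levels = .of$weekdays)),
    utilisation = mean(utilisation), lost_slots = mean(lost_slots),
    throughput = mean(throughput), .groups = "drop"
  )
  by_wd <- dplyr::arrange(by_wd, weekday)
  by_wd$weekday <- as.character(by_wd$weekday)

  overall <- tibble::tibble(weekday = "overall",
                            utilisation = mean(df$utilisation),
                            lost_slots = mean(df$lost_slots),
                            throughput = mean(df$throughput))

  by_proc <- tibble::tibble(
    procedure = .of$procedures,
    throughput = vapply(.of$procedures, function(p) mean(thr[[p]]), numeric(1))
  )

  structure(list(weekday = by_wd, overall = overall, by_procedure = by_proc,
                 meta = result$meta),
            class = "replication_summary")
}

# flatten a replication_summary to long (metric, weekday, value) form
.summary_long <- function(s) {
  wd <- rbind(as.data.frame(s$weekday), as.data.frame(s$overall))
  base <- do.call(rbind, lapply(c("utilisation", "lost_slots", "throughput"),
                                function(m) {
    data.frame(metric = m, weekday = wd$weekday, value = wd[[m]])
  }))
  proc <- data.frame(metric = paste0("throughput_", s$by_procedure$procedure),
                     weekday = "overall", value = s$by_procedure$throughput)
  rbind(base, proc)
}

#' Aggregate replication summaries
#'
#' Cross-replication mean and spread (min, lower quartile, median, upper
#' quartile, max) for every metric and weekday, in boxplot-ready long form.
#' Quartiles follow the Tukey convention used for boxplots
#' (`quantile(type = 7)` medians/hinges via `stats::quantile`).
#'
#' @param summaries Non-empty list of [summarise_replication()] results.
#' @return A tibble of class `summary_stats` with columns `metric`, `weekday`,
#'   `mean`, `min`, `q25`, `median`, `q75`, `max` and attribute `n_reps`.
#' @export
aggregate_replications <- function(summaries) {
  if (length(summaries) == 0L) stop("`summaries` is empty", call. = FALSE)
  ok <- vapply(summaries, inherits, logical(1), what = "replication_summary")
  if (!all(ok)) stop("`summaries` must be `replication_summary` objects",
                     call. = FALSE)
  long <- do.call(rbind, lapply(seq_along(summaries), function(i) {
    d <- .summary_long(summaries[[i]])
    d$rep <- i
    d
  }))
  agg <- dplyr::summarise(
    dplyr::group_by(long, .data$metric, .data$weekday),
    mean = mean(.data$value), min = min(.data$value),
    q25 = as.numeric(quantile(.data$value, 0.25)),
    median = median(.data$value),
    q75 = as.numeric(quantile(.data$value, 0.75)),
    max = max(.data$value), .groups = "drop"
  )
  wd_levels <- c(.of$weekdays, "overall")
  agg <- dplyr::arrange(agg, .data$metric,
                        factor(.data$weekday, levels = wd_levels))
  out <- tibble::as_tibble(agg)
  attr(out, "n_reps") <- length(summaries)
  class(out) <- c("summary_stats", class(out))
  out
}

#' Flag bed-pressure weekdays
#'
#' Annotates aggregated statistics with a logical `pressure` column: `TRUE`
#' for utilisation rows whose cross-replication mean exceeds the threshold
#' (`NA` for other metrics). Sustained mean occupancies above roughly 85–90%
#' are associated with recurrent bed crises, hence the default threshold.
#'
#' @param stats A [aggregate_replications()] result.
#' @param threshold Utilisation fraction in (0, 1]; default 0.85.
#' @return `stats` with a `pressure` column and attribute
#'   `pressure_threshold`.
#' @export
flag_pressure <- function(stats, threshold = 0.85) {
  stopifnot(inherits(stats, "summary_stats"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0 ||
      threshold > 1) {
    stop("`threshold` must lie in (0, 1]", call. = FALSE)
  }
  stats$pressure <- ifelse(stats$metric == "utilisation",
                           stats$mean > threshold, NA)
  attr(stats, "pressure_threshold") <- threshold
  stats
}

#' @export
print.summary_stats <- function(x, ...) {
  n <- attr(x, "n_reps")
  cat(sprintf("<summary_stats> %d replication(s)\n", n))
  NextMethod()
  invisible(x)
}
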