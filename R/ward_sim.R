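# The discrete-event engine.
#
# Because surgical demand is generated by the schedule (not by an arrival
# process that depends on system state) and lost slots are terminal, a
# replication factorises into three phases:
#   1. realise all bookings over the horizon (schedule randomness);
#   2. sample each booked patient's procedure, delay flag and total stay
#      (routing randomness) — drawn for every booking, admitted or not, so the
#      random-number stream is identical across bed counts (common random
#      numbers);
#   3. a deterministic chronological bed-allocation pass over bookings in
#      (arrival time, session, theatre, slot) priority order.
# Occupancy is audited once per day at 23:59. A discharge at exactly the same
# instant as an arrival frees its bed first.

# allocation pass: arrivals/los in priority order; returns logical admitted
.allocate_beds <- function(arrival, los, beds) {
  n <- length(arrival)
  admitted <- logical(n)
  if (beds <= 0L || n == 0L) return(admitted)
  disch <- numeric(0)
  for (i in seq_len(n)) {
    a <- arrival[i]
    if (length(disch)) disch <- disch[disch > a]
    if (length(disch) < beds) {
      admitted[i] <- TRUE
      disch <- c(disch, a + los[i])
    }
  }
  admitted
}

#' Run one seeded replication
#'
#' Simulates patient flow over `warmup_days + collect_days` days: the schedule
#' books patients into theatre sessions, each booked patient is routed through
#' delayed-discharge sampling, and at the arrival instant a ward bed is
#' claimed if one is free (held for the full stay) or the theatre slot is
#' recorded as lost — lost-slot patients leave the system and are not
#' rebooked. The ward starts empty; warm-up days are retained in the series
#' and excluded later by [summarise_replication()]. Identical seeds give
#' identical results.
#'
#' @param scenario A [scenario_config()].
#' @param params Baseline [model_params()]; the scenario's multipliers are
#'   applied internally via [apply_multipliers()].
#' @param seed Integer seed for this replication.
#' @param warmup_days,collect_days Horizon components; defaults 42 and 182
#'   (6 + 26 weeks). Their sum must be positive and `collect_days >= 1`.
#' @param delayed_mode Passed to [route_total_los()].
#' @param keep_patients If `TRUE`, the patient-level table is kept in the
#'   result (`$patients`).
#' @return An object of class `replication_result`: a list with `daily`
#'   (tibble: `day`, `weekday`, `bookings`, `admissions`, `lost_slots`,
#'   `occupancy`), `throughput` (tibble: `day` plus one admissions column per
#'   procedure), and `meta` (seed, beds, horizon, scenario label).
#' @export
#' @examples
#' res <- run_replication(scenario_config(40), baseline_params(), seed = 1,
#'                        warmup_days = 7, collect_days = 14)
#' head(res$daily)
run_replication <- function(scenario, params, seed,
                            warmup_days = 42, collect_days = 182,
                            delayed_mode = c("replace", "add"),
                            keep_patients = FALSE) {
  stopifnot(inherits(scenario, "scenario_config"),
            inherits(params, "model_params"))
  delayed_mode <- match.arg(delayed_mode)
  if (warmup_days < 0 || collect_days < 1) {
    stop("invalid horizon: need `warmup_days` >= 0 and `collect_days` >= 1",
         call. = FALSE)
  }
  horizon <- as.integer(warmup_days + collect_days)
  sparams <- apply_multipliers(params, scenario$los_multiplier,
                               scenario$prop_multiplier)

  sim <- function() {
    bookings <- .bookings_for_days(scenario$schedule, 0:(horizon - 1L))
    n <- nrow(bookings)
    if (n > 0L) {
      procedure <- character(n)
      is_rev <- bookings$surgical_class == "revision"
      if (any(!is_rev)) {
        procedure[!is_rev] <- sample_procedure(sparams$case_mix, "primary",
                                               sum(!is_rev))
      }
      if (any(is_rev)) {
        procedure[is_rev] <- sample_procedure(sparams$case_mix, "revision",
                                              sum(is_rev))
      }
      u_delay <- runif(n)
      u_los <- runif(n)
      route <- route_total_los(procedure, sparams, los_multiplier = 1,
                               delayed_mode = delayed_mode,
                               u_delay = u_delay, u_los = u_los)
    } else {
      procedure <- character(0)
      route <- tibble::tibble(delayed = logical(0), los_days = numeric(0))
    }
    list(bookings = bookings, procedure = procedure, route = route)
  }
  drawn <- withr::with_seed(seed, sim())
  bookings <- drawn$bookings

  admitted <- .allocate_beds(bookings$arrival, drawn$route$los_days,
                             scenario$n_beds)
  discharge <- ifelse(admitted, bookings$arrival + drawn$route$los_days, NA_real_)

  days <- 0:(horizon - 1L)
  dayf <- factor(bookings$day, levels = days)
  booked_per_day <- as.integer(table(dayf))
  adm_per_day <- as.integer(table(dayf[admitted]))
  lost_per_day <- booked_per_day - adm_per_day

  audit_t <- days + .of$audit_frac
  adm_sorted <- sort(bookings$arrival[admitted])
  dis_sorted <- sort(discharge[admitted])
  occupancy <- findInterval(audit_t, adm_sorted) -
    findInterval(audit_t, dis_sorted)

  daily <- tibble::tibble(
    day = days,
    weekday = .of$weekdays[days %% 7 + 1],
    bookings = booked_per_day,
    admissions = adm_per_day,
    lost_slots = lost_per_day,
    occupancy = as.integer(occupancy)
  )

  thr <- table(dayf[admitted],
               factor(drawn$procedure[admitted], levels = .of$procedures))
  throughput <- tibble::as_tibble(as.data.frame.matrix(thr))
  throughput <- tibble::add_column(throughput, day = days, .before = 1)

  out <- list(
    daily = daily,
    throughput = throughput,
    meta = list(scenario = scenario$label, seed = seed,
                n_beds = scenario$n_beds, warmup_days = as.integer(warmup_days),
                collect_days = as.integer(collect_days),
                delayed_mode = delayed_mode)
  )
  if (keep_patients) {
    out$patients <- tibble::tibble(
      id = seq_len(nrow(bookings)),
      day = bookings$day, weekday = bookings$weekday,
      session = bookings$session, theatre = bookings$theatre,
      slot = bookings$slot, surgical_class = bookings$surgical_class,
      procedure = drawn$procedure, delayed = drawn$route$delayed,
      los_days = drawn$route$los_days,
      admit_time = ifelse(admitted, bookings$arrival, NA_real_),
      discharge_time = discharge,
      outcome = ifelse(admitted, "admitted", "lost_slot")
    )
  }
  class(out) <- "replication_result"
  out
}

#' @export
print.replication_result <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<replication_result> %s (seed %d): %d+%d days, %d beds\n",
              m$scenario, m$seed, m$warmup_days, m$collect_days, m$n_beds))
  cat(sprintf("  total bookings %d, admissions %d, lost slots %d\n",
              sum(x$daily$bookings), sum(x$daily$admissions),
              sum(x$daily$lost_slots)))
  invisible(x)
}

#' Run independent replications
#'
#' Spawns one substream seed per replication from `base_seed` (master
#' `set.seed(base_seed)`, then `sample.int(.Machine$integer.max - 1, n_reps)`)
#' and runs [run_replication()] on each. Because the spawning rule depends
#' only on `base_seed`, scenarios run with the same `base_seed` share random
#' numbers replication-by-replication (common random numbers).
#'
#' @inheritParams run_replication
#' @param n_reps Number of replications (>= 1); default 30.
#' @param base_seed Master seed.
#' @return List of `replication_result` objects.
#' @export
run_replications <- function(scenario, params, n_reps = 30, base_seed = 1,
                             warmup_days = 42, collect_days = 182,
                             delayed_mode = c("replace", "add")) {
  if (n_reps < 1) stop("`n_reps` must be >= 1", call. = FALSE)
  delayed_mode <- match.arg(delayed_mode)
  seeds <- withr::with_seed(base_seed,
                            sample.int(.Machine$integer.max - 1L, n_reps))
  lapply(seeds, function(s) {
    run_replication(scenario, params, seed = s, warmup_days = warmup_days,
                    collect_days = collect_days, delayed_mode = delayed_mode)
  })
}
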