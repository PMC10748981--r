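#' Calibrate the per-session revision probability
#'
#' Under the baseline session rules — morning and afternoon sessions hold
#' either one revision or two primary surgeries, the evening session one
#' primary — a theatre-day books on average `5 - 2p` patients of which `2p`
#' are revisions, where `p` is the probability that a morning/afternoon
#' session is a revision session. Solving `2p / (5 - 2p) = s` for a target
#' revision share `s` gives `p = 5s / (2 (1 + s))`. Shares above 2/3 are
#' infeasible under these rules (even `p = 1` yields a 2/3 share).
#'
#' @param target_revision_share Desired long-run share of booked patients that
#'   are revision class, in `[0, 2/3]`.
#' @return The per-session revision probability `p`.
#' @export
#' @examples
#' revision_session_probability(0.13)  # ~0.288 reproduces the 13% case mix
revision_session_probability <- function(target_revision_share) {
  s <- target_revision_share
  if (!is.numeric(s) || length(s) != 1L || s < 0) {
    stop("`target_revision_share` must be a single probability", call. = FALSE)
  }
  if (s > 2 / 3) {
    stop("revision share ", s, " is infeasible: the session rules cannot ",
         "exceed a 2/3 revision share", call. = FALSE)
  }
  5 * s / (2 * (1 + s))
}

#' Theatre schedule configuration
#'
#' Describes the weekly theatre template: how many theatres run, on which
#' weekdays, how many sessions per theatre-day (in order morning, afternoon,
#' evening), and the probability that a morning/afternoon session books one
#' revision rather than two primaries. The probability may be a single number
#' or a length-7 vector named `Mon`..`Sun` to schedule revisions unevenly
#' across the week. The default probability is calibrated so the emergent
#' booked case mix is 13% revision (see [revision_session_probability()]).
#'
#' @param n_theatres Number of theatres (>= 0); baseline 4.
#' @param operating_weekdays Subset of `Mon`..`Sun`; baseline Mon–Fri.
#' @param sessions_per_day Sessions per theatre-day, 0–3; baseline 3.
#' @param revision_session_prob Scalar or per-weekday probabilities in [0, 1].
#' @param label Optional display label.
#' @return An object of class `schedule_config`.
#' @seealso [baseline_schedule()], [weekend_schedule()].
#' @export
schedule_config <- function(n_theatres = 4,
                            operating_weekdays = c("Mon", "Tue", "Wed", "Thu",
                                                   "Fri"),
                            sessions_per_day = 3,
                            revision_session_prob =
                              revision_session_probability(0.13),
                            label = NULL) {
  if (!is.numeric(n_theatres) || length(n_theatres) != 1L || n_theatres < 0 ||
      n_theatres != round(n_theatres)) {
    stop("`n_theatres` must be a single non-negative integer", call. = FALSE)
  }
  if (!all(operating_weekdays %in% .of$weekdays)) {
    stop("`operating_weekdays` must be a subset of ",
         paste(.of$weekdays, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(sessions_per_day) || length(sessions_per_day) != 1L ||
      sessions_per_day < 0 || sessions_per_day > 3 ||
      sessions_per_day != round(sessions_per_day)) {
    stop("`sessions_per_day` must be an integer between 0 and 3", call. = FALSE)
  }
  p <- revision_session_prob
  if (length(p) == 1L) p <- setNames(rep(p, 7), .of$weekdays)
  if (length(p) != 7L || is.null(names(p)) || !setequal(names(p), .of$weekdays)) {
    stop("`revision_session_prob` must be a scalar or a length-7 vector ",
         "named Mon..Sun", call. = FALSE)
  }
  p <- p[.of$weekdays]
  if (any(p < 0) || any(p > 1)) {
    stop("`revision_session_prob` values must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(label)) {
    label <- if (setequal(operating_weekdays, .of$weekdays)) "baseline_weekend"
             else "baseline"
  }
  structure(list(
    n_theatres = as.integer(n_theatres),
    operating_weekdays = .of$weekdays[.of$weekdays %in% operating_weekdays],
    sessions_per_day = as.integer(sessions_per_day),
    revision_session_prob = p,
    label = label
  ), class = "schedule_config")
}

#' Stock schedules
#'
#' `baseline_schedule()` is 4 theatres, Monday–Friday, 3 sessions per day;
#' `weekend_schedule()` keeps the same daily allocations with 7-day working.
#'
#' @param n_theatres Number of theatres.
#' @param ... Passed on to [schedule_config()].
#' @return A `schedule_config`.
#' @export
baseline_schedule <- function(n_theatres = 4, ...) {
  schedule_config(n_theatres = n_theatres, ...)
}

#' @rdname baseline_schedule
#' @export
weekend_schedule <- function(n_theatres = 4, ...) {
  schedule_config(n_theatres = n_theatres, operating_weekdays = .of$weekdays,
                  ...)
}

#' @export
print.schedule_config <- function(x, ...) {
  cat(sprintf("<schedule_config> %s: %d theatre(s), %d session(s)/day, %s\n",
              x$label, x$n_theatres, x$sessions_per_day,
              paste(x$operating_weekdays, collapse = " ")))
  cat(sprintf("  revision session probability: %s\n",
              paste(sprintf("%s %.3f", .of$weekdays,
                            x$revision_session_prob), collapse = ", ")))
  invisible(x)
}

#' Build the weekly theatre template
#'
#' Enumerates every (weekday, theatre, session) cell of the week: the baseline
#' schedule yields 5 days x 4 theatres x 3 sessions = 60 cells; the weekend
#' variant 84. Cells are ordered by weekday, then session (morning, afternoon,
#' evening), then theatre — the order in which bookings claim beds on ties.
#'
#' @param config A [schedule_config()].
#' @return A tibble of class `week_template` with columns `weekday`, `session`,
#'   `theatre` and the config stored as attribute `config`.
#' @export
#' @examples
#' nrow(build_week_template(baseline_schedule()))  # 60
build_week_template <- function(config) {
  stopifnot(inherits(config, "schedule_config"))
  sessions <- .of$sessions[seq_len(config$sessions_per_day)]
  cells <- expand.grid(theatre = seq_len(config$n_theatres),
                       session = sessions,
                       weekday = config$operating_weekdays,
                       stringsAsFactors = FALSE)
  cells <- cells[, c("weekday", "session", "theatre")]
  out <- tibble::as_tibble(cells)
  attr(out, "config") <- config
  class(out) <- c("week_template", class(out))
  out
}

# Bookings for a set of simulation days, fully vectorised. Day 0 is a Monday.
# RNG consumption order is deterministic: one uniform per morning/afternoon
# cell in (day, session, theatre) order. Returns bookings in arrival/priority
# order with session start fractions attached.
.bookings_for_days <- function(config, days) {
  wd <- .of$weekdays[days %% 7 + 1]
  operating <- wd %in% config$operating_weekdays
  days <- days[operating]
  wd <- wd[operating]
  n_cells <- config$sessions_per_day * config$n_theatres
  if (length(days) == 0L || n_cells == 0L) {
    return(tibble::tibble(day = integer(), weekday = character(),
                          session = character(), theatre = integer(),
                          slot = integer(), surgical_class = character(),
                          arrival = numeric()))
  }
  # per-day cell pattern (same for every operating weekday)
  sessions <- .of$sessions[seq_len(config$sessions_per_day)]
  cell_session <- rep(sessions, each = config$n_theatres)
  cell_theatre <- rep(seq_len(config$n_theatres), times = length(sessions))
  nd <- length(days)
  day_v <- rep(days, each = n_cells)
  wd_v <- rep(wd, each = n_cells)
  sess_v <- rep(cell_session, times = nd)
  thea_v <- rep(cell_theatre, times = nd)
  is_ma <- sess_v %in% c("morning", "afternoon")
  # revision draw for each morning/afternoon cell, in row order
  rev <- logical(length(sess_v))
  if (any(is_ma)) {
    p <- config$revision_session_prob[wd_v[is_ma]]
    rev[is_ma] <- runif(sum(is_ma)) < p
  }
  n_book <- ifelse(is_ma, ifelse(rev, 1L, 2L), 1L)
  idx <- rep(seq_along(sess_v), times = n_book)
  out <- tibble::tibble(
    day = day_v[idx],
    weekday = wd_v[idx],
    session = sess_v[idx],
    theatre = thea_v[idx],
    slot = sequence(n_book),
    surgical_class = ifelse(rev[idx], "revision", "primary"),
    arrival = day_v[idx] + .of$session_start[sess_v[idx]]
  )
  out
}

#' Realise one day's surgical bookings
#'
#' Applies the session rules to a simulation day: each morning/afternoon cell
#' books one revision (with the configured probability) or two primaries; each
#' evening cell books one primary. Bookings are returned in deterministic
#' priority order (session morning → afternoon → evening, theatre ascending,
#' slot ascending), the order used to break ties for beds. Day 0 is a Monday;
#' non-operating days return zero rows. Consumes the session RNG.
#'
#' @param template A [build_week_template()] result (its attached config is
#'   used), or a [schedule_config()].
#' @param day_index Simulation day (0-based).
#' @return A tibble with columns `day`, `weekday`, `session`, `theatre`,
#'   `slot`, `surgical_class`, `arrival` (continuous days).
#' @export
#' @examples
#' set.seed(1)
#' realise_daily_bookings(build_week_template(baseline_schedule()), 0)
realise_daily_bookings <- function(template, day_index) {
  config <- if (inherits(template, "schedule_config")) template
            else attr(template, "config")
  if (is.null(config)) stop("`template` carries no schedule config", call. = FALSE)
  stopifnot(length(day_index) == 1L, day_index >= 0)
  .bookings_for_days(config, as.integer(day_index))
}
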