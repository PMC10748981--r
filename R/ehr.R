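#' Sample procedure labels from the case mix
#'
#' Draws procedure labels from the within-class categorical distribution of a
#' [case_mix()].
#'
#' @param mix A `case_mix`.
#' @param surgical_class `"primary"` or `"revision"`.
#' @param n Number of draws.
#' @return Character vector of procedure labels.
#' @export
#' @examples
#' set.seed(1)
#' table(sample_procedure(case_mix(), "primary", 1000))
sample_procedure <- function(mix, surgical_class = c("primary", "revision"),
                             n = 1) {
  stopifnot(inherits(mix, "case_mix"))
  surgical_class <- match.arg(surgical_class)
  shares <- if (surgical_class == "primary") mix$within_primary else
    mix$within_revision
  sample(names(shares), n, replace = TRUE, prob = shares)
}

#' Generate synthetic EHR-like spell records
#'
#' Emulates spell-level electronic health records for the unit: each record has
#' a procedure label drawn from the case mix, a Bernoulli delayed-discharge
#' flag, and a length of stay drawn from the matching lognormal distribution
#' (delayed records draw their whole stay from the delayed distribution).
#' Entirely synthetic — no real patient data is involved.
#'
#' @param params A [model_params()].
#' @param n Number of records (>= 0).
#' @param seed Optional integer; when given, the draw is reproducible and the
#'   session RNG is left untouched.
#' @return A tibble with columns `patient_id`, `procedure`, `los_days`,
#'   `delayed` (logical).
#' @seealso [fit_los_parameters()] to recover parameters from such records,
#'   [synthetic_ehr_baseline()] for a fixed-size fixture with the baseline
#'   delayed count.
#' @export
#' @examples
#' generate_synthetic_ehr(baseline_params(), 5, seed = 1)
generate_synthetic_ehr <- function(params, n, seed = NULL) {
  stopifnot(inherits(params, "model_params"))
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != round(n)) {
    stop("`n` must be a single non-negative integer", call. = FALSE)
  }
  n <- as.integer(n)
  gen <- function() {
    if (n == 0L) {
      return(tibble::tibble(patient_id = character(), procedure = character(),
                            los_days = numeric(), delayed = logical()))
    }
    primary <- runif(n) < params$case_mix$primary_share
    procedure <- character(n)
    if (any(primary)) {
      procedure[primary] <- sample_procedure(params$case_mix, "primary",
                                             sum(primary))
    }
    if (any(!primary)) {
      procedure[!primary] <- sample_procedure(params$case_mix, "revision",
                                              sum(!primary))
    }
    delayed <- runif(n) < params$prop_delayed
    los <- .sample_spell_los(procedure, delayed, params)
    tibble::tibble(
      patient_id = sprintf("pt%06d", seq_len(n)),
      procedure = procedure,
      los_days = los,
      delayed = delayed
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# stays for a vector of records: delayed records from the delayed
# distribution, others from their procedure's distribution
.sample_spell_los <- function(procedure, delayed, params) {
  los <- numeric(length(procedure))
  dl <- lognormal_from_moments(params$delayed_los)
  if (any(delayed)) los[delayed] <- sample_los(dl, sum(delayed))
  for (p in unique(procedure[!delayed])) {
    idx <- !delayed & procedure == p
    los[idx] <- sample_los(lognormal_from_moments(params$los_specs[[p]]),
                           sum(idx))
  }
  los
}

#' Baseline-sized synthetic EHR fixture
#'
#' A synthetic cohort mirroring the baseline study population's counts: 6,912
#' spells of which exactly 529 are delayed discharges, so the delayed
#' proportion is exactly 529/6912 = 7.65%. Procedure labels and stays are
#' random under the baseline parameters.
#'
#' @param seed Integer seed (default 2016).
#' @return A tibble as from [generate_synthetic_ehr()].
#' @export
synthetic_ehr_baseline <- function(seed = 2016) {
  params <- baseline_params()
  n <- 6912L
  n_delayed <- 529L
  withr::with_seed(seed, {
    primary <- runif(n) < params$case_mix$primary_share
    procedure <- character(n)
    procedure[primary] <- sample_procedure(params$case_mix, "primary",
                                           sum(primary))
    procedure[!primary] <- sample_procedure(params$case_mix, "revision",
                                            sum(!primary))
    delayed <- seq_len(n) %in% sample.int(n, n_delayed)
    los <- .sample_spell_los(procedure, delayed, params)
    tibble::tibble(
      patient_id = sprintf("pt%06d", seq_len(n)),
      procedure = procedure,
      los_days = los,
      delayed = delayed
    )
  })
}

#' Fit model parameters from spell records
#'
#' Computes per-procedure sample mean/SD of length of stay among non-delayed
#' records, the delayed-stay mean/SD among delayed records, and the delayed
#' proportion as the fraction of all records flagged delayed. Delayed spells
#' are excluded from the per-procedure specifications because the simulation
#' draws a delayed patient's whole stay from the delayed distribution.
#'
#' @param records Data frame with columns `procedure`, `los_days`, `delayed`
#'   (as written by [write_ehr()]); every procedure label must be present among
#'   non-delayed records.
#' @param mix Case mix to carry into the result (the procedure mix is a
#'   scheduling input, not re-estimated from spells); defaults to [case_mix()].
#' @param delayed_fallback `los_spec` used (with a warning) when no delayed
#'   records exist; default is the baseline delayed distribution.
#' @return A [model_params()].
#' @export
#' @examples
#' recs <- generate_synthetic_ehr(baseline_params(), 2000, seed = 7)
#' fit_los_parameters(recs)
fit_los_parameters <- function(records, mix = case_mix(),
                               delayed_fallback = los_spec(16.5, 15.1)) {
  req <- c("procedure", "los_days", "delayed")
  if (!all(req %in% names(records))) {
    stop("`records` must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(records) == 0L) stop("`records` is empty", call. = FALSE)
  records$delayed <- as.logical(records$delayed)
  nd <- records[!records$delayed, ]
  missing <- setdiff(.of$procedures, unique(nd$procedure))
  if (length(missing)) {
    stop("no non-delayed records for procedure(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  specs <- lapply(.of$procedures, function(p) {
    x <- nd$los_days[nd$procedure == p]
    s <- if (length(x) > 1L) sd(x) else 0
    los_spec(mean(x), s)
  })
  names(specs) <- .of$procedures
  d <- records$los_days[records$delayed]
  if (length(d) == 0L) {
    warning("no delayed records; using fallback delayed length-of-stay spec",
            call. = FALSE)
    delayed_spec <- delayed_fallback
  } else {
    delayed_spec <- los_spec(mean(d), if (length(d) > 1L) sd(d) else 0)
  }
  model_params(los_specs = specs, delayed_los = delayed_spec,
               prop_delayed = mean(records$delayed), mix = mix)
}

#' Read and write spell records as CSV
#'
#' Plain UTF-8 comma-separated files with header
#' `patient_id,procedure,los_days,delayed`; `delayed` is stored as 0/1.
#'
#' @param path File path.
#' @return `read_ehr()` returns a tibble; `write_ehr()` returns `path`
#'   invisibly.
#' @export
read_ehr <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  req <- c("patient_id", "procedure", "los_days", "delayed")
  if (!all(req %in% names(df))) {
    stop(path, ": expected columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  df$delayed <- as.logical(as.integer(df$delayed))
  tibble::as_tibble(df)
}

#' @param records Data frame of spell records.
#' @rdname read_ehr
#' @export
write_ehr <- function(records, path) {
  out <- as.data.frame(records)
  out$delayed <- as.integer(as.logical(out$delayed))
  write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
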