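#' Surgical case mix
#'
#' The two-level case mix of an elective orthopaedic unit: the split between
#' primary and revision surgery, and the procedure mix within each class.
#' Defaults are the study baseline: 87% primary (p-THR 51%, p-TKR 38%,
#' p-UKR 11%) and 13% revision (r-THR 55%, r-TKR 45%).
#'
#' @param primary_share Probability that a patient is primary-class.
#' @param within_primary Named shares over `p-THR`, `p-TKR`, `p-UKR`; must sum
#'   to 1.
#' @param within_revision Named shares over `r-THR`, `r-TKR`; must sum to 1.
#' @return An object of class `case_mix`.
#' @export
#' @examples
#' case_mix()
case_mix <- function(primary_share = 0.87,
                     within_primary = c("p-THR" = 0.51, "p-TKR" = 0.38,
                                        "p-UKR" = 0.11),
                     within_revision = c("r-THR" = 0.55, "r-TKR" = 0.45)) {
  if (!is.numeric(primary_share) || length(primary_share) != 1L ||
      primary_share < 0 || primary_share > 1) {
    stop("`primary_share` must be a probability in [0, 1]", call. = FALSE)
  }
  check_shares <- function(x, labels, what) {
    if (is.null(names(x))) names(x) <- labels
    if (!setequal(names(x), labels)) {
      stop("`", what, "` must be named with: ", paste(labels, collapse = ", "),
           call. = FALSE)
    }
    x <- x[labels]
    if (any(x < 0) || any(x > 1) || abs(sum(x) - 1) > 1e-8) {
      stop("`", what, "` shares must lie in [0, 1] and sum to 1", call. = FALSE)
    }
    x
  }
  structure(list(
    primary_share = primary_share,
    revision_share = 1 - primary_share,
    within_primary = check_shares(within_primary, .of$primary_procedures,
                                  "within_primary"),
    within_revision = check_shares(within_revision, .of$revision_procedures,
                                   "within_revision")
  ), class = "case_mix")
}

#' @export
print.case_mix <- function(x, ...) {
  cat(sprintf("<case_mix> primary %.0f%% / revision %.0f%%\n",
              100 * x$primary_share, 100 * x$revision_share))
  cat("  within primary: ",
      paste(sprintf("%s %.0f%%", names(x$within_primary),
                    100 * x$within_primary), collapse = ", "), "\n", sep = "")
  cat("  within revision: ",
      paste(sprintf("%s %.0f%%", names(x$within_revision),
                    100 * x$within_revision), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Full stochastic input parameter set
#'
#' Bundles everything the simulation samples from: per-procedure length-of-stay
#' specifications, the delayed-discharge stay specification, the probability of
#' a delayed discharge, and the case mix.
#'
#' @param los_specs Named list of [los_spec()] objects covering all five
#'   procedure labels (see [procedure_labels()]).
#' @param delayed_los [los_spec()] for the total stay of delayed-discharge
#'   patients.
#' @param prop_delayed Probability that a patient's discharge is delayed.
#' @param mix A [case_mix()].
#' @return An object of class `model_params`.
#' @seealso [baseline_params()] for the packaged study values.
#' @export
model_params <- function(los_specs, delayed_los, prop_delayed, mix = case_mix()) {
  if (!is.list(los_specs) || !setequal(names(los_specs), .of$procedures)) {
    stop("`los_specs` must be a named list covering: ",
         paste(.of$procedures, collapse = ", "), call. = FALSE)
  }
  los_specs <- los_specs[.of$procedures]
  ok <- vapply(los_specs, inherits, logical(1), what = "los_spec")
  if (!all(ok)) stop("all `los_specs` entries must be `los_spec` objects",
                     call. = FALSE)
  if (!inherits(delayed_los, "los_spec")) {
    stop("`delayed_los` must be a `los_spec`", call. = FALSE)
  }
  if (!is.numeric(prop_delayed) || length(prop_delayed) != 1L ||
      prop_delayed < 0 || prop_delayed > 1) {
    stop("`prop_delayed` must be a probability in [0, 1]", call. = FALSE)
  }
  if (!inherits(mix, "case_mix")) stop("`mix` must be a `case_mix`",
                                       call. = FALSE)
  structure(list(los_specs = los_specs, delayed_los = delayed_los,
                 prop_delayed = as.numeric(prop_delayed), case_mix = mix),
            class = "model_params")
}

#' Baseline model parameters
#'
#' The unit's historical (2016–2019) parameters: lengths of stay in days
#' p-THR 4.4 (SD 2.9), p-TKR 4.7 (2.8), p-UKR 2.9 (2.1), r-THR 6.9 (7.0),
#' r-TKR 7.2 (7.6); delayed-discharge total stay 16.5 (15.1); 7.6% of patients
#' delayed; case mix per [case_mix()] defaults.
#'
#' @return A `model_params` object.
#' @export
#' @examples
#' baseline_params()
baseline_params <- function() {
  model_params(
    los_specs = list(
      "p-THR" = los_spec(4.4, 2.9),
      "p-TKR" = los_spec(4.7, 2.8),
      "p-UKR" = los_spec(2.9, 2.1),
      "r-THR" = los_spec(6.9, 7.0),
      "r-TKR" = los_spec(7.2, 7.6)
    ),
    delayed_los = los_spec(16.5, 15.1),
    prop_delayed = 0.076,
    mix = case_mix()
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n  length of stay (mean [sd] days):\n")
  for (p in names(x$los_specs)) {
    cat(sprintf("    %-6s %.1f [%.1f]\n", p,
                x$los_specs[[p]]$mean_days, x$los_specs[[p]]$sd_days))
  }
  cat(sprintf("  delayed discharge: %.1f [%.1f] days, proportion %.1f%%\n",
              x$delayed_los$mean_days, x$delayed_los$sd_days,
              100 * x$prop_delayed))
  print(x$case_mix)
  invisible(x)
}

# YAML keys use underscores (p_thr); internal labels use the clinical
# hyphenated form (p-THR).
.yaml_key <- function(label) tolower(gsub("-", "_", label))
.label_from_key <- function(key) {
  lab <- .of$procedures[.yaml_key(.of$procedures) == key]
  if (length(lab) != 1L) stop("unknown procedure key: ", key, call. = FALSE)
  lab
}

#' Read and write model parameters as YAML
#'
#' The YAML layout has top-level keys `los_specs` (one `{mean, sd}` pair per
#' procedure, keys `p_thr`, `p_tkr`, `p_ukr`, `r_thr`, `r_tkr`), `delayed_los`
#' (`{mean, sd}`), `prop_delayed`, and `case_mix` (`primary`, `within_primary`,
#' `within_revision`). A file with the baseline values ships with the package:
#' `system.file("extdata", "baseline_params.yaml", package = "orthoflow")`.
#'
#' @param path Path to a YAML file.
#' @return `read_model_params()` returns a `model_params`;
#'   `write_model_params()` returns `path` invisibly.
#' @export
#' @examples
#' read_model_params(system.file("extdata", "baseline_params.yaml",
#'                               package = "orthoflow"))
read_model_params <- function(path) {
  raw <- yaml::read_yaml(path)
  parse_model_params(raw, context = path)
}

# Build model_params from an already-parsed YAML list (shared with the
# experiment-config reader).
parse_model_params <- function(raw, context = "config") {
  need <- c("los_specs", "delayed_los", "prop_delayed", "case_mix")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop(context, ": missing parameter keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  specs <- lapply(raw$los_specs, function(s) los_spec(s$mean, s$sd))
  names(specs) <- vapply(names(raw$los_specs), .label_from_key, character(1))
  cm <- raw$case_mix
  wp <- unlist(cm$within_primary)
  names(wp) <- vapply(names(wp), .label_from_key, character(1))
  wr <- unlist(cm$within_revision)
  names(wr) <- vapply(names(wr), .label_from_key, character(1))
  model_params(
    los_specs = specs,
    delayed_los = los_spec(raw$delayed_los$mean, raw$delayed_los$sd),
    prop_delayed = raw$prop_delayed,
    mix = case_mix(primary_share = cm$primary, within_primary = wp,
                   within_revision = wr)
  )
}

#' @param params A `model_params` to serialise.
#' @rdname read_model_params
#' @export
write_model_params <- function(params, path) {
  stopifnot(inherits(params, "model_params"))
  specs <- lapply(params$los_specs, function(s) list(mean = s$mean_days,
                                                    sd = s$sd_days))
  names(specs) <- vapply(names(specs), .yaml_key, character(1))
  cm <- params$case_mix
  out <- list(
    los_specs = specs,
    delayed_los = list(mean = params$delayed_los$mean_days,
                       sd = params$delayed_los$sd_days),
    prop_delayed = params$prop_delayed,
    case_mix = list(
      primary = cm$primary_share,
      revision = cm$revision_share,
      within_primary = as.list(setNames(as.numeric(cm$within_primary),
                                        vapply(names(cm$within_primary),
                                               .yaml_key, character(1)))),
      within_revision = as.list(setNames(as.numeric(cm$within_revision),
                                         vapply(names(cm$within_revision),
                                                .yaml_key, character(1))))
    )
  )
  yaml::write_yaml(out, path)
  invisible(path)
}
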