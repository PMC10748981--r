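#' Route patients through delayed-discharge sampling
#'
#' For each patient, draws the delayed-discharge flag (Bernoulli with the
#' model's `prop_delayed`) and a total length of stay. Non-delayed patients
#' draw from their procedure's lognormal distribution with mean and SD scaled
#' by `los_multiplier`; delayed patients draw their *whole* stay from the
#' delayed distribution, which is never scaled — in productivity scenarios the
#' delayed-stay parameters remain at their baseline values.
#'
#' `delayed_mode = "add"` is an alternative interpretation in which the
#' delayed draw is added on top of the (scaled) procedure stay instead of
#' replacing it; the default replacement semantics reflect that the delayed
#' distribution was fitted on delayed patients' whole spells.
#'
#' Stays are produced by quantile transform (`qlnorm`) of the supplied (or
#' freshly drawn) uniforms, so matched uniforms give stays monotone in
#' `los_multiplier` — the basis of common-random-number scenario comparisons.
#'
#' @param procedure Character vector of procedure labels.
#' @param params A [model_params()].
#' @param los_multiplier Positive scale applied to procedure mean and SD.
#' @param delayed_mode `"replace"` (default) or `"add"`.
#' @param u_delay,u_los Optional uniform(0,1) vectors, one per patient, for the
#'   delay flag and the stay quantile; drawn from the session RNG when `NULL`.
#' @return A tibble with columns `delayed` (logical) and `los_days`.
#' @export
#' @examples
#' set.seed(1)
#' route_total_los(rep("p-THR", 5), baseline_params())
route_total_los <- function(procedure, params, los_multiplier = 1,
                            delayed_mode = c("replace", "add"),
                            u_delay = NULL, u_los = NULL) {
  stopifnot(inherits(params, "model_params"))
  delayed_mode <- match.arg(delayed_mode)
  if (!is.numeric(los_multiplier) || length(los_multiplier) != 1L ||
      los_multiplier <= 0) {
    stop("`los_multiplier` must be a single positive number", call. = FALSE)
  }
  unknown <- setdiff(unique(procedure), .of$procedures)
  if (length(unknown)) {
    stop("unknown procedure label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  n <- length(procedure)
  if (is.null(u_delay)) u_delay <- runif(n)
  if (is.null(u_los)) u_los <- runif(n)
  stopifnot(length(u_delay) == n, length(u_los) == n)

  delayed <- u_delay < params$prop_delayed
  los <- numeric(n)
  # per-procedure lognormal with scaled moments (sigma is invariant under a
  # common scaling of mean and SD; mu shifts by log(multiplier))
  for (p in unique(procedure)) {
    idx <- procedure == p
    spec <- params$los_specs[[p]]
    lp <- lognormal_from_moments(spec$mean_days * los_multiplier,
                                 spec$sd_days * los_multiplier)
    los[idx] <- qlnorm(u_los[idx], meanlog = lp$mu, sdlog = lp$sigma)
  }
  if (any(delayed)) {
    dl <- lognormal_from_moments(params$delayed_los)
    d_draw <- qlnorm(u_los[delayed], meanlog = dl$mu, sdlog = dl$sigma)
    if (delayed_mode == "replace") {
      los[delayed] <- d_draw
    } else {
      los[delayed] <- los[delayed] + d_draw
    }
  }
  tibble::tibble(delayed = delayed, los_days = los)
}
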