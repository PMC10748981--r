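#' Length-of-stay specification
#'
#' A length-of-stay distribution is specified by its mean and standard
#' deviation in days; sampling always uses a lognormal distribution with these
#' moments (see [lognormal_from_moments()]). `sd_days = 0` is allowed and gives
#' a degenerate (constant) stay.
#'
#' @param mean_days Mean stay in days; must be strictly positive.
#' @param sd_days Standard deviation of stay in days; must be non-negative.
#' @return An object of class `los_spec`.
#' @export
#' @examples
#' los_spec(4.4, 2.9)  # primary hip replacement, study baseline
los_spec <- function(mean_days, sd_days) {
  if (!is.numeric(mean_days) || length(mean_days) != 1L || !is.finite(mean_days) ||
      mean_days <= 0) {
    stop("`mean_days` must be a single positive number, got ",
         deparse(mean_days), call. = FALSE)
  }
  if (!is.numeric(sd_days) || length(sd_days) != 1L || !is.finite(sd_days) ||
      sd_days < 0) {
    stop("`sd_days` must be a single non-negative number, got ",
         deparse(sd_days), call. = FALSE)
  }
  structure(list(mean_days = as.numeric(mean_days),
                 sd_days = as.numeric(sd_days)),
            class = "los_spec")
}

#' @export
print.los_spec <- function(x, ...) {
  cat(sprintf("<los_spec> mean %.3g days, sd %.3g days\n", x$mean_days, x$sd_days))
  invisible(x)
}

#' Convert length-of-stay moments to lognormal parameters
#'
#' Moment matching: for a lognormal with log-scale parameters `mu`, `sigma`,
#' `sigma^2 = log(1 + (sd/mean)^2)` and `mu = log(mean) - sigma^2 / 2`, so the
#' returned distribution reproduces the requested mean and SD exactly.
#' An SD of zero yields `sigma = 0`, a point mass at the mean.
#'
#' @param mean_days Mean in days (> 0), or a `los_spec`.
#' @param sd_days SD in days (>= 0); ignored when `mean_days` is a `los_spec`.
#' @return An object of class `lognormal_params` with fields `mu` and `sigma`
#'   (log-days).
#' @seealso [moments_from_lognormal()] for the inverse, [sample_los()] to draw.
#' @export
#' @examples
#' lognormal_from_moments(4.4, 2.9)
lognormal_from_moments <- function(mean_days, sd_days = NULL) {
  if (inherits(mean_days, "los_spec")) {
    spec <- mean_days
  } else {
    spec <- los_spec(mean_days, sd_days)
  }
  sigma2 <- log1p((spec$sd_days / spec$mean_days)^2)
  structure(list(mu = log(spec$mean_days) - sigma2 / 2,
                 sigma = sqrt(sigma2)),
            class = "lognormal_params")
}

#' Recover mean/SD from lognormal parameters
#'
#' @param params A `lognormal_params` object.
#' @return A `los_spec` with the distribution's mean and SD in days.
#' @export
moments_from_lognormal <- function(params) {
  stopifnot(inherits(params, "lognormal_params"))
  m <- exp(params$mu + params$sigma^2 / 2)
  # expm1 keeps precision when sigma is tiny
  v <- expm1(params$sigma^2) * exp(2 * params$mu + params$sigma^2)
  los_spec(m, sqrt(v))
}

#' @export
print.lognormal_params <- function(x, ...) {
  cat(sprintf("<lognormal_params> mu %.4f, sigma %.4f (log-days)\n", x$mu, x$sigma))
  invisible(x)
}

#' Sample lengths of stay
#'
#' Draws from the lognormal distribution described by `params` (either
#' `lognormal_params` or a `los_spec`, which is converted by moment matching).
#' Consumes the session RNG; seed with [set.seed()] (or let
#' [run_replication()] manage seeding) for reproducibility.
#'
#' @param params `lognormal_params` or `los_spec`.
#' @param n Number of draws.
#' @return Numeric vector of `n` strictly positive stays in days.
#' @export
#' @examples
#' set.seed(1)
#' mean(sample_los(los_spec(4.4, 2.9), 1e4))
sample_los <- function(params, n = 1) {
  if (inherits(params, "los_spec")) params <- lognormal_from_moments(params)
  stopifnot(inherits(params, "lognormal_params"))
  rlnorm(n, meanlog = params$mu, sdlog = params$sigma)
}
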