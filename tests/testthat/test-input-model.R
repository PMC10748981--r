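test_that("moment matching reproduces closed-form parameters", {
  # p-THR: sigma^2 = log(1 + (2.9/4.4)^2), mu = log(4.4) - sigma^2/2
  lp <- lognormal_from_moments(4.4, 2.9)
  expect_equal(lp$mu, 1.3012, tolerance = 1e-4)
  expect_equal(lp$sigma, 0.6006, tolerance = 1e-4)
  # delayed discharge
  ld <- lognormal_from_moments(16.5, 15.1)
  expect_equal(ld$mu, 2.4991, tolerance = 1e-4)
  expect_equal(ld$sigma, 0.7800, tolerance = 1e-4)
  # degenerate: zero SD is a point mass at the mean
  l0 <- lognormal_from_moments(7.5, 0)
  expect_identical(l0$sigma, 0)
  expect_equal(l0$mu, log(7.5))
  expect_true(all(abs(sample_los(l0, 50) - 7.5) < 1e-9))
})

test_that("moment-matching round trip recovers mean and SD", {
  for (m in c(0.1, 1, 2.9, 4.4, 16.5, 120)) {
    for (s in c(0, 0.01, 1, 7.6, 15.1, 40)) {
      back <- moments_from_lognormal(lognormal_from_moments(m, s))
      expect_equal(back$mean_days, m, tolerance = 1e-9)
      expect_equal(back$sd_days, s, tolerance = 1e-9)
    }
  }
})

test_that("invalid length-of-stay specifications are rejected", {
  expect_error(los_spec(0, 1), "positive")
  expect_error(los_spec(-4.4, 2.9), "positive")
  expect_error(los_spec(4.4, -1), "non-negative")
  expect_error(lognormal_from_moments(0, 1), "positive")
})

test_that("large samples reproduce the specified moments", {
  n <- 1e5
  for (spec in list(c(4.4, 2.9), c(16.5, 15.1))) {
    set.seed(spec[1] * 100)
    x <- sample_los(los_spec(spec[1], spec[2]), n)
    expect_true(all(x > 0))
    se_mean <- spec[2] / sqrt(n)
    expect_lt(abs(mean(x) - spec[1]), 3 * se_mean)
    # SD check with a generous band (SE of the SD of a skewed lognormal)
    expect_equal(sd(x), spec[2], tolerance = 0.05)
  }
})

test_that("case mix validates shares and samples the right procedures", {
  expect_error(case_mix(primary_share = 1.2), "probability")
  expect_error(case_mix(within_primary = c("p-THR" = 0.7, "p-TKR" = 0.7,
                                           "p-UKR" = 0.1)), "sum to 1")
  mix <- case_mix()
  expect_equal(mix$primary_share + mix$revision_share, 1)

  only_thr <- case_mix(within_primary = c("p-THR" = 1, "p-TKR" = 0,
                                          "p-UKR" = 0))
  expect_true(all(sample_procedure(only_thr, "primary", 200) == "p-THR"))

  set.seed(11)
  prim <- sample_procedure(mix, "primary", 1e5)
  expect_equal(mean(prim == "p-THR"), 0.51, tolerance = 0.01)
  rev <- sample_procedure(mix, "revision", 1e5)
  expect_equal(mean(rev == "r-THR"), 0.55, tolerance = 0.01)
})

test_that("synthetic EHR generation honours n, seed and the case mix", {
  params <- baseline_params()
  expect_identical(nrow(generate_synthetic_ehr(params, 0)), 0L)
  expect_error(generate_synthetic_ehr(params, -1), "non-negative")

  a <- generate_synthetic_ehr(params, 500, seed = 99)
  b <- generate_synthetic_ehr(params, 500, seed = 99)
  expect_identical(a, b)

  big <- generate_synthetic_ehr(params, 1e5, seed = 7)
  primary <- big$procedure %in% c("p-THR", "p-TKR", "p-UKR")
  expect_equal(mean(primary), 0.87, tolerance = 0.01)
  # p-UKR share is the product of printed shares: 0.87 * 0.11
  expect_lt(abs(mean(big$procedure == "p-UKR") - 0.0957), 0.005)
  expect_lt(abs(mean(big$delayed) - 0.076), 0.003)
  expect_true(all(big$los_days > 0))
})

test_that("baseline-sized fixture has exactly 529 delayed of 6912 spells", {
  recs <- synthetic_ehr_baseline(seed = 5)
  expect_identical(nrow(recs), 6912L)
  expect_identical(sum(recs$delayed), 529L)
  fit <- fit_los_parameters(recs)
  expect_equal(fit$prop_delayed, 529 / 6912)
  expect_equal(fit$prop_delayed, 0.0765, tolerance = 1e-3)
})

test_that("fitting recovers parameters from self-generated records", {
  # tolerance per procedure: the nominal band (2% means / 5% SDs) widened to
  # 3 Monte-Carlo standard errors where the per-procedure sample is small
  # (rare revision procedures with heavy-tailed stays)
  params <- baseline_params()
  n <- 50000
  recs <- generate_synthetic_ehr(params, n, seed = 123)
  fit <- fit_los_parameters(recs)
  mix <- params$case_mix
  share <- c(mix$primary_share * mix$within_primary,
             mix$revision_share * mix$within_revision)
  for (p in procedure_labels()) {
    spec <- params$los_specs[[p]]
    n_p <- n * share[[p]] * (1 - params$prop_delayed)
    sigma2 <- log1p((spec$sd_days / spec$mean_days)^2)
    kurt <- exp(4 * sigma2) + 2 * exp(3 * sigma2) + 3 * exp(2 * sigma2) - 3
    se_mean <- spec$sd_days / sqrt(n_p)
    se_sd <- spec$sd_days * sqrt((kurt - 1) / (4 * n_p))
    expect_lt(abs(fit$los_specs[[p]]$mean_days - spec$mean_days),
              max(0.02 * spec$mean_days, 3 * se_mean))
    expect_lt(abs(fit$los_specs[[p]]$sd_days - spec$sd_days),
              max(0.05 * spec$sd_days, 3 * se_sd))
  }
  expect_equal(fit$delayed_los$mean_days, 16.5, tolerance = 0.05)
  expect_lt(abs(fit$prop_delayed - 0.076), 0.01)
})

test_that("fitting handles degenerate and incomplete record sets", {
  # all-identical p-THR spells, other procedures stubbed with one spell each
  stub <- tibble::tibble(
    patient_id = paste0("s", 1:4),
    procedure = c("p-TKR", "p-UKR", "r-THR", "r-TKR"),
    los_days = c(4, 3, 7, 7), delayed = FALSE
  )
  recs <- rbind(
    tibble::tibble(patient_id = paste0("a", 1:20), procedure = "p-THR",
                   los_days = 5.0, delayed = FALSE),
    stub
  )
  expect_warning(fit <- fit_los_parameters(recs), "fallback")
  expect_equal(fit$los_specs[["p-THR"]]$mean_days, 5.0)
  expect_identical(fit$los_specs[["p-THR"]]$sd_days, 0)
  expect_identical(fit$prop_delayed, 0)
  expect_equal(fit$delayed_los$mean_days, 16.5)  # fallback spec

  expect_error(fit_los_parameters(recs[recs$procedure != "p-UKR", ]),
               "p-UKR")
})

test_that("EHR records and model parameters round-trip through files", {
  dir <- withr::local_tempdir()
  recs <- generate_synthetic_ehr(baseline_params(), 50, seed = 1)
  path <- file.path(dir, "ehr.csv")
  write_ehr(recs, path)
  expect_equal(as.data.frame(read_ehr(path)), as.data.frame(recs))

  ypath <- file.path(dir, "params.yaml")
  write_model_params(baseline_params(), ypath)
  back <- read_model_params(ypath)
  expect_equal(back, baseline_params())

  shipped <- read_model_params(system.file("extdata", "baseline_params.yaml",
                                           package = "orthoflow"))
  expect_equal(shipped, baseline_params())
})
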