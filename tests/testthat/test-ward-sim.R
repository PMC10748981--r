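test_that("delayed-discharge routing has the specified semantics", {
  params <- baseline_params()

  never <- apply_multipliers(params, 1, 1e-9)  # prop effectively 0
  set.seed(1)
  r0 <- route_total_los(rep("p-THR", 1000), never)
  expect_false(any(r0$delayed))

  always <- model_params(params$los_specs, params$delayed_los,
                         prop_delayed = 1, mix = params$case_mix)
  set.seed(2)
  r1 <- route_total_los(rep("p-TKR", 1e5), always)
  expect_true(all(r1$delayed))
  expect_lt(abs(mean(r1$los_days) - 16.5), 3 * 15.1 / sqrt(1e5))

  # multiplier scales non-delayed stays: 0.25 x 4.4 = 1.1
  set.seed(3)
  r2 <- route_total_los(rep("p-THR", 1e5), never, los_multiplier = 0.25)
  expect_lt(abs(mean(r2$los_days) - 1.1), 3 * 0.725 / sqrt(1e5))

  # delayed stays never scale: identical draws under matched uniforms
  u1 <- rep(0.5, 100); u2 <- runif(100)
  a <- route_total_los(rep("p-THR", 100), always, los_multiplier = 1,
                       u_delay = u1, u_los = u2)
  b <- route_total_los(rep("p-THR", 100), always, los_multiplier = 0.25,
                       u_delay = u1, u_los = u2)
  expect_identical(a$los_days, b$los_days)

  expect_error(route_total_los("hip-resurfacing", params), "unknown procedure")
})

test_that("an empty schedule yields identically zero series", {
  sc <- scenario_config(10, schedule_config(n_theatres = 0))
  res <- run_replication(sc, baseline_params(), seed = 1, warmup_days = 2,
                         collect_days = 12)
  expect_true(all(res$daily$bookings == 0))
  expect_true(all(res$daily$occupancy == 0))
  expect_true(all(res$daily$lost_slots == 0))
  expect_identical(nrow(res$daily), 14L)
})

test_that("capacity-1 contention loses the second booking of a session", {
  # one theatre, morning session only: two primary bookings, one bed
  sched <- weekend_schedule(n_theatres = 1, sessions_per_day = 1,
                            revision_session_prob = 0)
  sc <- scenario_config(1, sched)
  res <- run_replication(sc, constant_params(los = 10), seed = 1,
                         warmup_days = 0, collect_days = 3)
  d0 <- res$daily[res$daily$day == 0, ]
  expect_identical(d0$bookings, 2L)
  expect_identical(d0$admissions, 1L)
  expect_identical(d0$lost_slots, 1L)
  expect_identical(d0$occupancy, 1L)
  # the bed stays blocked afterwards: every later slot is lost
  expect_true(all(res$daily$admissions[-1] == 0))
})

test_that("deterministic instance matches Little's law exactly", {
  # 5 bookings/day every day, stays of exactly 2 days, ample beds:
  # steady-state audited occupancy is L = lambda x W = 5 x 2 = 10
  sc <- scenario_config(20, deterministic_schedule())
  res <- run_replication(sc, constant_params(los = 2), seed = 1,
                         warmup_days = 7, collect_days = 28)
  collected <- res$daily[res$daily$day >= 7, ]
  expect_true(all(collected$occupancy == 10L))
  expect_true(all(collected$lost_slots == 0L))
  s <- summarise_replication(res)
  expect_identical(s$overall$utilisation, 0.5)
})

test_that("with ample beds no slot is lost and throughput equals bookings", {
  sc <- scenario_config(10000, baseline_schedule())
  res <- run_replication(sc, baseline_params(), seed = 42, warmup_days = 0,
                         collect_days = 56)
  expect_identical(sum(res$daily$lost_slots), 0L)
  expect_identical(res$daily$admissions, res$daily$bookings)
})

test_that("conservation and capacity invariants hold on every simulated day", {
  params <- baseline_params()
  for (seed in 1:4) {
    sc <- scenario_config(c(5, 20, 40, 70)[seed], baseline_schedule(),
                          los_multiplier = c(1, 0.25, 1, 0.25)[seed])
    res <- run_replication(sc, params, seed = seed, warmup_days = 7,
                           collect_days = 35)
    expect_true(all(res$daily$bookings ==
                      res$daily$admissions + res$daily$lost_slots))
    expect_true(all(res$daily$occupancy >= 0))
    expect_true(all(res$daily$occupancy <= sc$n_beds))
    # per-procedure throughput sums to total admissions
    thr <- res$throughput
    expect_identical(as.integer(rowSums(thr[, procedure_labels()])),
                     res$daily$admissions)
  }
})

test_that("replications are reproducible and substreams are spawned by rule", {
  sc <- scenario_config(40, baseline_schedule())
  params <- baseline_params()
  a <- run_replication(sc, params, seed = 7, warmup_days = 7, collect_days = 21)
  b <- run_replication(sc, params, seed = 7, warmup_days = 7, collect_days = 21)
  expect_identical(a$daily, b$daily)
  expect_identical(a$throughput, b$throughput)

  reps1 <- run_replications(sc, params, n_reps = 3, base_seed = 11,
                            warmup_days = 7, collect_days = 21)
  reps2 <- run_replications(sc, params, n_reps = 3, base_seed = 11,
                            warmup_days = 7, collect_days = 21)
  expect_identical(lapply(reps1, `[[`, "daily"),
                   lapply(reps2, `[[`, "daily"))

  # documented spawning rule: master seed, then sample.int
  first_seed <- withr::with_seed(11, sample.int(.Machine$integer.max - 1L, 3))[1]
  single <- run_replication(sc, params, seed = first_seed, warmup_days = 7,
                            collect_days = 21)
  expect_identical(reps1[[1]]$daily, single$daily)

  # replications genuinely differ
  occ_means <- vapply(reps1, function(r) mean(r$daily$occupancy), numeric(1))
  expect_gt(sd(occ_means), 0)
})

test_that("common random numbers give bed-monotone outcomes", {
  params <- baseline_params()
  for (rep_seed in c(101, 202, 303)) {
    thr <- c(); lost <- c()
    for (beds in c(10, 20, 30, 40)) {
      sc <- scenario_config(beds, baseline_schedule())
      res <- run_replication(sc, params, seed = rep_seed, warmup_days = 14,
                             collect_days = 56)
      keep <- res$daily$day >= 14
      thr <- c(thr, sum(res$daily$admissions[keep]))
      lost <- c(lost, sum(res$daily$lost_slots[keep]))
    }
    expect_true(all(diff(thr) >= 0))
    expect_true(all(diff(lost) <= 0))
  }
})

test_that("mean occupancy responds monotonically to the LOS multiplier", {
  params <- baseline_params()
  occ <- vapply(c(0.25, 0.5, 1), function(m) {
    sc <- scenario_config(200, baseline_schedule(), los_multiplier = m)
    res <- run_replication(sc, params, seed = 5, warmup_days = 14,
                           collect_days = 42)
    mean(res$daily$occupancy[res$daily$day >= 14])
  }, numeric(1))
  expect_true(all(diff(occ) > 0))
})

test_that("additive delayed-discharge mode lengthens delayed stays", {
  params <- baseline_params()
  sc <- scenario_config(500, baseline_schedule())
  rep_r <- run_replication(sc, params, seed = 9, warmup_days = 0,
                           collect_days = 84, delayed_mode = "replace")
  rep_a <- run_replication(sc, params, seed = 9, warmup_days = 0,
                           collect_days = 84, delayed_mode = "add")
  expect_gt(mean(rep_a$daily$occupancy), mean(rep_r$daily$occupancy))
})

test_that("invalid horizons are rejected", {
  sc <- scenario_config(10, baseline_schedule())
  expect_error(run_replication(sc, baseline_params(), 1, warmup_days = -1,
                               collect_days = 10), "horizon")
  expect_error(run_replication(sc, baseline_params(), 1, warmup_days = 10,
                               collect_days = 0), "horizon")
  expect_error(run_replications(sc, baseline_params(), n_reps = 0), ">= 1")
})
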