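# deterministic parameter set: every stay is a constant, no delayed discharges
constant_params <- function(los = 2, prop_delayed = 0,
                            delayed_mean = 16.5, delayed_sd = 0) {
  specs <- lapply(procedure_labels(), function(p) los_spec(los, 0))
  names(specs) <- procedure_labels()
  model_params(los_specs = specs,
               delayed_los = los_spec(delayed_mean, delayed_sd),
               prop_delayed = prop_delayed)
}

# one theatre, every day, all-primary sessions: exactly 5 bookings per day
# (2 + 2 + 1) at fixed session times
deterministic_schedule <- function(n_theatres = 1) {
  weekend_schedule(n_theatres = n_theatres, revision_session_prob = 0)
}

overall_stat <- function(stats, metric) {
  stats$mean[stats$metric == metric & stats$weekday == "overall"]
}
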