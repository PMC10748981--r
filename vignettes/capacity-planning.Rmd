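---
title: "Modelling ring-fenced elective orthopaedic capacity with orthoflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ring-fenced elective orthopaedic capacity with orthoflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthoflow)
```

## The system being modelled

orthoflow simulates an elective orthopaedic surgical unit whose ward beds are
*ring-fenced*: reserved for elective joint-replacement patients and protected
from emergency admissions. The unit's dynamics are driven entirely by its own
theatre schedule — demand is not an arrival process estimated from data but
the deterministic-plus-stochastic consequence of session booking rules, under
the standing assumption of an **infinite waiting list** (every theatre slot
can always be filled). The binding constraint is the interaction between
theatre activity and ward beds: a patient whose surgery is scheduled but for
whom no bed is free at the surgery instant loses the slot and leaves the
system. Lost slots are therefore the model's measure of demand–capacity
mismatch, alongside surgical throughput and per-weekday bed utilisation.

This is deliberately a high-level model. Patient attributes (age, frailty,
complexity) are not represented; their effect is carried entirely by the
length-of-stay distributions and the delayed-discharge mechanism. Real-world
mitigations of bed shortages — transfers to an acute site, bed-management
escalation, short-notice rebooking — are intentionally absent, so the lost-slot
series should be read as *pressure*, not as a literal prediction of cancelled
operations.

## Stochastic inputs

Five procedures are modelled, with baseline length-of-stay (LOS) means and
SDs in days fitted from historical spell records:

| procedure | mean | SD |
|---|---|---|
| p-THR (primary hip) | 4.4 | 2.9 |
| p-TKR (primary knee) | 4.7 | 2.8 |
| p-UKR (unicompartmental knee) | 2.9 | 2.1 |
| r-THR (revision hip) | 6.9 | 7.0 |
| r-TKR (revision knee) | 7.2 | 7.6 |

All stays are sampled from lognormal distributions because ward stays are
positive and right-skewed. Since the inputs are given as a mean and SD, the
lognormal is parameterised by **moment matching**:
$\sigma^2 = \ln(1 + (\mathrm{sd}/\mu)^2)$, $m = \ln\mu - \sigma^2/2$, which
reproduces the input moments exactly (`lognormal_from_moments()`, inverted by
`moments_from_lognormal()`; `expm1` is used in the inverse so the round trip
holds to ~1e-9 relative error even for tiny SDs). We chose moment matching
over fitting on log-spells because mean/SD pairs are the canonical interface:
they are what planners read off dashboards, and they keep the
fit → generate → refit pipeline closed. A zero SD is allowed and produces a
degenerate (constant) stay, which the deterministic test oracles exploit.

A proportion of patients (baseline 7.6%, the historical 529 of 6,912 spells)
are **delayed discharges**: medically fit but still occupying a bed. Routing
is Bernoulli per patient, and a delayed patient's *entire* stay is drawn from
a separate distribution (mean 16.5 d, SD 15.1 d). Replacement — rather than
adding a delay on top of the procedure stay — is an interpretation: the
delayed distribution was fitted on delayed patients' whole spells, so adding
it to a procedure stay would double-count the pre-fit portion. Because the
evidence for either reading is indirect, the additive variant is available
behind `delayed_mode = "add"` in `route_total_los()` and
`run_replication()`; the default everywhere is `"replace"`.

The case mix is two-level: 87% primary (51/38/11 within class) and 13%
revision (55/45). Within-class procedure labels are sampled per booking.

**Fitting from records.** `fit_los_parameters()` recovers all of the above
from spell-level records (procedure, LOS, delayed flag): per-procedure
mean/SD over *non-delayed* spells, delayed mean/SD over delayed spells, and
the delayed proportion as a simple fraction. Whether the historical
per-procedure parameters included delayed spells is not documented in the
source material; fitting on non-delayed spells is the choice consistent with
the replacement semantics above, and is flagged here as an interpretation.

## The theatre schedule and calibration

Each theatre runs up to three sessions per operating day, in fixed order
morning → afternoon → evening (nominal starts 09:00, 13:00, 17:00; only the
ordering matters at daily audit resolution). Morning and afternoon sessions
book **either one revision or two primaries**; the evening session books one
primary. The baseline schedule is 4 theatres, Monday–Friday; the
"baseline+weekend" variant keeps the same daily allocations over 7 days.

How a morning/afternoon session "chooses" revision or primaries is not part
of the rule set, so the package makes it a Bernoulli draw with probability
*p*, calibrated from the target revision share *s*: a theatre-day books
$5 - 2p$ patients of which $2p$ are revisions in expectation, so
$p = 5s/(2(1+s))$ (`revision_session_probability()`; `p ≈ 0.288` for the 13%
target, feasible only for $s \le 2/3$). This reproduces the observed case mix
without introducing a waiting-list model. The probability may be specified
per weekday to explore front-loading revisions early in the week; the default
is uniform.

Both patients of a two-primary session arrive at the session start; ties for
the last free bed are broken deterministically in (session, theatre index,
booking slot) order.

## The discrete-event engine

Because demand is schedule-driven and lost slots are terminal, a replication
factorises into (1) realising all bookings over the horizon, (2) sampling
every booked patient's procedure, delay flag and stay, and (3) a
deterministic chronological bed-allocation pass. Step 2 runs for *every*
booking, admitted or not, and stays are produced by quantile transform
(`qlnorm` of a per-patient uniform), which yields **common random numbers**
across scenarios: replications matched on seed consume identical randomness
regardless of bed count, and stays are monotone in the LOS multiplier. This
makes bed-sweep comparisons (throughput non-decreasing, lost slots
non-increasing in beds) hold replication-by-replication, which the test suite
checks across the 30–70 bed sweep.

Time is continuous in days; day 0 is a Monday. Occupancy is audited once per
day at 23:59; a discharge at exactly an arrival instant frees its bed first.
Same-day admit-and-discharge stays can be invisible to the audit — an accepted
discretisation, relevant mainly in deep low-LOS scenarios where sub-day stays
occur. Utilisation is day-level: each collection day contributes
occupancy/beds, then days are grouped by weekday and averaged; cross-
replication spread is reported as Tukey boxplot statistics (quartiles via
`quantile(type = 7)`).

**Run-length defaults** (all configurable): 42 warm-up days, 182 collection
days (26 weeks), 30 replications. The source material does not state its
values; these were fixed once, a priori, on the reasoning that the slowest
transient is set by delayed stays (mean 16.5 d), so six weeks comfortably
clears initialisation bias from an empty ward, 26 weeks gives every weekday
26 observations, and 30 replications is a conventional size for stable means
with heavy-tailed stays. The acceptance script and the headline tests use
exactly these sizes; deterministic oracle tests use shorter horizons.

**Seeding.** All stochastic functions consume the R session RNG;
`run_replication(seed=)` isolates itself with `withr::with_seed`.
`run_replications()` spawns one substream seed per replication by the
documented rule: `set.seed(base_seed)` then
`sample.int(.Machine$integer.max - 1, n_reps)`. Two scenario runs sharing a
`base_seed` are therefore matched replication-by-replication.

## Scenarios

`scenario_config()` holds one experiment cell: beds, schedule, a LOS
multiplier and a delayed-proportion multiplier. `apply_multipliers()` scales
every procedure's mean *and* SD (preserving the coefficient of variation and
hence the lognormal shape parameter — the least-informative choice given no
guidance on how variability shrinks as stays shorten), scales the delayed
proportion, and **never touches the delayed-stay distribution**, which stays
at baseline in all scenarios. The default grid crosses beds 30–70 (step 5),
the two schedules, and multipliers {1, 0.25} on both productivity axes — 72
cells, labelled with the grid vocabulary (`high_los`/`low_los`,
`prop_high`/`prop_low`).

A load-arithmetic orientation for reading results: the calibrated baseline
schedule books $4 \times (5 - 2p) \approx 17.7$ patients per operating day
and the case-mix mean stay is ~4.7 d (plus the delayed contribution), so the
5-day baseline's offered load is ~70 beds — the scale of the grid's upper
bed range — while the 0.25× LOS cells sit near 26–30 offered beds. Offered
load is an upper bound on what a 40-bed ward can show as mean occupancy;
simulated utilisation falls below it only through losses and audit effects.

## What the synthetic generator does and does not emulate

`generate_synthetic_ehr()` produces spell records (procedure, LOS, delayed
flag) by running the input model forward; `synthetic_ehr_baseline()` fixes
the cohort size at 6,912 with exactly 529 delayed spells so the historical
7.65% proportion is exactly representable. These records emulate the *joint
distribution the model assumes* — independent spells, exact lognormals,
delay independent of procedure. Real spell data would violate all three
(casemix drift, LOS tails beyond lognormal, delay correlated with
complexity). Passing the fit–generate closure tests therefore demonstrates
that the pipeline is self-consistent, not that the lognormal family or the
independence assumptions are right for any particular hospital; with real
records, `fit_los_parameters()` is only as good as those assumptions.

## Numerical and degenerate-input notes

- Moment matching and its inverse are exact in closed form; the inverse uses
  `expm1` to avoid cancellation at small $\sigma$.
- `sd = 0` specs, zero theatres, zero beds, empty schedules and `n = 0`
  generators all produce well-defined degenerate outputs (constant stays,
  empty templates, all-zero series) rather than errors; invalid values
  (negative SD, shares not summing to 1, scaled delayed proportion above 1,
  warm-up not shorter than the horizon) error immediately with named
  messages. An infeasible cell inside a grid run is reported and skipped
  while the rest of the grid completes.
- The bed allocator is an O(bookings × beds) pass over arrivals in priority
  order — small enough (≈3,700 bookings per 32-week replication) that a full
  72-cell grid at 30 replications runs in a few minutes on one core.

## Known limitations

No waiting-list or referral dynamics (infinite-list assumption); no
emergency outliers (the ring-fence is assumed perfect); no patient-reason
cancellations — only system-reason (no-bed) losses are modelled; no theatre-
time constraints beyond the session booking rules; five procedures only, so
day-case and complex spinal work are out of scope. Scenario multipliers act
uniformly across procedures; differential improvement (e.g. faster primaries
but unchanged revisions) requires editing the parameter set directly, which
`model_params()` supports.
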