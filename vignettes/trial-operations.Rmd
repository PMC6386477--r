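---
title: "Managing a double-blind trial's participants, randomization and drug supply"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Managing a double-blind trial's participants, randomization and drug supply}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialops)
```

`trialops` implements the operational machinery of a long phase-III
double-blind prevention trial in people with metabolic syndrome: screening,
two balanced randomizations, blinded kit allocation, an expiry-aware virtual
drug warehouse, order forecasting, and a savings analysis comparing the
on-demand supply policy against the conventional *patients' pack* policy.
This vignette explains the models and the design decisions; every number it
mentions is computed by the package's tests or examples, not asserted.

## The participant state machine

Each participant *is* a state. The protocol flow is

`REGISTERED → DIET_RANDOMIZED → RUN_IN → TREATMENT_RANDOMIZED →
SUPPLY_STEP_1 → SUPPLY_STEP_2 → MAINTENANCE → COMPLETED`

with `SCREEN_FAILED` reachable from screening and the run-in,
`BLOCKED` (non-compliance, serious adverse event) reachable from any active
state, and `WITHDRAWN` (consent withdrawal) reachable from any active state
including `BLOCKED`. `SCREEN_FAILED`, `WITHDRAWN` and `COMPLETED` are
terminal; whether a screen failure may re-enter is not specified by the
protocol materials we model, so we treat it as terminal. Non-compliance
detection is outside the system: `BLOCKED` is triggered by an external
event. Every transition appends exactly one audit event, and
`replay_states()` reconstructs the full roster from the log alone
(event-sourcing round trip), which `validate_store()` uses as its
consistency check.

Supply is gated entirely by state: `dispense()` refuses anyone who is
blocked, withdrawn, completed or not yet randomized, so a participant whose
progress is stopped consumes no further drug — that is the entire point of
the on-demand policy.

## Eligibility screening

Eligibility requires at least three of the five metabolic-syndrome
disorders, with inclusive thresholds exactly as the protocol prints them
("85 cm or more", "50 mg/dL or less"): waist ≥ 85 cm (women) / ≥ 100 cm
(men); fasting glycemia ≥ 100 mg/dL; triglycerides ≥ 150 mg/dL or treated;
HDL ≤ 50 (women) / ≤ 40 (men) mg/dL or treated for hypercholesterolemia;
blood pressure ≥ 130/85 mmHg or treated. The pressure criterion is read as
systolic ≥ 130 **or** diastolic ≥ 85, the standard ATP-III reading of
"130/85 or more". Exclusions: glycemia > 126 mg/dL in **two** repeated
samples (a single high value does not exclude), concomitant metformin,
cancer in the last five years (skin carcinomas exempt), creatinine
> 124 µmol/L, proteinuria, potassium-sparing diuretics or proton-pump
inhibitors, excessive alcohol. The five-year cancer window and "excessive
alcohol" have no operational definition in the source protocol, so they are
intake-time boolean flags, not recomputed from history; the diabetes
exclusion is subsumed by the two-sample rule plus the metformin flag.

## The two randomizations

**Diet** (blue = active lifestyle intervention, green = control) happens at
registration and balances sex and family membership: all members of a
family receive the proband's arm. **Treatment** (blinded labels X/Y)
unlocks only after a complete registration data set, satisfied eligibility
and a 30-day 500 mg metformin run-in with no adverse events; it balances
sex and age group ("up to 67" is inclusive, computed as floored whole years
at the randomization date).

The source system documents *which* factors are balanced but not the
algorithm, so the package uses deterministic marginal minimization: for
each candidate arm, sum the post-assignment absolute imbalances over the
declared margins and assign the arm with the smaller sum. For the diet
randomization the margins are the overall arm totals and the participant's
sex margin, weighted equally. Exact ties are broken deterministically on
the overall margin first and only then by a fair coin from the trial's
seeded stream. The deterministic tie-break is deliberate: with equal
weights and a pure coin the overall difference can drift to two, whereas
with the overall-margin tie-break one can show the proband blue–green
difference never exceeds one — which matches the published recruitment
table, whose proband arm totals differ by exactly one (806 vs 805). Per-sex
imbalance is *not* forced to one (the published table shows per-sex gaps up
to 22), which is expected when the overall margin shares the weight.

Familiars inherit the family arm and are excluded from the minimization
counters (they would otherwise bias the counts by family size), but they do
appear in the balance report, which mirrors the published
proband/familiar × arm × sex table. The family rule applies only to the
diet randomization; treatment randomization treats familiars independently.
Treatment minimization scores the sex and age margins and breaks ties on
overall label counts, keeping every margin's imbalance within the number of
random tie-breaks (asserted ≤ 2 over thousands of simulated arrivals).

## Blinding

Bottle codes are pre-generated in permuted blocks of four — two metformin,
two placebo, in one of the six possible orders drawn uniformly — so the
cumulative treatment ratio is exactly 1:1 after every whole block. The
clear code→treatment list exists in two places only: the manufacturer
export (bottle code and treatment, nothing else — the packaging instructions,
with no participant field in the schema) and the sealed in-database copy.
Which label (X or Y) means metformin is itself drawn once per trial from
the seeded stream, so the alias carries no information.

The sealed map is serialized and XOR-ed with a keystream derived from the
key and a per-trial salt, with an Adler-32 integrity check so a wrong key
fails loudly rather than yielding garbage. This is a keyed sealing with
integrity checking, adequate for enforcing the operational access path in a
single-process tool; a networked deployment should swap in vetted
authenticated encryption — the sealing function is isolated precisely so
that can be done in one place. Operational views return only code, block,
status and label; `break_blind()` is the sole decryption path, requires the
PI role, a non-empty reason and the key, and appends an audit event per
decryption (the test suite asserts decryptions = unblinding audit events,
and a string scan over all serialized operational outputs finds zero
treatment names).

## The virtual warehouse

One bottle holds 62 tablets of 850 mg metformin or placebo. The schedule:
step 1 is one bottle at one tablet/day (62 days ≈ two months); step 2 one
bottle at two tablets/day — 1700 mg/day — for 31 days; maintenance is a
six-month supply, 6 bottles at full dose or 3 at half dose (the PI may
halve the dose for poor tolerance or regression of the syndrome). All month
arithmetic uses a 31-day month, the convention implied by "62 tablets at
two per day covers one month". The 500 mg run-in product is a separate
open-label line tracked as 30-tablet units outside the blinded inventory.

Deliveries are registered with batch number, load date and expiry and must
carry at least twelve months of shelf life (31-day months, so 372 days;
configurable). Dispensing picks bottles of the participant's label
first-expire-first-out, under the guard that a bottle must outlive the
period the dispensation covers — the protocol only says drugs "close to
expiry" must not be assigned, and outliving the covered period is the
weakest guard that guarantees a participant never holds expired drug.
Stock that exists but fails the guard raises an expiry error, distinct from
a stockout. `dispose_expired()` retires expired stock permanently. FEFO is
therefore FEFO *among guard-eligible bottles*: a short-dated bottle may
remain in stock awaiting a shorter request or disposal, and the test
suite's independent replay checks exactly that formulation along with
conservation (generated = unloaded + in stock + dispensed + disposed).

Early re-supply for lost bottles is not implemented; it would be a
PI-authorized override and is left as an extension point.

## Order forecasting: (A + B1 + B2) − C

Orders are estimated as `(A + B1 + B2) − C`: `A`, bottles scheduled for
already-randomized active participants within the horizon (12 months by
default), computed by walking each participant's schedule at their current
dose; `B1`, bottles for projected future randomizations — the mean monthly
treatment-randomization count over a trailing 6-month window times the
horizon times the first-year bottle need per participant (14 bottles,
derived from the schedule itself); `B2`, one run-in unit per participant
currently between screening and randomization; `C`, the expected-withdrawal
discount, the drop-out rate (3.2%/year by default) applied to `A + B1`.
The formula gives only the combination; how each component is computed is
our reconstruction, every term is configurable, and `C` does not discount
`B2` (run-in product is already committed). The `A` component is tested for
exact equality against an independent day-stepping enumeration of every
scheduled dispensation.

Orders must go out at least 30 days before the last batch expires; the
supplier delivers within 60 days (the initial agreement also mentions a
30-day ordering term, so both lead times are separate configuration
fields). `order_trigger()` additionally projects demand over the delivery
lead plus the monthly review cadence plus the 30-day buffer, ordering early
enough that the delivery lands before the shelf empties.

## The savings analysis

The patients'-pack counterfactual assigns every consented code a full
mean-treatment allotment up front at one full-dose bottle per month,
discounted by the expected loss to follow-up; the one-bottle-per-month rate
is reconstructed from the published requirement (1755 × 36 × 0.95 rounds
to exactly the printed bottle count). Savings are
`100 × (pp − (dispensed + projected)) / pp`, reported to one decimal; the
budget saving is bottles saved × unit cost (4.00 Euro), reported raw and
rounded to the nearest thousand, matching how the source reports it.

## The simulator

`run_simulation()` drives every module end to end with no external data.
Defaults are the study conditions: 40 months of Poisson accrual at 44
consented/month (≈ 1755 consented), familiar fraction 144/1755, female
fraction 1061/1755, ages from a truncated normal (mean 56, sd 8, range
40–80, putting roughly a tenth of randomizations in the over-67 stratum),
screen-failure 0.32 and run-in adverse-event 0.10 — chosen once so that
about 60% of consented volunteers reach randomization, the published ratio
— 3.2%/year drop-out, 5%/year dose halving, 36 months of treatment,
48-month batch expiries (the supplier's stability tests extended expiry
from 12 to 48 months during the real trial) and a 4.00 Euro bottle.
Time advances in one-day ticks; accrual, drop-out and dose-reduction
hazards, disposal and order checks run on 31-day month boundaries.
Screening draws the failure outcome at the configured rate and synthesizes
a measurement record consistent with it, which is then pushed through the
real eligibility functions — the rules are exercised, but the covariate
*distributions* are placeholders, so passing tests validate the machinery,
not the epidemiology of any real cohort. The accrual calendar is likewise
synthetic (the real trial's month-by-month recruitment is unpublished), so
the simulator brackets the published dispensed/projected split rather than
reproducing it; the acceptance suite asserts the savings percentage lands
in a 20–40% band across a 20-seed battery rather than matching a point.

All randomness flows through the trial's private seeded stream, so a seed
reproduces a run exactly. Aggregates in a `sim_result` are recomputed from
the audit log, not from side tallies. For throughput the `trial` object is
an environment holding typed vectors (reference semantics, like the R6
pattern, but dependency-free): the test suites run hundreds of simulated
trials, including a battery at the full ~1,755-participant scale, inside a
few minutes on one CPU.

## Numerical and interface conventions

Dates are ISO-8601 at every file boundary and numeric days internally; all
store files are UTF-8 CSV/JSON/JSONL with deterministic column order, and
the sealed map is hex-encoded so a store bundle is plain text. Errors are
classed conditions (`trialops_state_error`, `trialops_auth_error`,
`trialops_gating_error`, `trialops_stockout_error`,
`trialops_expiry_error`, `trialops_validation_error`,
`trialops_lookup_error`); the CLI maps usage errors to exit 2 and domain
errors to exit 1. Bottle codes are zero-padded integers with a checksum
letter, but any unique string is accepted on import.

## Known limitations

The sealing scheme is not vetted cryptography (see above). The simulator's
covariates and accrual calendar are synthetic. Persistence is a
single-writer directory bundle — multi-user concurrency, web deployment,
email notification and regulatory-compliance claims of the original
deployment are out of scope. The annual anthropometric visit is modelled
only through the fields eligibility needs.
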