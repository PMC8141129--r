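---
title: "Methods: the HbA1c screening-interval microsimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the HbA1c screening-interval microsimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbscreen)
```

## The decision problem

How often should healthy adults be screened for type 2 diabetes with an
HbA1c test?  Frequent screening detects incident diabetes earlier —
treatment lowers complication and mortality risks — but each test costs
money, and imperfect specificity sends healthy people into follow-up care.
Because both the incidence of diabetes and the test's effective
characteristics vary strongly with age and adiposity, the economically
optimal interval differs across age × BMI strata.  `hbscreen` implements an
individual-level state-transition model of this trade-off for twelve strata
(age bands 30–44, 45–59, 60–74; BMI categories underweight, normal,
overweight, obese), evaluates screening strategies by discounted lifetime
cost and quality-adjusted life years (QALYs), and compares them by
incremental cost-effectiveness analysis at a willingness-to-pay (WTP)
threshold of $50,000/QALY.

A subtlety worth stating: the test's sensitivity and specificity here are
*interval-specific*.  The reference standard is progression to diabetes over
the screening interval, so a longer interval — more time for HbA1c to drift
upward — yields higher sensitivity.  Annual sensitivities in the built-in
preset are essentially zero (encoded as exactly 0): one year is too short
for the biomarker to separate incident cases from noise.

## States and cycle structure

Six health states, 1-year cycles:

| state | annual cost | utility | mortality RR |
|---|---|---|---|
| `HEALTHY` | 0 | 1 | 1 |
| `FALSE_POSITIVE` | 1,400 (follow-up) | 1 | 1 |
| `UNDETECTED_T2DM` | 0 | 0.785 | 2.61 |
| `TREATED_T2DM` | 3,500 | 0.785 | 1 |
| `COMPLICATION` | 8,000 | 0.638 | 5.22 |
| `DEAD` | 0 | 0 | — |

Within each cycle `t = 0, 1, 2, …` the engine applies, in order:

1. **Screening**, when `t %% interval == 0` and the individual is healthy,
   false positive, or undetected.  Undetected diabetes is detected with
   probability `sensitivity`; a healthy individual is flagged with
   probability `1 − specificity`; an existing false positive is
   re-classified as if healthy (reverting on a true-negative result).  The
   screening fee is charged to everyone screened.
2. **Incidence**: healthy or false-positive individuals develop diabetes
   with the stratum's annual incidence.  A false positive who develops
   diabetes becomes *undetected* — their old positive label predates the
   disease and is not a diagnosis.
3. **Complication**: undetected diabetes at the untreated annual rate
   (0.014); treated diabetes at that rate adjusted by the treatment relative
   risk (0.79) on the hazard scale.  The complication state is absorbing
   among the living and implies diagnosis: it accrues the treated
   complication fee regardless of how it was reached.
4. **Death**: the life-table `qx` at the current age, adjusted by the
   current state's mortality relative risk.
5. **Accrual**: the post-transition state's cost and utility for the cycle,
   both multiplied by `(1 + d)^(−t)` with `d = 0.02`.  No half-cycle
   correction is applied.

Events are sequential, so an incident case can progress to a complication
and die at the complication's relative risk within a single cycle.
Individuals leave the screening schedule on detection or complication;
simulation stops at death or age 110.

Two engines share this cycle definition exactly.  `run_microsim()` is the
first-order Monte Carlo engine (vectorized over individuals;
`simulate_individual()` is the scalar reference).  `run_cohort_expectation()`
propagates the full state distribution with per-age 6×6 transition matrices
and returns the *exact* expectation of the microsimulation — the test suite
leans on this equivalence, checking the two engines against each other
within Monte Carlo error and checking the cohort recursion against an
independent exhaustive path-enumeration oracle on short horizons.

## Relative risks act on the hazard scale

All relative risks adjust annual probabilities as `1 − (1 − q)^rr`
(`adjusted_mortality()`), not by multiplication.  With `rr = 5.22` and the
large `qx` of old age, `rr · qx` would exceed 1; the hazard-scale form stays
in `[0, 1]`, equals `q` at `rr = 1`, and approaches `rr · q` for small `q`
(the suite checks < 1% relative error when `rr · q < 0.01`).

## Entry age

Entry age is sampled uniformly over the stratum's integer ages (seeded),
the least-informative choice given that nothing more specific is published;
a fixed entry age can be set in the configuration (`settings.entry_age`),
and the deterministic engine averages over the same entry-age distribution
exactly.

## Parameters, point estimates, and published variants

The built-in preset (`preset_config()`) carries the published
parameterization: per-stratum interval/sensitivity/specificity triplets,
costs (screening 100; treatment 3,500 without and 8,000 with complication;
false-positive follow-up 1,400 USD/year), utilities (1 / 0.785 / 0.638 — the
complication utility is an aggregate over complication types weighted by
their reported proportions, a generic operation exposed as
`aggregate_utility()`), risks (complication rate 0.014/year, mortality RRs
5.22 / 2.61 / 1, treatment complication RR 0.79), and economic settings (2%
discount, $50,000/QALY WTP, 50,000 individuals, horizon age 110).

Three parameters have two published values each; the preset defaults to one
and exposes the other as an argument: screening cost 100 (alternate 80),
complication mortality RR 5.22 (alternate 5.61; `exp(1.65) = 5.21` supports
the default), treatment complication RR 0.79 (alternate 0.78).

The stratum-specific **annual incidence was never published**.
`preset_config()` deliberately refuses to run without one rather than invent
a value; `gen_incidence()` supplies a clearly-synthetic stand-in (below).

## Synthetic inputs: what they emulate and what they do not

Two inputs are generated because the originals are not public:

* **Background mortality** — `make_gompertz_lifetable()` builds a
  Gompertz–Makeham period table,
  `qx(age) = 1 − exp(−(c + a·e^{b·age}))`, defaults `a = 2e-5`, `b = 0.1`,
  `c = 5e-4`, terminal age 110.  These give a life expectancy at age 30 of
  ≈ 49 years — plausible for a high-income country, and the suite pins the
  45–60-year sanity band — but this is *not* the Japanese national table.
* **Incidence** — `gen_incidence()` is multiplicative on the ordinal
  stratum indices: `base · age_slope^a · bmi_slope^b`, defaults base 0.003,
  age slope 1.6, BMI slope 1.8, clipped to `[0, 0.5]`.  Direction (risk
  rises with age and BMI) is epidemiologically grounded; the magnitudes are
  a documented choice, not estimates.

Consequently, passing tests demonstrate that the *machinery* is correct —
engines agree, frontiers match oracles, distributions sample correctly —
not that absolute costs or QALYs reproduce any national setting.  The
published per-stratum outcome pairs are shipped separately
(`reference_outcomes()`) so the incremental-analysis layer can be validated
against them directly, independent of the unavailable inputs.  With those
rounded 2-decimal inputs, 10 of the 12 published recommended intervals
reproduce exactly; the other two cannot be recovered from the printed
precision (a decision-relevant QALY difference of ≈ 0.006 rounds to 0.01,
flipping one frontier ICER across the threshold) or are contradicted
between the published tables themselves, and the suite documents both.

## Incremental analysis

`build_cea_table()` sorts strategies by cost, marks strict dominance
(another strategy costs no more and yields no fewer QALYs, one strictly),
removes extended dominance (repeatedly dropping any interior strategy whose
ICER against the previous frontier point is ≥ the next point's ICER against
it, so frontier ICERs strictly increase — collinear points are dropped),
computes incremental cost/QALY/ICER between consecutive frontier
strategies, and recommends the highest-QALY frontier strategy whose ICER
chain stays within WTP.  `"dominant"` is reserved for a strategy that
weakly dominates every other.  Exact cost-and-QALY ties are both kept
(neither dominates; the ICER between them is undefined and skipped).  The
suite verifies the frontier against a brute-force oracle — the unique
maximizers of `λ·QALY − cost` over all candidate `λ` segments — and the
recommendation against argmax net monetary benefit (`wtp·QALY − cost`) on
random tie-free instances.

## Probabilistic sensitivity analysis

Parameters are sampled **independently** (only marginal distributions are
published): gamma for costs, lognormal for relative risks, beta for the
complication rate.  Sensitivities, specificities, utilities, and the
discount rate have no published distributions and are held fixed.  The
printed gamma parameters are mutually inconsistent with their point
estimates under any standard parameterization (e.g. shape 27.3 × scale 292
≫ 100); `check_psa_consistency()` detects such conflicts and
`sample_draw()` samples from method-of-moments re-centered versions (shape
kept, scale = point/shape), so the PSA is centered on the base case while
keeping the printed dispersion.  Draws outside a parameter's domain are
rejected and redrawn (error after 1,000 consecutive rejections).

Per draw, every strategy is re-evaluated either with the deterministic
cohort engine (default — isolates parameter uncertainty) or with the
microsimulation at a configurable cohort size (mirroring the published
1000 × 1000 two-level design, which conflates first- and second-order
noise).  `acceptability()` tallies, per WTP value, the fraction of draws in
which each strategy maximizes NMB (ties split equally); rows sum to 1 by
construction and the suite checks the tally against a brute-force loop.
`psa_summary()` reports the ICER of mean deltas — not the mean of per-draw
ratios, which is unstable when a QALY difference crosses zero — plus
empirical 2.5/97.5 percentile intervals.

## Numerical and reproducibility choices

* One global seed; per-stratum, per-strategy, and per-draw streams are
  derived with a Lehmer-style integer hash (`derive_seed()`), so units of
  work can run in any order with bit-identical results, and every report
  writes a manifest sufficient to reproduce its outputs.
* The cohort recursion's total state mass is tracked; its largest deviation
  from 1 is exposed as an attribute and held below 1e-12 in tests.
* Degenerate inputs are defined, not accidental: terminal `qx` is coerced
  to 1 on read (with a notice), `qx = 1` at entry yields zero QALYs and
  only the first screening fee, and a zero-risk, zero-discount cohort
  accrues exactly `max_age − entry_age` QALYs — all asserted exactly.
* Problem sizes in the shipped tests and acceptance script are scaled for a
  laptop-class single core: 20,000-individual microsimulations against the
  analytic engine, 1e5-draw moment checks, 300-draw cohort-mode PSAs.  The
  full published design (50,000 individuals; 1000 × 1000 PSA) runs through
  the same entry points by changing the size arguments.

## Known limitations

* One aggregate complication state (absorbing, no recovery), as in the
  published model; no complication subtypes, no indirect costs, no currency
  or price-year adjustment.
* Strata are fixed for life: no BMI migration or re-stratification by age.
* Treated individuals are assumed to reach background mortality
  (`rr_mort_treated = 1` by default) and exit screening permanently.
* Test outcomes are pure (sensitivity, specificity) Bernoulli draws; no
  HbA1c trajectory is modelled, so correlation between successive test
  results within a person is absent.
* Absolute results under synthetic life tables and incidence are
  illustrative; only the incremental layer is validated against published
  numbers.
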