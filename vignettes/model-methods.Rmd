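---
title: "Decision-analytic methods behind cytoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision-analytic methods behind cytoscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

cytoscreen implements a cost-utility model of one-off Cytosponge-TFF3
screening for Barrett esophagus (BE) in patients with gastro-esophageal
reflux disease (GERD), compared with usual care. This vignette is the
package's own account of the model: its structure and assumptions, the
parameters that matter, the choices made where the design was genuinely
open, and what the shipped tests do and do not demonstrate.

## The decision problem

GERD patients on long-term acid suppression carry an elevated risk of BE,
the precursor lesion of esophageal adenocarcinoma (EAC). Endoscopy for all
of them is infeasible; Cytosponge-TFF3 is a cheap, non-endoscopic triage
test whose positives are sent to confirmatory endoscopy. Detected BE can be
treated endoscopically before it becomes cancer. The economic question is
whether the up-front cost of one screening round (device, laboratory,
pathology, nurse time, confirmatory endoscopies) is justified by the
quality-adjusted life-years (QALYs) gained through earlier treatment.

## Model structure

The disease space has seven states: `NoBE`, `NDBE` (non-dysplastic BE),
`LGD`, `HGD` (low/high-grade dysplasia), `EarlyEAC` (curable, stage-1-like),
`LateEAC` (stage-4-like, palliative) and `Dead` (absorbing). Utilities are
defined for the six alive states. The model is a yearly-cycle Markov cohort
run from a starting age of 69 to an age cap of 100 — an explicit, bounded
realisation of a "lifetime" horizon; any cohort mass still alive at the cap
is reported as a censoring fraction rather than silently extrapolated.

Each arm of the comparison has two chains:

* **treatment chain** — patients whose disease was found (true positives
  confirmed by endoscopy). At model entry they receive the state-appropriate
  therapy: an endoscopic management episode for NDBE, endotherapy (EMR/RFA)
  for dysplasia, and a 50/50 split between an esophagectomy + chemotherapy
  pathway and endotherapy for early EAC. Treatment succeeds with a per-state
  probability; successes move to `NoBE`, failures stay in-state. Surgical
  patients face a 90-day post-esophagectomy mortality. One-off treatment
  costs and procedural disutilities are charged at entry.
* **natural-history chain** — everyone else, including false negatives.
  Disease progresses (and, for LGD, partially regresses) under annual
  transition probabilities with no intervention; early EAC progresses to
  late EAC, which carries high excess mortality and a one-off palliative
  cost at death.

After entry, all patients evolve under the same natural-history dynamics —
treatment in this model is a one-time reallocation of starting states, not
an ongoing programme. The comparison between arms is therefore driven
entirely by *who is detected at entry*: both arms carry identical per-state
disease totals (an invariant the package enforces), and only the split
between the chains differs.

### Cohort entry

Starting allocations are reconstructed from the trial-observed detection
counts (123 NDBE, 1 LGD, 3 HGD, 4 early EAC in the screened arm; 11.6 NDBE
and 4 early EAC found by symptomatic referral under usual care) and a
prevalence vector whose total is just under 9%. Fractional persons are
allowed throughout — the cohort is an expectation, and the published
starting table itself contains decimals. False positives (specificity 92.4%
among non-diseased attendees) incur screening and endoscopy costs but enter
the natural-history chain in `NoBE` with no treatment cost, so they affect
the cost side only through the endoscopy volume.

The screening scenario carries both the TFF3-positive referrals (221) and
the endoscopies actually attended (198). Uptake rescaling multiplies every
funnel count and the detected counts by the uptake ratio: at 50% uptake
this yields 3417 tests and about 457 referrals, consistent with proportional
scaling of the whole funnel.

### Cycle mechanics

* **Transition matrices** are age-specific: annual disease probabilities are
  composited with all-cause mortality from a packaged abridged life table
  (ages 50–100, overridable via configuration). Background death applies
  first; survivors face excess cancer mortality in the EAC states; disease
  moves among those who survive both. Every row sums to 1 to within 1e-12
  and `Dead` is absorbing.
* **Half-cycle correction** is trapezoidal and applies to state-occupancy
  quantities — QALYs, life-years and recurring costs — not to one-off entry
  costs (screening, treatment, palliative), which are event-timed.
* **Discounting** uses `1/(1+r)^t` with `t` whole cycles since entry and
  `r = 3.5%`/year; cycle-0 screening and treatment-entry costs are
  undiscounted.
* **Event ordering** within a cycle: transitions first, then accrual on
  corrected occupancy — the ordering consistent with the trapezoid.
* **EAC deaths** are the excess-mortality component `(1-q)·m` in the EAC
  states (deaths that would not have happened under background mortality
  alone); palliative care is charged exactly once per death from late EAC.
* Acid-suppressant (PPI/H2RA) drug costs accrue for all alive person-time
  by default — the modelled population is on long-term acid suppression by
  definition — with a configuration switch to restrict them to pre-cancer
  states.

## Parameters

All model inputs live in one registry (YAML settings plus CSV tables:
transitions, costs, utilities, disutilities, life table), each row carrying
value, optional low/high bounds, optional SD, a distribution family for the
probabilistic analysis, and a provenance tag (`paper-main-text`,
`paper-appendix`, `assumption`, `derived-calibration`). Nothing downstream
uses a numeric constant that is not in the registry; a test enforces this.

Key settings and their defaults:

| parameter | default | units | basis |
|---|---|---|---|
| start_age | 69 | years | trial median age |
| cohort_size | 6834 | persons/arm | trial intervention arm |
| discount_rate | 0.035 | /year | NICE reference case |
| age_cap | 100 | years | bounded lifetime horizon |
| wtp_threshold | 20000 | GBP/QALY | NICE threshold |
| sensitivity / specificity | 0.799 / 0.924 | — | accuracy study of the test |
| uptake | 1654/6834 | — | observed attendance |
| cytosponge_test | 258.82 | GBP/test | derived (below) |
| endoscopy_biopsy | 488 | GBP | printed usual-care total / 16 procedures |

The Cytosponge unit cost is never printed in the source material; it is
derived once as the value that makes 1654 tests plus 198 endoscopies at
£488 equal the printed screening total of £524,716 — £258.82, comfortably
inside the £144–£344 range explored in sensitivity analysis. It is shipped
with provenance `derived-calibration`.

### Calibration of appendix-sourced parameters

The natural-history transition probabilities, state utilities and several
unit costs were published only in an appendix that is not part of this
package's sources. They are shipped as *data, not code*, and were populated
by a one-off documented calibration: a numerical fit of the life table
(Gompertz `q(x) = exp(a + b·x)`), six transition probabilities, the NDBE
treatment success and the `NoBE`/`NDBE` utilities to the printed per-arm
outputs (usual-care QALYs, life-years, EAC deaths, the between-arm death
difference and the QALY/life-year increments), with weak log-scale priors
keeping rates near typical literature values; then a fit of the
acid-suppressant and endotherapy unit costs to the printed cost breakdown.
Survival, transitions and utilities were fitted jointly rather than
sequentially because QALYs are their product and the stages do not
separate cleanly; costs were fitted last, as they do not feed back into
the health outcomes.

Consequences worth knowing:

* The calibrated base case reproduces the headline results — incremental
  cost ≈ £82, incremental QALYs ≈ 0.015, ICER ≈ £5,500, usual-care EAC
  deaths ≈ 173, ~19 deaths averted — to within a few percent, as the
  acceptance script verifies at run time.
* The cumulative "start with or develop LGD/HGD" stage counts are *not*
  reproduced (the model produces substantially more dysplasia-years than
  the published table). The published stage counts are in internal tension
  with the published death counts under any single-pathway parameterisation
  we examined (177 ever-EAC and 173 EAC deaths cannot both follow from 151
  ever-HGD unless nearly all EAC bypasses HGD, which the near-equal LGD
  counts across arms contradict). We prioritised costs, QALYs and mortality
  — the quantities the cost-utility conclusions rest on — and document the
  stage counts as a known limitation.
* Calibrated transition values are provisional data: tests of structural
  properties (conservation, monotonicity, limits) deliberately do not
  depend on them.

## Sensitivity analysis

**Probabilistic (PSA).** 1000 draws by default. Each draw samples every
registry parameter that carries a distribution — beta for probabilities,
utilities and disutility decrements (moment-matched), gamma for costs —
and reruns both arms on the *common* draw, so parameter uncertainty that
affects both arms equally cancels in the increments, as it should. Default
dispersion is SD = 20% of the mean, matching the ±20% convention of the
one-way analysis; utilities carry explicit SDs of about 4–5% of the mean
in the data file, because a 20% SD on a utility near the ceiling of 1 is
not a credible elicitation and the dispersion of the published per-arm PSA
results corresponds to a few percent. Both choices are overridable per
parameter. The trial-observed detection counts are held fixed across
draws: they are data, not parameters. Outputs: the cost-effectiveness
plane, the acceptability curve (share of draws with positive net monetary
benefit, computed on a £0–£50,000 grid in £1,000 steps), the ratio-of-means
point ICER, and a percentile interval of per-draw ICERs in which draws with
negative increments are retained, so the interval can span negative
(cost-saving) values.

**Deterministic (DSA).** Every registry parameter is varied one at a time
to its explicit bounds where given (Cytosponge cost £144–£344, treatment
successes capped at 1) and ±20% of the base value otherwise, clamped to
the parameter's support. Four structural parameters rebuild the cohort
entry rather than just the Markov inputs: uptake (10–50%, proportional
funnel scaling), starting age (50–74, same allocation, different life-table
entry point), BE prevalence (4–12%, diseased totals and detected counts
scale together, `NoBE` absorbs the difference), and test sensitivity
(76.4–83.0%, detected counts scale with the capture ratio). Entries are
ranked by the width of the induced ICER range; in the shipped base case the
`NoBE`/`NDBE` utilities dominate the tornado, ahead of starting age,
prevalence, uptake and the Cytosponge unit cost, and the ICER is monotone
decreasing in prevalence and increasing in test cost — both directions are
enforced by tests over five-point sweeps.

## Synthetic trials

`generate_trial()` simulates the screening funnel person by person:
attendance ~ Bernoulli(uptake), true state ~ multinomial(prevalence), TFF3
positive with probability `sensitivity` if diseased else `1 − specificity`,
endoscopy attendance ~ Bernoulli, endoscopy itself perfect. An optional
repeat-test pathway re-administers an inadequate-sample fraction (base
311/1654) with a retest attendance of 202/311, reproducing the repeat-round
volumes in expectation. The generator emulates the *statistical* structure
the analysis assumes — independent Bernoulli/multinomial draws at the
stated rates. It does not emulate cluster randomisation, practice-level
effects, self-selection of attendees (the trial's attendees had a higher
disease yield than the funnel expectation), stage-specific test
sensitivity, or symptom-driven referral timing in the usual-care arm.
Passing tests on synthetic data therefore validate the pipeline's
arithmetic and the funnel-inversion prevalence estimator, not the clinical
realism of the trial itself.

`recover_prevalence()` inverts the funnel — detected / (attendees ×
sensitivity × endoscopy attendance) — with a delta-method binomial standard
error; a 200-replicate experiment in the test suite checks the estimator
is unbiased at the base-case operating point.

## Numerical choices and degenerate inputs

* Conservation of cohort mass is asserted each cycle to 1e-9 relative;
  row sums to 1e-12. Tiny negative occupancies from floating-point are
  clamped at zero; genuinely negative occupancy raises an error.
* A zero QALY increment returns an `NA` ICER with an explicit `"undefined"`
  status rather than a division error; cost-saving, health-gaining results
  are flagged `"dominant"` and never headlined as a negative ICER.
* Zero-count scenarios cost zero; a zero-invitee scenario with non-zero
  volumes is an error.
* Beta sampling truncates the variance just below the feasibility bound
  `m(1-m)`; parameters at the support boundary (0 or 1) are returned
  unchanged.
* The per-draw ICER interval requires at least two draws; degenerate
  (zero-dispersion) PSAs collapse to the base case exactly.

## Problem sizes

The shipped analyses use the cohort engine over 31 yearly cycles; 1000 PSA
draws; a 50,000-person microsimulation as an independent oracle for the
cohort engine (agreement required within 3 Monte-Carlo standard errors);
and 200 replicate synthetic trials for the prevalence-recovery experiment.
These sizes make every result deterministic given a seed and keep the full
test suite comfortably fast while leaving Monte-Carlo error well below the
tolerances being checked.

## Known limitations

* One screening round only; repeat screening programmes need
  post-screening incidence data the trial cannot yet provide.
* Two EAC stages only; stage-to-stage transition evidence is weak, and the
  shipped values are calibrated, not observed.
* The published cumulative stage counts are not reproduced (see
  calibration notes above).
* PSA draws are independent across parameters; no correlation structure,
  no value-of-information analysis.
* Whether treated NDBE receives active therapy or surveillance alone is
  not knowable from the main text; here NDBE "treatment" is a cheap
  management episode with a calibrated success probability, and its cost
  and success are both exposed to sensitivity analysis.
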