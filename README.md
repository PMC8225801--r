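# cytoscreen

Decision-analytic cost-utility modelling of one-off **Cytosponge-TFF3
screening for Barrett esophagus (BE)** in patients with gastro-esophageal
reflux disease (GERD), versus usual care.

Esophageal adenocarcinoma (EAC) is usually detected too late to cure. Its
precursor, BE, can be found by a swallowed cell-collection sponge coupled
with trefoil-factor-3 immunostaining — a cheap triage test administered in
primary care, with positives referred to confirmatory endoscopy and
endoscopically treatable disease treated before it becomes cancer. This
package is for health economists and screening researchers who want a
tested, reusable implementation of the full analysis pipeline around that
question: cohort entry from a screening funnel, a two-chain Markov cohort
model of BE natural history, incremental cost-effectiveness, probabilistic
and one-way sensitivity analysis, budget impact, and a synthetic-trial
generator for end-to-end validation.

## The model in brief

Seven health states — NoBE, NDBE, LGD, HGD, EarlyEAC, LateEAC, Dead — with
yearly cycles from age 69 to an age cap of 100, half-cycle correction, and
discounting at 3.5%/year. Each arm splits into a **treatment chain**
(endoscopy-confirmed detections, treated at entry; successes return to
NoBE) and a **natural-history chain** (everyone else, including the test's
false negatives), after which all patients share one set of age-specific
transition matrices built from annual disease probabilities composited
with life-table mortality.

Cost-effectiveness is summarised by the incremental cost-effectiveness
ratio and net monetary benefit,

    ICER = (C_int − C_usual) / (E_int − E_usual),    NMB = ΔE·λ − ΔC,

with per-person costs C in GBP, effects E in QALYs, and willingness-to-pay
λ = £20,000/QALY. The probabilistic sensitivity analysis re-runs both arms
on 1000 common parameter draws (beta for probabilities/utilities, gamma
for costs) and reports the cost-effectiveness plane, the acceptability
curve P(ΔE·λ − ΔC > 0), and a percentile ICER interval; the deterministic
analysis varies each parameter to its bounds and ranks the induced ICER
ranges as a tornado.

All parameters live in plain configuration files (YAML settings + CSV
tables with provenance tags); `base_case()` loads the packaged set that
reproduces the published base case. See the methods vignette
(`vignettes/model-methods.Rmd`) for the model's assumptions, the
calibration of appendix-sourced parameters, and known limitations.

## Worked example

```r
library(cytoscreen)
params <- base_case()
params
#> <cyto_params> Barrett esophagus screening model parameter set
#>   cohort: 6834 persons entering at age 69 (horizon to age 100)
#>   discount rate: 3.5%/yr, WTP threshold: £20,000/QALY
#>   Cytosponge-TFF3 sensitivity 79.9%, specificity 92.4%
#>   BE prevalence (all stages): 8.83%
#>   34 registered parameters (34 with PSA distributions)

res <- run_cea(params)
res$ce
#> <cyto_ce> incremental cost-effectiveness (per person)
#>   intervention: cost £565 (screen £76.78 + treat £489), 9.920 QALYs, 12.392 LYs
#>   usual care:   cost £483 (screen £1.14 + treat £482), 9.905 QALYs, 12.380 LYs
#>   increments: £82.28, 0.0150 QALYs, 0.0115 LYs
#>   ICER £5491/QALY; NMB £217 at £20,000/QALY

budget_impact(res$ce)
#> <cyto_budget>
#>   262,941 eligible patients x £82.28 incremental cost = £21,634,086 total
#>   £746,003 per year over 29 years
```

Reading the output: screening the cohort costs £76.78 per invited GERD
patient (1654 tests plus 198 confirmatory endoscopies); treating what is
found adds £7 per person over usual care but averts about 19 EAC deaths in
the 6834-person cohort, for 0.015 extra QALYs per person — an ICER of about
£5,500 per QALY, far below the £20,000 threshold. Rolling one screening
round out to the ~263k eligible GERD patients nationally would cost about
£21.6M, ≈ £746k per year spread over 29 years.

Sensitivity analyses:

```r
psa <- run_psa(params, psa_config(n_draws = 1000, seed = 1))
ceac(psa, 20000)        # probability cost-effective at £20k/QALY (> 0.9)
icer_interval(psa, 0.95)
dsa <- run_dsa(params)  # tornado-ordered one-way analysis
plot_ceac(psa); plot_tornado(dsa)   # optional ggplot2 renderings
```

Report commands (`cmd_base()`, `cmd_psa()`, `cmd_dsa()`, `cmd_budget()`,
`cmd_scenario()`, `cmd_synth()`) write the corresponding CSV tables plus a
run manifest; `inst/scripts/cytoscreen` wraps them as shell subcommands.

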