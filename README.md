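# smicea

Lifetime cost-effectiveness modelling of tailored smoking-cessation
interventions for people with severe mental illness (SMI), from a UK
healthcare perspective.

People with SMI (schizophrenia, bipolar disorder, psychosis, severe PTSD)
smoke at far higher rates than the general population, carry roughly
double the mortality risk, and engage poorly with standard stop-smoking
services. Tailored interventions — behavioural support delivered by mental
health practitioners alongside pharmacotherapy — raise 12-month quit
rates but cost more to deliver. This package asks whether that extra
spend is good value: it estimates lifetime costs (GBP 2018/19) and
quality-adjusted life years (QALYs) for two comparisons, a bespoke
smoking-cessation intervention (BSCI) versus usual care, and integrated
tobacco-and-mental-health care (IC) versus standard smoking-cessation
clinic (SCC) referral.

## The model

A three-state annual-cycle Markov cohort: **current smoker**, **former
smoker**, **dead** (absorbing). The cohort enters entirely as current
smokers; the intervention determines the probability of being a former
smoker at 12 months; thereafter a net annual cessation probability
(2%/year) moves current to former smokers and relapse is 0% in the base
case (relapse is folded into the net rate). Death probabilities come from
an age x sex x smoking-status life table multiplied by the SMI relative
mortality risk (RR = 2.22).

Costs and utilities accrue from six smoking-related comorbidities
(asthma, COPD, CHD, lung cancer, MI, stroke) through their age-, sex- and
status-specific prevalence. SMI-specific adjustments:

* comorbidity prevalence is scaled by converting the SMI odds ratio
  (OR = 3.1) to a relative risk at each cell's baseline prevalence,
  `RR = OR / (1 - p + p*OR)` (asthma exempt);
* a weighted mental-health disutility of 0.125 (mood 0.196 x 38.8%,
  anxiety 0.043 x 51.6%, substance misuse 0.278 x 9.6%) is subtracted
  from every live state's utility.

Cohorts are run for every starting age 12–100 and both sexes, combined
with population age weights, and discounted at 3.5%/year. Decisions use
the incremental cost-effectiveness ratio ICER = ΔC/ΔQ against a
£20,000/QALY threshold, with net monetary benefit NMB = λ·ΔQ − ΔC and
explicit dominance labels. Uncertainty is handled by one-way
deterministic sensitivity analysis (95% CI bounds), three scenario
analyses (self-reported quitting; service-utilisation costs; 4.1%
cessation with 10% relapse), and a 3000-iteration probabilistic
sensitivity analysis with moment-matched distributions (log-normal
relative risks, beta probabilities/utilities, gamma costs) and
cost-effectiveness acceptability curves.

The external reference surfaces (life tables, prevalence, population
weights) are generated synthetically in-package with the qualitative
structure the model assumes — mortality and prevalence increasing with
age and higher for current than former smokers — and can be replaced by
real data via `read_surfaces()`.

## Worked example

```r
library(smicea)
pset     <- build_parameter_set()          # Tables of effectiveness, costs, utilities
surfaces <- make_reference_surfaces(seed = 1)

run_comparison(pset, surfaces, "bsci_vs_uc")
#> <ce_result> bsci vs usual_care
#>   dCost £258 (intervention £485, comorbidity £-227); dQALY 0.062
#>   ICER £4192/QALY; NMB £975 at £20,000/QALY; cost-effective: TRUE

run_comparison(pset, surfaces, "ic_vs_scc")
#> <ce_result> integrated_care vs scc_referral
#>   dCost £366 (intervention £551, comorbidity £-185); dQALY 0.050
#>   ICER £7293/QALY; NMB £638 at £20,000/QALY; cost-effective: TRUE
```

Reading: the BSCI costs £485 more per person to deliver than usual care
but saves £227 of lifetime comorbidity treatment costs, for a net £258;
it buys 0.062 discounted QALYs, so each QALY costs £4,192 — well under
the £20,000 threshold, hence cost-effective. `run_scenario()` gives the
scenario variants, `run_dsa()` the tornado table and `run_psa()` the
probabilistic analysis; `run_full_evaluation()` orchestrates all of them
and writes CSV outputs plus a reproducibility manifest.

The analysis itself lives in numbered drivers under `analysis/`
(01 reference surfaces → 02 base case → 03 scenarios → 04 one-way
sensitivity → 05 PSA), each writing its tables under `results/`.

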