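---
title: "Model structure, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smicea)
```

## The decision problem

Current smokers with severe mental illness (SMI) making a quit attempt
can be offered either standard stop-smoking support or an intervention
tailored to their mental-health needs. Tailored care costs more to
deliver; quitting earlier reduces lifetime exposure to smoking-related
disease. The package weighs these against each other over a lifetime
horizon from a UK healthcare (NHS + personal social services)
perspective, in GBP 2018/19, for two pairwise comparisons: a bespoke
smoking-cessation intervention (BSCI) against usual care, and integrated
tobacco-and-mental-health care (IC) against referral to a standard
smoking-cessation clinic (SCC).

## Cohort model

Three states: current smoker, former smoker, dead (absorbing). Cycles
are annual. A cohort enters at a single starting age, 100% current
smokers. The model's timing conventions:

* **Cycle 0 (the intervention year).** Everyone accrues current-smoker
  costs and utility plus the arm's full intervention delivery cost,
  undiscounted. The quit split materialises at the 12-month boundary:
  the transition into cycle 1 uses the arm's 12-month quit probability.
* **Later cycles.** Transitions use the net annual cessation probability
  (2%, which already nets out relapse and uptake at the population
  level) and an explicit relapse probability (0% in the base case).
  These are population book-keeping rates, not individual trajectories:
  the cohort average is what the model tracks.
* **Death competes first.** With annual death probability $d$ at the
  attained age, the behavioural transition applies conditional on
  survival, e.g. current→former is $(1-d)\,q$. This keeps each row of
  the transition matrix exactly stochastic without renormalisation; it
  is the standard conditioning order in cohort models, adopted here as a
  design choice since nothing in the source material fixes it.
* **No half-cycle correction.** Costs and QALYs accrue for the full year
  at each cycle's opening occupancy.
* **Age indexing.** A cohort starting at age $a$ is aged $a+t$ in cycle
  $t$; mortality, prevalence, costs and utilities are looked up at the
  attained age. Age 100 is absorbing-by-death: the synthetic life table
  forces $q(100)=1$, and in any case no accrual happens past age 100.

Death probabilities are life-table values by age, sex and smoking status
multiplied by the SMI relative mortality risk (2.22, SD 0.02) and capped
at 1. Only the current- and former-smoker series are ever occupied; the
never-smoker series is generated for completeness but unused.
A single former-smoker mortality rate per age is used — mortality does
not decay toward never-smoker rates with abstinence duration, since no
such gradient is available for this population.

### Costs and utilities

Six comorbidities drive both: asthma, COPD, coronary heart disease, lung
cancer, myocardial infarction, stroke. Annual state cost is the
prevalence-weighted sum of per-cycle condition costs. State utility is

$$u = \mathrm{clamp}\big(\,u_\text{base} - \delta_\text{status}
  - \delta_\text{SMI} - \textstyle\sum_c p_c\,(u_\text{base} - u_c),\ 0,\ 1\big)$$

with base non-smoker utility 0.88, status decrements 0.04 (current) and
0.02 (former), and the SMI decrement 0.125. The additive-decrement
combination (rather than multiplicative) is a design choice: the
inherited general-population structure is not published, and with no
joint-prevalence data the comorbidity decrements are summed without
interaction. Utilities are clamped to $[0,1]$ after combination. The
dead state contributes zero cost and utility.

The SMI decrement is derived as a population-weighted average of
condition-specific decrements (mood disorder 0.196 at 38.8%, anxiety
0.043 at 51.6%, substance misuse 0.278 at 9.6%), giving 0.125 — the
value also used as the sampling mean (one printed source rounds it to
0.13; the derived 0.125 is taken as canonical, SD 0.013).

### SMI comorbidity adjustment

SMI raises the odds of smoking-related chronic disease (OR 3.10, SD
0.29). Odds ratios do not multiply prevalences safely, so each cell's OR
is first converted to a relative risk at that cell's general-population
prevalence, $RR = OR/(1 - p + p\,OR)$, then applied:
$p' = \min(1,\ p \cdot RR)$. Asthma is exempt (its exacerbation-based
definition does not match the chronic-disease evidence), so it stays at
general-population rates. The conversion guarantees $p'$ is monotone in
$p$, preserves the current ≥ former ordering, and never exceeds 1.

### Aggregation and economics

Lifetime discounted costs and QALYs are computed for every starting age
12–100 and both sexes (178 cohorts, up to 89 cycles each), then averaged
with population age/sex weights. Both costs and QALYs are discounted at
3.5% per year, cycle 0 undiscounted. The decision statistics are
ICER = ΔC/ΔQ, net monetary benefit $\lambda\Delta Q - \Delta C$ at
$\lambda = \pounds20{,}000$/QALY, and dominance labels. Edge handling
(never exercised on the shipped inputs, but defined): ΔQ = 0 with ΔC > 0
is *dominated*, with ΔC < 0 *dominant*, both zero *equivalent*; the
south-west quadrant (cheaper and worse) reports the ratio with an
explicit quadrant tag because a bare ratio is sign-ambiguous there. The
cost-effective flag is exactly NMB > 0, which coincides with "dominant
or ICER below threshold" everywhere except the measure-zero boundary.

## Synthetic reference surfaces

The life table, prevalence surfaces and population weights the model
consumes are national-statistics-style reference data that are not
shipped with the package; instead a generator produces synthetic
stand-ins with the structure the model relies on, and real data can be
dropped in as long-format CSV (`read_surfaces()`).

* **Mortality**: Gompertz, $q = \min(1, a e^{b\,\text{age}})$ times
  status multipliers (current 1.9, former 1.35, never 1.0), with
  $a \approx 1.4\text{–}2.0 \times 10^{-5}$ and $b \approx 0.0925$.
  Two-parameter exponential ageing keeps the curve monotone and easy to
  reason about.
* **Prevalence**: per-condition logistic curves in age with a
  former-smoker attenuation of 0.6 and a 10% male uplift; asymptotes
  range from 0.045 (lung cancer) to 0.34 (COPD).
* **Weights**: a smooth unimodal age profile (Gaussian, peak ≈ 41,
  width 21), split evenly by sex, normalised to 1; a uniform option
  exists for testing.

Seeds perturb the generator parameters slightly (within a few percent)
so that different seeds give different but structurally valid surfaces,
and the same seed is bit-reproducible. Defaults were calibrated once so
that population-average lifetime discounted QALYs land around 11–12 per
person and lifetime comorbidity costs around £20k — the order of
magnitude at which the downstream directional checks (QALY gains,
partial cost offsets, scenario orderings) are meaningful. The surfaces
emulate the *shape* of real reference data, not its values: passing
tests demonstrate that the machinery is correct and that the qualitative
cost-effectiveness pattern is robust on structurally realistic inputs,
not that any specific published ICER is reproduced. Results on real
life tables and survey prevalence will differ numerically.

Scenario 2's service-utilisation add-on costs per arm (BSCI £7,903,
usual care £8,667, IC £18,091, SCC £18,941) are differences of printed
cost totals; scenario 1's self-reported effectiveness inputs are not
published, so the shipped file is a clearly labelled synthetic
placeholder preserving the qualitative pattern (higher rates, larger
increments) and should be replaced via
`config$selfreport_effectiveness` when real values are available.

## Uncertainty analyses

**PSA.** Every parameter with a reported SD gets a moment-matched
distribution: log-normal for relative risks ($\sigma^2 = \ln(1 +
sd^2/m^2)$, $\mu = \ln m - \sigma^2/2$), beta for probabilities and
utilities ($\nu = m(1-m)/sd^2 - 1$), gamma for costs ($k = m^2/sd^2$,
$\theta = sd^2/m$); SD 0 gives a point mass. Method-of-moments is the
conventional parameterisation in health-economic PSA and inverts the
reported moments exactly in closed form. Utility decrements are sampled
as beta magnitudes and applied negatively, keeping the stated family
while respecting sign. Effectiveness is sampled per arm independently on
the probability scale (no published correlation structure or log-odds
specification); all shared parameters are drawn once per iteration, so
they act as common random numbers across arms. The PSA runs a fixed
3000 iterations — stability is reported rather than adaptive, via the
running-mean ICER trace — and outputs the probabilistic ICER as the
ratio of mean increments (not the mean of ratios), the probability of
positive NMB at the threshold, and the CEAC over £0–£50,000.

**One-way DSA.** Each parameter moves to mean ± 1.96 SD (constructed on
the log scale for log-normal parameters, clamped to the family's
support), everything else at the mean; shared parameters move in both
arms simultaneously, effectiveness one arm at a time. Bars are ranked by
ICER range; a bound that flips the comparison into dominance is reported
as a label, never as a negative ICER.

**Scenarios.** (1) self-reported + validated quitting; (2)
service-utilisation add-ons folded into cycle-0 intervention costs; (3)
bidirectional post-12-month rates, cessation 4.1% and relapse 10%,
replacing the net rates from the second transition onward. The cessation
rate is configurable because two printed figures disagree (4.1% in text,
4.4% in a table footnote); 0.041 is the default. A restricted 5-year
horizon variant truncates accrual after five cycles. Because the 10%
relapse applies to all former smokers regardless of abstinence duration,
scenario 3 overstates relapse for long-abstinent quitters and its ICER
should be read as pessimistic.

## Numerical and testing notes

* The engine is vectorised over starting ages (a few thousand vector
  operations per arm evaluation), which keeps a full 3000-iteration PSA
  for both arms of a comparison around a minute on one CPU; a
  per-cohort reference implementation (`run_cohort`) produces full
  traces and is tested to agree with the vectorised path to 1e-10, and
  with an explicit matrix-power evaluation of the chain on random
  parameterisations.
* Problem sizes used in the shipped analyses: 178 cohorts × ≤89 cycles
  deterministic; 3000 PSA iterations per comparison; 10^5-draw
  round-trip checks on the sampling distributions.
* Degenerate inputs are defined, not accidental: SD 0 parameters sample
  exactly at the mean; an all-degenerate PSA reproduces the
  deterministic result bit-for-bit; certain death at entry reduces the
  trace to cycle-0 accruals; OR = 1 and RR = 1 and SMI disutility 0
  collapse the SMI adjustments to the general-population structure.
* Printed intervention cost totals differ from their component sums by
  up to £7 (rounding in the sources); totals are canonical and the
  loader enforces the ±£7 tolerance.
* Known limitations: no time-since-quit gradients in mortality or
  relapse; only six comorbidities; additive utility decrements; no
  correlation between sampled parameters; cohort averages rather than
  individual trajectories.
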