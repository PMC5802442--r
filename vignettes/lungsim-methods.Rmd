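---
title: "Model and methods: a population-level lung cancer screening microsimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: a population-level lung cancer screening microsimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`lungsim` estimates the population-level benefits and harms of annual
low-dose CT lung cancer screening under the CMS eligibility criteria for a
multi-birth-cohort population whose smoking prevalence declines across
cohorts. This vignette documents the model structure, the default
parameterization and why each piece looks the way it does, the coupling
architecture that makes the counterfactual comparison exact, and the known
limitations of what the simulator can and cannot say.

## Why multiple birth cohorts

Single-birth-cohort screening analyses follow one cohort (typically one with
high smoking prevalence) and therefore estimate the benefit of screening at
its historical maximum. A population-level estimate must instead mix cohorts:
as older, heavier-smoking cohorts age out of the screening-eligible window
(ages 55–77) they are replaced by cohorts that smoke less, so the eligible
fraction of the population — and with it the achievable mortality reduction —
falls over the projection horizon. That replacement dynamic is the central
mechanism of this package. The default configuration follows everyone aged
30–84 at any point in 2016–2030, i.e. birth cohorts 1932–2000.

## Population and smoking histories

Each simulated person carries a birth year, sex, and a smoking history
(initiation age, constant cigarettes-per-day intensity, cessation age).
Cohort sizes grow geometrically at `cohort_growth_rate` (default 0.5%/year);
the metric layer is scale-invariant, so no census ingestion is attempted.

Ever-smoking initiation is logistic in birth year, per sex:

$$p(\text{by}, s) = \operatorname{logit}^{-1}\!\big(\operatorname{logit}(p_{1950,s}) + \beta_t\,(\text{by} - 1950)\big)$$

with defaults $p_{1950,\text{male}} = 0.64$, $p_{1950,\text{female}} = 0.50$
and trend $\beta_t = -0.075$ per birth year. A negative trend makes
initiation probability strictly decreasing in birth year, which is what
drives the declining eligible fraction. Initiation age is truncated normal
(mean 17, sd 3, range 11–35); intensity is lognormal (median ≈ 20
cigarettes/day, capped at 60); cessation follows a geometric waiting time
with annual quit probability 0.025. Intensity is constant over a smoking
career: pack-year eligibility logic only needs cumulative exposure, and dose
tapering would add parameters with nothing to pin them down.

These defaults were chosen once so that the structural shape of the
population matches what a US-like population should look like: about 6.3% of
the study population is screening-eligible in 2016, declining to about 3.5%
by 2030, screens at 45% adherence are about 2.8–2.9% of the study population
in the first year, and never smokers account for roughly 7–8% of lung cancer
deaths. They are a documented stand-in for an external smoking history
generator, not estimates of it.

## Competing mortality

Death from causes other than lung cancer follows a Gompertz hazard
$b\,e^{g\,\text{age}}$ ($b = 4\times10^{-5}$, $g = 0.09$) multiplied by a
smoking-status hazard ratio (current 1.6, former 1.25, never 1) that switches
at the initiation and cessation ages. The age at other-cause death is drawn
by exact piecewise inversion of the cumulative hazard and capped at
`max_lifespan_age` (default 100). Smokers therefore die earlier of competing
causes, which matters for overdiagnosis: a screen-detected cancer in someone
who dies of something else first is an overdiagnosis.

## Natural history of lung cancer

Latent onset is a nonhomogeneous hazard
$h(a) = c_0\,e^{c_1 a}\,\text{rr}(a)$ with baseline $c_0 = 4.5\times10^{-7}$,
$c_1 = 0.09$ and relative risk $\text{rr} = 1 + 1.3\times\text{cigs/day}$
while smoking, decaying as $e^{-0.05\,(a - a_{quit})}$ toward 1 after
cessation. Onset ages are drawn by inverting the closed-form piecewise
cumulative hazard (vectorized bisection to ~1e-15 relative precision).
Never smokers face the baseline hazard only, so they are never structurally
excluded from lung cancer death.

Each tumor receives a histology (adenocarcinoma 40%, squamous 22%, large
cell 8%, small cell 15%, other 15%) and then progresses through preclinical
stages I→II→III→IV with exponential sojourns (means 2.5, 1, 1 years; stage
IV absorbing; small cell progresses 2.5× faster). Within each stage a
stage-specific clinical-detection hazard (0.18, 0.50, 1.20, 2.50 per year)
competes with progression; the first detection event fixes the clinical
detection age and stage. The detection clock restarts at each stage entry —
a modeling convention, stated here because it is not the only possible one.

## Survival, stage shift, and the comonotone coupling

Post-diagnosis survival is a cure mixture: with stage-specific probability
(5%, 3%, 2%, 0.5%; halved for small cell) the person never dies of lung
cancer; otherwise an exponential residual (rates 0.20, 0.35, 0.55, 0.95 per
year; 1.5× for small cell) applies. The death age is the inverse survival
function evaluated at a single per-person quantile drawn once and shared by
both scenarios. Because cure fractions are non-increasing and residual rates
non-decreasing from stage I to IV (enforced at config validation), this
mapping is comonotone: at any fixed quantile, an earlier detection stage
never produces an earlier lung cancer death.

Two design choices follow from this and deserve emphasis:

* **Screening benefit flows only through stage shift.** There is no separate
  "screen-detected" survival bonus. If screening does not change the stage at
  detection, it changes nothing.
* **Lung cancer death is anchored at the latent clinical detection age in
  both scenarios.** The screening scenario's death age is
  `clinical_detection_age + residual(stage at actual detection, quantile)`,
  not `screen_detection_age + residual`. Anchoring at the (scenario-invariant)
  clinical detection age removes lead-time bias entirely: detecting the same
  stage earlier confers zero spurious survival, and the per-person non-harm
  property — screening never moves any death earlier — holds exactly, not
  just in expectation. This is what makes per-person counterfactual
  accounting (deaths avoided, life-years gained, overdiagnosis) clean.

One tumor per person (first onset only); second primaries play no role in
any outcome definition here.

## Screening program

CMS eligibility at an exam: age 55–77 inclusive, at least 30 pack-years
(exactly 30 qualifies), and current smoker or former smoker strictly fewer
than 15 years since quitting (exactly 15 does not qualify). Adherence is a
fixed per-person attribute: each person carries one uniform draw and is
adherent iff it falls below the adherence rate (default 0.45). Thresholding
one shared draw makes adherent sets nested across rates, so the adherence
sweep is monotone by construction and runs on a single simulated population.

Adherent, alive, eligible, not-yet-diagnosed persons receive one CT exam at
the start of each calendar year from 2016 on (the exam precedes that year's
clinical detection and deaths — the within-year event order is fixed for
reproducibility). A preclinical tumor is detected with stage-specific
sensitivity (0.85, 0.90, 0.95, 0.97); detection fixes stage and mode and
stops further screening. Specificity affects no harm pathway; false
positives are not modeled beyond exam counting.

## Random-number architecture

Every stochastic quantity is an inverse-CDF transform of a keyed uniform
`hash(master_seed, person_id, substream, counter)` (SplitMix64 finalizer,
implemented in C++). Named substreams (other-cause death, onset, histology,
stage sojourns, clinical detection, survival quantile, screen detection by
year, adherence) are pairwise independent and reproducible per person. The
two scenarios therefore share the population, tumor process and survival
quantile exactly — common random numbers by construction rather than by
stream discipline — and replications are bit-for-bit reproducible from their
seed. Replication r of a run with master seed S uses seed `S*1000 + r`.

## Metrics

All outcome metrics operate on the paired person-level event log:

* **Mortality reduction** = deaths avoided / no-screening lung cancer deaths
  within the horizon, as a percent (2 decimals, half away from zero). The
  screened-population variant restricts both numerator and denominator to
  persons with at least one exam.
* **Life-years gained** sums the per-person difference in years lived inside
  the calendar window while study-aged (a truncation-at-horizon convention:
  gains accruing after 2030 are not counted).
* **Overdiagnosis (counterfactual definition)** counts screen-detected
  diagnoses in persons whose eventual death — followed past the horizon to
  the lifespan cap — is from another cause; reported absolutely, per 100
  deaths avoided, and as a percent of screen-detected diagnoses.
* **Excess diagnosis rate** (the trial-based public-health definition) is
  (screening-arm cases − control-arm cases) / screening-arm diagnoses, with
  the no-screening scenario as control.
* Deaths and deaths avoided are attributed to smoker type at the clinical
  detection anchor (status at diagnosis). Status at death would let a death
  deferred past a cessation age migrate between strata across scenarios,
  breaking the per-stratum non-negativity of deaths avoided; the anchor age
  is scenario-invariant, so the invariant holds exactly.

Across replications (20 by default), every metric is reported as a mean with
a normal-approximation 95% CI, mean ± 1.96·sd/√R. With R = 20 the true
coverage of that interval on Gaussian quantities is closer to 93–94% than
95% (1.96 vs the t₁₉ quantile 2.09); the tests assert coverage in that
approximate-nominal band.

## Numerical choices and degenerate inputs

Bisection inversion of the onset cumulative hazard runs 60 halvings on
[0, lifespan cap], well below double precision at the scale of ages.
Zero-probability branches (cessation probability 0, detection hazard 0,
sensitivity 0, adherence 0) are exact, not limits of small numbers; ties at
eligibility boundaries follow the stated inclusive/exclusive semantics; an
other-cause and lung-cancer death at the same instant is classified as
other-cause (measure-zero under continuous draws). Histology mixtures must
sum to 1 within 1e-9. Quit ages at or beyond the lifespan cap are treated as
never quitting.

## Problem sizes

Default runs use 100,000 simulated persons per replication; the bundled
acceptance script runs 5 replications at that size plus an adherence sweep
and three 150,000-person single-cohort trajectories. Those sizes give
stable percentages (binomial noise on the eligible fraction is ~0.1%) while
a full run completes in about a minute. The simulation is
weight-scalable: `person_weight` converts simulated persons to represented
persons without changing any rate or percentage.

## What the generator does and does not emulate

The synthetic population reproduces the structural features the screening
question needs: cohort-declining smoking prevalence, smoking-dependent lung
cancer risk and competing mortality, realistic eligibility fractions and
their decline. It does not emulate race or socioeconomic structure,
time-varying smoking intensity, relapse after quitting, migration, or
calibrated absolute US counts. Passing tests therefore demonstrate the
internal correctness and structural behavior of the method — counterfactual
identity, non-harm, adherence linearity, cohort ordering — not agreement
with any national projection.

## Known limitations

* The natural-history parameterization is a transparent stand-in, not a
  calibrated estimate. In particular, a cure-mixture survival model bounds
  the overdiagnosis rate below by the cure fraction of screen-detected cases
  plus competing-mortality interception during the residual window; with
  defaults, roughly a quarter of screen-detected diagnoses end in
  other-cause death, higher than trial-calibrated models report. The
  benefit/harm *balance* is therefore more conservative here than in
  calibrated models, while the orderings and scalings (adherence linearity,
  cohort ordering, screened vs total mortality reduction) are robust.
* Stages are I–IV for all histologies, including small cell (no
  limited/extensive dichotomy); small cell differs only through rate
  multipliers.
* Annual mortality reduction in this parameterization keeps building
  through the late horizon rather than peaking mid-horizon: with no
  calibrated cohort-risk gradient beyond smoking prevalence, benefit
  accumulation dominates eligibility decline for longer.
* Life-years gained truncate at the horizon; lifetime gains would be larger.
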