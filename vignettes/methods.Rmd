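---
title: "Model and methods: MSLT cost-effectiveness of weight-loss app promotion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the model `appmslt` implements, the assumptions
behind each stage, the parameters that matter (with units and defaults),
the design of the synthetic baseline generator, and the numerical choices
— so a reader can judge what results on the synthetic data do and do not
say about real populations.

## The cohort and its life tables

The modelled population is a **closed cohort**: everyone alive in the base
year 2011, cross-classified by sex, ethnicity (Māori / non-Māori) and
single year of age 0–110 — 444 strata. No births or migration enter after
2011; each stratum is simulated in annual cycles until the cohort reaches
the terminal age of 110, where the annual death probability is 1.

Two arms run in parallel from identical initial conditions:
business-as-usual (BAU) and intervention. The model is a **proportional
multistate life table**: state occupancies are proportions of each stratum,
not simulated individuals.

Alongside the main (alive/dead) table, each of 14 BMI-related diseases —
coronary heart disease, stroke, type 2 diabetes, osteoarthritis, and
endometrial, kidney, liver, esophageal, pancreatic, thyroid, colorectal,
breast, ovarian and gallbladder cancers — runs its own closed three-state
life table (healthy $h$, prevalent $p$, dead-of-disease $d$) with annual
difference equations

$$
\begin{aligned}
\text{new} &= h_t \, i_t (1 - \mathrm{PIF}_t), &
\text{rem} &= p_t r_t, &
\text{dth} &= p_t f_t,\\
h_{t+1} &= h_t - \text{new} + \text{rem}, &
p_{t+1} &= p_t + \text{new} - \text{rem} - \text{dth}, &
d_{t+1} &= d_t + \text{dth},
\end{aligned}
$$

where $i$, $f$, $r$ are the annual incidence, case fatality and remission
probabilities at the **attained age** (the cohort experiences the rates of
the age it has reached, the standard life-table convention). Remission is
zero for the noncancers (lifetime diagnoses); for cancers, case fatality
and remission split a 1/5-per-year exit from the prevalent state so that
the probability of dying equals the 5-year case-fatality risk and
remission is its complement (5-year relative survival read as cure). The
three states sum to one by construction; the engine verifies drift stays
below $10^{-9}$ over the full run.

Rates carry annual proportional **trends**, applied from 2011 and frozen
after 2026: $x_t = x_{2011}(1+\text{trend})^{\min(t,2026)-2011}$.

Each disease table is initialised at the steady state of the embedded
healthy↔prevalent chain, $p_0 = i/(i+f+r)$. Because this expression
ignores competing mortality, the generator's case fatalities for the
low-lethality chronic diseases (diabetes, osteoarthritis) are set higher
than clinically typical (~0.01–0.03/yr) so that $p_0$ stays plausible;
this is a deliberate generator design choice, not an estimate.

### Linking disease tables to the main table

The intervention only perturbs disease **inflow**. Its mortality and
morbidity consequences reach the main table through prevalence
*differences* against BAU, which makes the null-intervention identity
exact (PIF ≡ 0 ⇒ the two arms are bitwise identical):

* mortality: the intervention arm dies at
  $m - \sum_d f_d (p_{d,\mathrm{BAU}} - p_{d,\mathrm{int}})$, where $m$ is
  all-cause mortality. The relief can turn slightly negative late in life
  (survivors age into disease); at the terminal age, where $m = 1$, this
  can overshoot 1 by ~$10^{-9}$, which the engine clamps. Only gross
  violations (signalling incoherent rates) raise an error.
* morbidity: QALYs weight life-years by
  $1 - (\mathrm{pYLD} - \sum_d \mathrm{dr}_d\,(p_{d,\mathrm{BAU}} -
  p_{d,\mathrm{arm}}))$, clamped to $[0,1]$; pYLD is prevalent
  years-lived-with-disability per capita and $\mathrm{dr}_d$ the
  disability rate per prevalent case (assumed pre-scaled for
  comorbidity).

Life-years credit deaths half a cycle (midpoint rule,
$(\text{alive}_t + \text{alive}_{t+1})/2$); the within-year timing of
deaths is otherwise unresolved at annual resolution.

## The intervention

The campaign is one-off, in 2011, targeted at adults (18+). Its effective
coverage is the **cascade product**: smartphone access 0.7442 × campaign
exposure 0.7794 × app download 0.1346 (scaled by the scenario multiplier
1 / 1.5 / 2, capped at 1) × regular use 0.26 ≈ 2.0% of overweight/obese
adults; population-weighted over the synthetic cohort this is ~1.4% of all
adults.

Regular users lose an extra 0.43 kg (95% CI 0.25–0.61), converted to BMI
units by the sex×ethnicity mean height, $\Delta_{\mathrm{BMI}} = \Delta_{kg}/h^2$
(≈ −0.15 units). After the intervention year the loss is regained at 0.03
BMI units/month — each later year's value is the mean of its 12 monthly
values, floored at zero (no overshoot into net gain) — so the effect is
exhausted about five months in. The no-decay scenario holds the loss
permanent.

Each stratum's population-mean BMI change is
`uptake × overweight_prop × decay_profile(Δ_BMI)`: the effect operates in
the overweight/obese fraction (BMI ≥ 25) and is spread over the stratum as
a location shift of its whole BMI distribution, shape preserved. Because
the decay profile is floored at zero, the profile is linear in the effect
size only where the floor is not binding (exactly so in the intervention
year and under no-decay); linearity in the uptake fraction holds
everywhere.

## Relative risk and population impact fractions

The exposure–response is the standard comparative-risk-assessment form:
$RR(b) = \rho^{\max(0,\,\min(b, 60) - \mathrm{TMREL})}$, flat at or below
the theoretical minimum risk exposure level (TMREL, default BMI 21) and
flat again above BMI 60. The upper plateau is required, not cosmetic: a
log-normal has no moment generating function, so without it
$E[\rho^X]$ diverges. Any quadrature or Monte-Carlo estimate of the
uncapped expectation is silently an estimate of *some* truncation; the cap
makes the truncation explicit and shared by every backend.

The population impact fraction for a stratum, disease and year is

$$\mathrm{PIF} = 1 - \frac{E[RR(X + \delta)]}{E[RR(X)]},$$

with $X$ the stratum's log-normal BMI (parameterised from the arithmetic
mean and SD of its sex×ethnicity×age-band cell, looked up at attained
age) and $\delta$ the **lagged** population-mean BMI change: the mean of
the per-year change over the past 0–5 years (CHD, stroke, diabetes,
osteoarthritis) or 10–30 years (cancers), both endpoints included,
pre-intervention years counted as zero, divisor always the full window
length. Relative risks apply from attained age 25; PIFs are forced to
zero below it.

Two independent numeric backends compute $E[RR(\cdot)]$:

* `pif()` uses adaptive integration (`stats::integrate`, relative
  tolerance $10^{-8}$), split at the TMREL and cap kinks, with the
  integrand evaluated in log space to avoid `Inf × 0` in the tail;
* the engine evaluates the tail masses below TMREL and above the cap in
  closed form (`plnorm`) and applies 24-node Gauss–Legendre quadrature to
  the smooth middle segment, where the integrand is analytic — relative
  error ~$10^{-11}$ against the adaptive backend, and vectorised across
  strata. Baseline (zero-shift) expectations are cached per unique
  (age-band, RR) pair.

The tests cross-check the two backends against each other and against a
$10^6$-draw Monte-Carlo estimate.

## Health-system costs

Per person-year of each stratum, the ledger charges

* the sex×age **baseline cost** to the alive fraction *without* a
  BMI-related disease (`1 − Σ_d p_d`, floored at 0). Because prevalent
  fractions are netted out of this pool, the generator's
  `cost_prevalent` is the *full* annual cost of a prevalent case, set
  above the age-typical baseline cost; disease deaths are a subset of
  prevalent cases, so no separate netting of the dying is applied, and
  deaths from causes outside the model keep their baseline cost;
* per disease: `cost_first_year × new cases`,
  `cost_prevalent × (prevalent − new cases)`, and `cost_last6m × disease
  deaths` in the death year (annual cycles cannot resolve six months).

Longer survival in the intervention arm therefore accrues more baseline
cost, partially offsetting disease-cost savings. Net cost is the
intervention cost (NZ$2,883,000 = 72,000 web promotion + 2,791,000 mass
media + 20,000 app identification) plus the discounted cost difference.

Discounting is year-end, anchored at 2011: $\sum_t v_t (1+r)^{-(t-2011)}$,
with $r = 3\%$ (0% and 6% in scenarios); whether mid-year or year-end
discounting is intended is unstated in the source material, so year-end
was chosen and applied consistently. ICERs are net cost over QALY gain,
flagged dominant when cost-saving and health-gaining; US$ conversion uses
2011 purchasing power parity (NZ$1.486 per US$1). Reporting rounds to 2–3
significant digits at the report layer only; summaries include
per-1000-adult rates (all adults and overweight/obese only) and direct age
standardization to the WHO World Standard population, restricted to
cohorts aged 25+ in 2011.

## The synthetic baseline generator

No public deposit of the real inputs exists, so `generate_baseline()`
emits a dataset with the *structure* the analysis assumes, seeded and
deterministic (identical seed+config ⇒ identical dataset):

* **Population**: 4.4 million split ~15% Māori, with a younger Māori age
  structure; ~1% multiplicative noise per cell.
* **Mortality**: Gompertz–Makeham ($4\times10^{-4} + 2.2\times10^{-5}
  e^{0.095\,\mathrm{age}}$, plus an infant bump), male ×1.35, Māori ×1.6 —
  the higher Māori background burden the equity analysis needs; forced to
  1 at age 110.
* **Morbidity** (pYLD/capita) rising with age, Māori ×1.35.
* **BMI**: log-normal per sex×ethnicity×5-year band; mean rising from ~25.5
  at 20 to ~28.8 at 65, Māori +1.8; SD ≈ 17% of the mean.
  Overweight/obese prevalence is $P(\mathrm{BMI} \ge 25)$ under the *same*
  distribution, so the cascade and PIF stages are mutually consistent.
* **Heights**: normal; means 1.74/1.76 m (Māori/non-Māori men), 1.61/1.62 m
  (women), SD 0.07 — spanning the published −0.14 to −0.17 BMI-unit effect
  range.
* **Diseases**: CHD/stroke incidence rising exponentially with age,
  diabetes peaking mid-life, osteoarthritis logistic in age; cancers rare
  with site-specific 5-year case-fatality risks (0.05 thyroid … 0.90
  pancreas) annualised as above; Māori incidence ×1.3; ~3% log-normal rate
  noise per cell. Relative risks per BMI unit range from 1.02 (thyroid,
  breast, ovarian) to 1.18 (diabetes).
* **Coherence guarantee**: case fatalities are rescaled per cell (a few
  fixed-point passes, deterministic) so that expected disease deaths
  $\sum_d f_d p_d$ never exceed half of all-cause mortality;
  `coherence_check()` verifies this, the probability bounds, zero
  noncancer remission, and the one-step balance of the embedded chain at
  the derived prevalence (relative tolerance 25%, an artifact choice that
  guards hand-edited datasets).

What the generator does **not** emulate: real age×cohort rate surfaces,
correlated noise across neighbouring ages, regional heterogeneity,
DISMOD-style reconciliation of independently measured incidence and
prevalence, or the true NZ cost distributions. Passing tests on this data
demonstrate the *mechanics* — orderings, invariants, oracle agreement —
not the reference analysis' absolute numbers, which depend on the
non-public inputs; headline magnitudes here (for example ~7 QALYs in the
base case) should be read only as "same order of magnitude, same
qualitative structure".

## Uncertainty analysis

Each perturbable input has a parameter spec (`inst/extdata/parameters.yaml`):
family, central value, SD or 95% interval (SD = width/3.92), domain
clamps, a correlation group and a tornado group. Fitting is by moment
matching — beta ($\alpha+\beta = m(1-m)/s^2 - 1$), gamma (shape
$(m/s)^2$, so a 20% SD gives shape 25), log-normal from arithmetic
moments. Effect-size draws are truncated at zero (no harmful draws). The
TMREL draw is uniform on an interpolation fraction mapped to BMI 21–23;
the central (expected-value) run uses 21. Lag-window boundary draws
(±20% SD around 5, 10, 30) are rounded to whole years with the noncancer
lower bound fixed at 0 and validity enforced.

Heterogeneity simplification: where the reference analysis draws
parameters per sex/age/ethnicity cell, this implementation draws one
global multiplier per parameter family (disease incidence / case fatality
/ remission at 5% SD; pYLD 10%; disability rates 10%; health-system costs
10%; trends ±0.5% absolute, diabetes ±1.5%; an RR log-scale factor at 10%;
additive height shifts). This preserves each family's contribution to
output uncertainty while keeping the spec table small.

Sampling is a **Gaussian copula**: latent normals correlated within the
named group — intervention cost with the three uptake-cascade stages — at
latent Pearson $2\sin(\pi \cdot 0.75/6)$ so the realised *Spearman*
correlation is 0.75 exactly, pushed through each marginal's inverse CDF.
Marginals are preserved; draws are seeded.

`run_psa()` propagates each draw through the whole pipeline and reports
means, medians, percentile 95% uncertainty intervals (2.5th/97.5th), and
the probability the ICER falls below NZ$45,000/QALY. Invalid draws are
logged and rejected; more than 1% rejections aborts. The reference
analysis uses 2000 draws; the packaged scenario grid and acceptance script
use 500, which this engine (≈0.3 s per draw) completes in minutes on one
CPU — chosen as a sensible default for iterative work, with `n` exposed
everywhere.

`tornado()` re-runs the PSA one parameter group at a time (all others at
central values) and ranks groups by the 2.5–97.5 percentile span of the
QALY and net-cost outputs. Only the *ranking* is comparable across
implementations — the reference tool's tornado algorithm is not public —
and on the synthetic data the download-rate group dominates while BMI
decay contributes least, matching the reported ordering.

## Numerical choices, degenerate inputs, limitations

* Quadrature: 24 Gauss–Legendre nodes on the smooth RR segment (relative
  error ~$10^{-11}$); adaptive integration tolerance $10^{-8}$.
* Clamps: rates clamped to $[0,1]$ only where a trend could push them out;
  case-fatality + remission renormalised if their sum would exceed 1;
  QALY weights clamped to $[0,1]$; adjusted mortality clamped as above.
* Degenerate inputs: zero-variance parameter specs return their central
  value for every quantile; empty disease lists run the bare demographic
  life table (used by the closed-form survival oracle); a zero effect
  profile short-circuits to identical arms.
* Equity swap: replaces Māori all-cause mortality and pYLD with same-sex
  same-age non-Māori values, leaving disease tables and population counts
  unchanged; idempotent by construction.
* Known limitations: no physical-activity pathway, no J-shaped BMI–
  mortality relation, no comorbidity states beyond YLD scaling, no repeat
  campaigns or diffusion, societal costs out of scope; disease tables are
  closed systems, so disease-state proportions are linked to survival
  multiplicatively when costing, an approximation shared by both arms.
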