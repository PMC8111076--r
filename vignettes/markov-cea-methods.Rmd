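---
title: "Methods: a three-state Markov cost-effectiveness model from reconstructed survival curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a three-state Markov cost-effectiveness model from reconstructed survival curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markovcea)
```

# The decision problem

`markovcea` implements a trial-based cost-utility comparison of two
first-line treatment strategies for metastatic non-small-cell lung cancer
(NSCLC): the anti-PD-L1 antibody atezolizumab versus platinum-based
chemotherapy, evaluated from a health-sector perspective in three PD-L1
expression strata (high, high-or-intermediate, any). The pipeline is,
however, generic: any two strategies described by a progression-free
survival (PFS) curve, an overall survival (OS) curve and a set of economic
inputs can be compared.

The pipeline has five stages, each usable on its own:

1. **Curve reconstruction** (`reconstruct_ipd()`): pseudo
   individual-patient data (IPD) from digitized Kaplan-Meier coordinates
   plus a numbers-at-risk table.
2. **Parametric extrapolation** (`fit_families()`, `select_best()`):
   maximum-likelihood fits of six families, AIC selection.
3. **Cohort model** (`markov_trace()`): a three-state Markov trace driven
   by time-dependent transition probabilities.
4. **Economics** (`accumulate()`, `icer()`): discounted costs and QALYs,
   incremental cost-effectiveness ratios.
5. **Uncertainty** (`one_way()`, `psa()`, `ceac()`, `price_scan()`).

# Health states and transition probabilities

The cohort occupies three mutually exclusive states — progression-free
(PFS), progressed disease (PD), and death — starting 100% progression-free.
Both survival curves are functions of time in months; call the cycle length
$\mu$. Per cycle ending at $t$:

* staying progression-free is the conditional survival
  $P_{PFS \to PFS} = S_{PFS}(t)/S_{PFS}(t-\mu)$;
* death from the progression-free state occurs at the background (other-
  cause) mortality rate;
* progression takes the remaining exit mass;
* the total alive mass is governed by the OS curve through
  $P_{S \to S} = S_{OS}(t)/S_{OS}(t-\mu)$, and the PD-to-PD retention is
  solved from the balance
  $[(n_{PFS}+n_{PD})\,P_{S\to S} - n_{PFS}\,P_{PFS\to PFS} -
    n_{PFS}\,P_{PFS\to PD}]\,/\,n_{PD}$
  using the previous cycle's occupancies; death from PD takes the rest.

Two degenerate situations need care, and both are resolved so that the
trace keeps tracking the curves exactly:

* **Empty PD state.** In the first cycle (and whenever PD is empty) the
  balance above has no denominator. The exit from PFS is then split so
  that PD receives exactly the survivors the OS curve leaves beyond PFS;
  the remainder goes to death. Without this, the deaths the OS curve
  implies in the first cycle would never be realized and every later
  occupancy would be inflated by a constant factor.
* **Over-fast early progression.** Early on, the PFS curve can fall faster
  than the OS-PFS gap grows, so the preferred split would push more
  patients into PD than the OS curve allows. The PD retention is clamped
  at 0 and the PFS-to-PD flow is reduced to the OS balance; the excess
  rapid progressors die within the cycle. (Progression and death within
  one 3-week cycle is clinically unremarkable.)

With these rules the engine satisfies, to machine precision and for any
background mortality,
$n_{PFS}(t) = S_{PFS}(t)$ and $n_{PFS}(t) + n_{PD}(t) = S_{OS}(t)$,
which is what makes life-years provably invariant to the background-
mortality setting (deaths are only re-attributed between states). A PFS
curve that crosses *above* the OS curve is a genuine inconsistency; the PD
state is clamped at zero with a warning and the cohort still conserves
mass.

The stay probability is implemented as the conditional survival ratio. A
"1 minus ratio" reading would be the *leaving* probability: it would empty
the progression-free state within a handful of cycles and cannot reproduce
any published life-year figure, so the conditional-survival reading is the
only self-consistent one.

# Time conventions

The defaults in `model_settings()` are the conventions under which the
packaged published parameters reproduce the published base-case table,
and they are deliberately plain:

* **Cycle length 0.75 months.** Treatment is administered every 3 weeks
  and a 3-week cycle is entered on the survival time axis as three
  quarters of a month (the 4-week-month convention common in spreadsheet
  cohort models). The exact-calendar alternative (21/30.4375 = 0.6899
  months) under-reproduces every published life-year cell by 2.5-5%;
  the 0.75-month convention reproduces all twelve within 0.015.
* **Horizon 174 cycles** — ten years of 3-week cycles.
* **Start-of-cycle occupancy accrual.** Each cycle credits the occupancy
  holding at its start (no half-cycle correction). Setting
  `half_cycle_correction = TRUE` switches to trapezoidal accrual, which
  tracks the restricted mean survival time (RMST) of the OS curve to
  within 0.01 years and is the right choice when the trace is validated
  against quadrature.
* **Discount clock on model months.** Costs and QALYs are discounted at
  5%/year with factor $(1+r)^{-t/12}$, $t$ the model-month clock at cycle
  start; life-years are undiscounted. (Discounting life-years as well
  would visibly under-shoot the published undiscounted LY column.)
* **Background mortality** defaults to an annual other-cause death
  probability of 1%, roughly the all-cause mortality of Chinese adults in
  the trial age range; because of the occupancy identity above, its value
  cannot move life-years or QALYs, only the state a death is recorded
  from, and a test asserts exactly that.

# Kaplan-Meier reconstruction

`reconstruct_ipd()` implements the iterative published-curve
reconstruction in its standard unconstrained variant: within each
risk-table interval a censoring count is proposed, censorings are spread
uniformly over the interval, the event count at each digitized coordinate
is chosen so the running product-limit estimate tracks the digitized
survival, and the censoring count is adjusted until the implied number at
risk matches the next printed count. In the final interval (no further
risk tick) the earlier intervals' censoring rate is carried over, and
whoever remains at risk past the last coordinate is administratively
censored there, so the reconstructed cohort always has the printed arm
size. Reported total event counts are stored but not imposed as a
constraint.

Coordinates are taken as exact: a digitization whose survival values
increase is rejected rather than repaired, so reconstruction stays
deterministic and any smoothing of digitization noise is an explicit
upstream step. Risk-table counts are read as subjects still under
observation immediately after the tick, so a curve step exactly at a tick
is processed before the count applies; for the dense grids this package
generates and consumes the boundary choice is immaterial.

On synthetic fixtures (n = 150-300, exponential or Weibull truth, 3-month
risk ticks, 0.25-month digitization grid) the recomputed KM curve tracks
the digitized coordinates within 0.02 absolute and the implied risk table
matches the printed one exactly.

# Parametric fitting and model selection

Six families are supported — exponential, gamma, Weibull, log-logistic,
log-normal, Gompertz — in the parameterizations stated in
`?surv_dist`; the Gompertz shape may be negative, giving a survival
plateau at $\exp(b/a)$, the form the published high-or-intermediate OS
extrapolation takes. Fitting is right-censored maximum likelihood via
`flexsurv::flexsurvreg()`, which matches the package's parameter naming
exactly and supplies the log-likelihood and the parameter covariance on
the transformed (log-positive) scale; `markovcea` keeps its own
closed-form survival functions, which the test suite cross-checks against
the reference distribution functions, so the fitted curve that enters the
Markov engine never depends on flexsurv at evaluation time.

Selection is by AIC ($2k - 2\ell$); ties go to the family with fewer
parameters and then to a fixed family order, so selection is
deterministic. Non-convergence of one family is a flagged failure that
excludes it from selection, not an error. One property worth knowing:
when the truth *is* exponential, each of its 2-parameter superfamilies
(Weibull, gamma, Gompertz) beats it whenever twice the log-likelihood gain
exceeds the AIC penalty, which happens with probability
$P(\chi^2_1 > 2) \approx 0.16$ per family even at n = 1000, so the
exponential recovery rate sits near 0.79 while Weibull and log-normal
recover at 0.98+; the mixed recovery probability is about 0.92.

# Economics

Costs enter per cycle in the configured currency (USD throughout the
shipped configs; `cny_to_usd()` applies the 6.899 CNY/USD analysis rate).
Drug cost accrues over treated-state occupancy (progression-free by
default, optionally capped at a number of cycles); supportive-care and
follow-up costs over alive occupancy; second-line treatment over PD
occupancy scaled by a treated fraction; end-of-life cost per incident
death; and serious adverse events (grade 3+, kept only when the
between-arm incidence difference is at least 3 percentage points) are
charged — cost and QALY decrement alike — once in the first cycle.
Utilities default to 0.804 progression-free and 0.321 progressed.

The patient-assistance program is a repeating 2-paid/3-free schedule:
cycles 1, 2, 6, 7, 11, 12, ... are paid. Over a long treatment course
this prices roughly 40% of cycles, which is why the published
with-assistance incremental costs are a bit over 40% of the without-
assistance ones.

Monetary magnitudes in `make_cost_config()` are synthetic stand-ins (the
original charge inputs are not redistributable) and every config carries a
`synthetic = TRUE` flag; `calibrate_drug_price()` solves the treatment
drug price — total cost is affine in any per-cycle price — so that the
incremental cost hits a chosen target exactly, which is how the published
incremental costs are reproduced for the ICER checks. Chemotherapy dosing
(per-m^2 doses at a body surface area of 1.72 m^2) is available through
`drug_cost_from_dose()` with linear per-mg pricing and no vial rounding;
carboplatin's AUC-based dose needs a creatinine-clearance assumption the
source analysis never states, so carboplatin enters as a direct mg dose.

# Sensitivity analysis

One-way analysis moves each parameter to its low and high value (default
±25% of base, or an explicit interval) with everything else at base and
reports the ICER swing, sorted into a tornado. Probabilistic analysis
samples all parameters jointly but independently — gamma for costs, beta
for utilities, incidences and proportions, log-normal for ratio-like
quantities — with hyperparameters by method of moments from (mean, SE),
SE defaulting to a quarter of the mean when no interval is known.
Sampling is quantile-based (each parameter consumes one uniform per
iteration), which makes draws reproducible under a seed and monotone in
the parameter's mean; the price-reduction scan exploits that monotonicity
to guarantee a nondecreasing probability curve along the reduction grid
under a shared seed.

Survival-curve uncertainty is propagated by resampling the fitted
parameters from a multivariate normal on the fit scale using the MLE
covariance (`resample_fit()`, fed to `psa()` through `curve_draws`). A
hazard-ratio sampling channel is deliberately absent: the model contains
no hazard-ratio term, so there is nothing for a log-normal HR draw to act
on.

The acceptability curve applies the net-monetary-benefit rule — the
probability at willingness-to-pay $\lambda$ is the fraction of samples
with $\lambda\,\Delta QALY - \Delta cost > 0$ — on the same sample set at
every grid point. The default threshold constant is $30,828/QALY (three
times China's 2019 per-capita GDP); the default grid runs 0-200,000 by
1,000.

# The synthetic-data generator

`simulate_trial()` draws PFS times from a chosen family and builds OS
additively as PFS plus a strictly positive post-progression residual, so
the OS curve dominates the PFS curve by construction — the same ordering
the model needs. Administrative censoring and exponential dropout are
applied, and the "digitization" a downstream user would produce is
emulated by reading the KM step curve on a regular grid and counting
subjects under observation at regular risk ticks. What it deliberately
does not emulate: digitization noise (clicks are exact), delayed
treatment effects or crossing hazards, informative censoring, and
reporting coarseness of published curves. Passing round-trip tests on
these fixtures therefore demonstrates correctness of the reconstruction
arithmetic, not robustness to a noisy human digitization.

# Problem sizes and numerical choices

The test suite runs the full published base case (three populations, two
arms, 174-cycle traces), reconstruction round-trips at n = 150-300,
parameter recovery at n = 286-1000, 50 model-selection replicates at
n = 1000 (seeded 1..50), and probabilistic analyses of 1000 iterations;
the whole suite completes in two to three minutes on one core. Fitted
probabilities are clamped to [0, 1] with violations beyond 1e-9 treated
as structural (warning or error, never silent); quadrature uses
`stats::integrate` at 1e-8 relative tolerance; occupancy conservation is
asserted at 1e-9 and the curve-tracking identity at 1e-6.

# Known limitations

* The three-state structure has no treatment-discontinuation state and no
  tunnel states; atezolizumab is costed while progression-free.
* Extrapolation trusts a single best-AIC family per curve; structural
  extrapolation uncertainty (e.g. model averaging, spline models) is out
  of scope.
* The cohort is homogeneous: no age-sex stratification, and background
  mortality is a constant annual probability rather than a life table
  (harmless for outcomes, see the invariance above, but it does shape the
  attribution of deaths between states).
* Parameters are sampled independently in the probabilistic analysis;
  correlated sampling and value-of-information measures are not
  implemented.
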