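---
title: "Modeling tumor volume kinetics and single-fraction radiation response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling tumor volume kinetics and single-fraction radiation response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gomprad)
```

## The model and its assumptions

`gomprad` treats the tumor as two well-mixed compartments of volume —
dividing cells $V_T$ and non-dividing (dead, not yet cleared) cells
$V_{ND}$ — under three structural assumptions:

1. **Volume is proportional to cell number.** All rate equations written
   for cell counts apply to volumes unchanged. This breaks down if cell
   size or intercellular spacing changes after irradiation.
2. **Growth is vasculature-limited.** The specific growth rate is
   proportional to the vascular-to-tumor volume ratio, and the vasculature
   grows $\theta$ times as fast as the tumor ($0 < \theta \le 1$).
   Linearizing both specific growth rates at their initial values gives
   $d\lambda/dt = -(1-\theta)\lambda(0)\lambda$, hence
   $\lambda(t) = \lambda(0)e^{-(1-\theta)\lambda(0)t}$ and the Gompertz
   closed form with plateau $V_0 e^{1/(1-\theta)}$. $\theta = 1$ is pure
   exponential growth. The vascular volume itself and its proportionality
   constant are eliminated variables: only $\theta$ survives in the
   equations.
3. **Radiation death is delayed, not instantaneous.** A dose $D$ at $t_R$
   opens a window of length $\tau_{rad}$ during which a cell completes a
   division with probability $p(D)$ per cycle and transitions to the
   non-dividing pool at rate $g(D)$. Both derive from the linear-quadratic
   lethality exponent $\chi(D) = \alpha D(1 + D/(\alpha/\beta))$ by
   requiring that the two-state branching dynamics, scored at the colony
   counting time $T_m$, reproduce the LQ clonogenic survival
   $e^{-\chi(D)}$: $p = 1 - \frac{T^*}{3T_m}\chi$, $g = \frac{\chi}{3T_m}$.
   During the window $\lambda$ is frozen (the vascular-to-tumor ratio is
   assumed constant while cells die); afterwards $p \to 1$, $g \to 0$, the
   growth-rate decay resumes from the frozen value, and $V_{ND}$ clears at
   $\eta_{cl} = \ln 2/T_{cl}$.

The observable volume is $V_T + V_{ND}$, continuous everywhere — in
contrast to the standard instantaneous-kill model
(`simulate_standard_model()`), where $V_T$ drops by the factor $e^{-\chi}$
at the instant of irradiation. The two models coincide in surviving $V_T$
when $\lambda_R = 0$, $\eta_{cl} = 0$ and $\tau_{rad} = 3T_m$, which is the
consistency check the test suite enforces to $10^{-10}$.

Quiescent/arrested states, sublethal damage repair, fractionated
schedules, vascular radiation damage, and cancer-stem-cell dynamics are all
out of scope.

## Parameters, units, defaults

| Parameter | Meaning | Unit | Default |
|---|---|---|---|
| $\alpha$ | LQ radiosensitivity | 1/Gy | fitted (0.05–0.30 typical) |
| $\alpha/\beta$ | LQ dose ratio | Gy | 10 |
| $T^*$ | characteristic (cell-cycle) time | d | 1 |
| $T_m$ | colony-counting time ($\approx$ 10 cycles) | d | 10 |
| $T_d(0)$ | initial volume doubling time, $\lambda(0)=\ln2/T_d(0)$ | d | fitted |
| $\theta$ | vascular growth retardation factor | — | fitted |
| $\tau_{rad}$ | active radiation-effect time | d | 8 (working range 3–10) |
| $T_{cl}$ | cell clearance time, $\eta_{cl}=\ln2/T_{cl}$ | d | fitted |

$\tau_{rad}$ is deliberately **not** a fitting parameter. Doses for the
clinical fixtures are mean target doses; dose heterogeneity inside the
target is ignored. `ln 2` is used exactly (not 0.693); the difference is
far below parameter-rounding noise.

### A sign convention worth documenting

The growth-rate decay is implemented as
$d\lambda/dt = -(1-\theta)\lambda(0)\lambda$. An alternative convention
with coefficient $\theta\lambda(0)$ circulates in the two-compartment
literature, but it is inconsistent with the derivation from
$\lambda_v = \theta\lambda$: the rate of change of $\lambda$ is the
*difference* of the specific growth rates, $(\theta - 1)\lambda(0)$. The
$(1-\theta)$ form is also the only one that makes a $\theta \to 1$ tumor
keep growing essentially exponentially (as the progressive-disease fixture
requires) and that reproduces the fixtures' printed pre-treatment volumes
and 40-day response ratios. The self-consistent nonlinear variant
$d\lambda/dt = -(1-\theta)\lambda^2$ (no linearization at $t=0$) was
considered and rejected as the default: the linearized form is what the
closed forms and fixture parameters assume.

### The doubling-time override

Clinical fixtures carry the *observed* doubling time at radiosurgery
(`td_at_treatment`). For several cases it cannot be produced by exponential
decay from $T_d(0)$ — the two printed rows are mutually inconsistent —
while the printed volumes at radiosurgery *are* consistent with decay from
baseline. The simulator therefore supports an override: at $t_R$,
$\lambda_R$ is set to $\ln 2/$`td_at_treatment` when present. Reproducing
the 40-day response ratios uses the override; full-curve simulation from
baseline does not need it. Case 4's printed ratio (0.69) is not
recoverable from its printed parameters under any convention we tested
(recomputed $\approx 0.60$) and is excluded from the acceptance checks, as
are the printed AIC column and percent-cell-survival rows, whose exact
definitions could not be reconstructed; the MSD/AIC *arithmetic* is
unit-tested against hand examples instead.

## Numerical choices

* **Closed-form engine by default.** Every phase is linear with constant or
  exponentially-relaxing coefficients, so the trajectory is evaluated
  exactly: Gompertz form in phase 1, matrix-free scalar exponentials in
  phase 2 (with the $a = -\eta_{cl}$ degenerate limit switched in below
  $|a+\eta| < 10^{-12}$), exponential-integral factors in phase 3. Output
  is therefore grid-independent.
* **Cross-check integrator.** `integrate_numeric()` is an adaptive
  embedded Cash–Karp RK4(5) (relative tolerance $10^{-10}$) that restarts
  at both phase boundaries. The system is smooth and non-stiff within each
  phase at physiological rates, so an explicit pair suffices; the original
  analysis used a stiff solver, but stiffness there came from
  non-dimensionalization, not from the dynamics at these parameter values.
  The acceptance suite requires closed-form/numeric agreement to $10^{-6}$
  over 200 days for all ten fixtures (observed: $\sim 5\times 10^{-10}$).
* **Equations are solved in physical units** (days, cm³) rather than
  non-dimensionalized — mathematically equivalent and simpler to
  serialize.
* **Simulated annealing schedule.** The estimation literature behind the
  fixtures specifies only "simulated annealing, $10^5$ steps" with bounds
  $\alpha \in (0.01, 0.2)$, $\theta \in (0,1)$, $T_d \in (0.5, 15)$,
  $T_{cl} \in (1, 50)$. We use: uniform random initial point, Gaussian
  proposals with per-parameter standard deviation 5% of the bound width
  reflected at the bounds, initial temperature equal to the initial
  objective value, and geometric cooling to $10^{-4}$ of it over the run.
  These are standard, reproducible choices; recovery tests show the
  schedule is not load-bearing. The seed is a required argument and the
  global RNG state is restored on exit.
* **Off-grid metric evaluation** interpolates linearly in log-volume,
  matching the locally exponential structure of the model.
* **$p(D)$ clamping.** $\chi > 3T_m/T^*$ would make $p$ negative; it is
  clamped to 0 with a warning rather than an error because optimizer
  excursions can transiently violate the bound.

## The synthetic-data generator

`synthesize_observations()` stands in for caliper or MRI measurements (the
original animal series exist only as a published figure, which this package
does not digitize). Two noise modes:

* `multiplicative_lognormal` (default): each true volume is scaled by a
  mean-one lognormal factor with coefficient of variation `cv`.
  Multiplicative noise is the realistic choice — both caliper and
  MRI-delineation errors scale with tumor size. The recovery tests use
  `cv = 0.05`, a typical relative volumetric uncertainty for
  contrast-enhanced MRI of small metastases.
* `sphere_radius`: the radius of the volume-equivalent sphere is perturbed
  by Uniform($-dr$, $+dr$) (default spirit: $dr = 1$ mm) and the volume
  recomputed — mirroring how ±1 mm equivalent-sphere error bars are
  constructed for MRI volumes. The uniform law is our choice; only the
  ±`dr` support is externally specified.

Observation grids are uniform over the plotted 0–40 day range of the
animal experiment (the true measurement days are not published), with the
original per-dose point counts (11/11/19/18/14) available as fixture
metadata. What a green recovery test establishes: the four-parameter model
is locally and practically identifiable from 18 noise-free or mildly noisy
points on this design. What it does not establish: identifiability under
real measurement schedules (sparse, irregular, censored), under model
misspecification, or for parameter regimes far from the fixtures.

## Known limitations

* $\theta$ is a single constant; the data behind the fixtures suggest the
  effective $\theta$ differs before and after irradiation.
* The same $\alpha$ that fits post-radiosurgery volume curves sits below
  the usual clonogenic range (0.1–0.3/Gy), likely because the mean dose
  under-represents a highly non-uniform dose distribution; interpret
  fitted $\alpha$ as an effective parameter.
* The predictor-screening p-values (`quadratic_regression_pvalue()`) are
  overall-regression F-tests by default; the originating analysis tool's
  definition is ambiguous, so a coefficient-wise t-test variant is exposed
  via `method = "coefficient_t"` and neither is asserted to match printed
  values exactly — only the qualitative significance calls.
* Five clinical cases is far too small a sample for confirmatory claims
  about $\alpha$ or $\theta$ as outcome predictors; the metrics here are
  screening tools.

## A minimal session

```{r example, eval = FALSE}
cfg <- clinical_case_configs()[[5]]          # progressive disease, theta = 0.99
traj <- simulate_response(cfg, seq(0, 70, 0.5))
r40(traj, t_r = cfg$treatment$t_r)           # ~9.8: volume grows 10-fold

obs <- synthesize_observations(rat_case_configs()[[4]],
                               seq(0, 40, length.out = 18),
                               noise_spec(cv = 0.05, seed = 1))
fit_simulated_annealing(obs, fit_spec(steps = 100000, seed = 2),
                        rat_case_configs()[[4]])
```
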