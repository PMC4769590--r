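# gomprad

Two-compartment tumor-volume kinetics under single-fraction irradiation:
simulation, parameter fitting, model scoring, and outcome metrics.

## The problem

After a single large radiation fraction — the setting of Gamma Knife
stereotactic radiosurgery (GKSRS) for brain metastases, or classic
single-dose animal experiments — the imaged tumor volume does not drop
instantly. Irradiated cells keep dividing for a few more cell cycles before
they die, and the dead-cell mass is cleared away only slowly, so the
measured volume can plateau or even rise before it shrinks. At the same
time, untreated tumor growth is not exponential: growth decelerates as the
tumor outruns its vasculature. `gomprad` is for modelers and radiation
oncology researchers who want a minimal mechanistic model that captures both
effects, can be fitted to a handful of volume measurements, and yields
interpretable parameters (radiosensitivity α, vascular retardation θ,
doubling time T_d, clearance time T_cl) that may act as outcome predictors.

## The model

Tumor volume is the sum of dividing cells V_T and non-dividing cells V_ND.
Before treatment:

    dV_T/dt = λ(t) V_T,      dλ/dt = −(1−θ) λ(0) λ,      λ(0) = ln2 / T_d(0)

θ ∈ (0, 1] is the ratio of the vascular to the tumor specific growth rate;
θ < 1 yields the closed-form Gompertz solution
V(t) = V₀ exp[(1 − e^{−(1−θ)λ(0)t})/(1−θ)]. A dose D at time t_R opens an
active radiation-effect window of length τ_rad during which λ is frozen at
λ_R and

    dV_T/dt  = (λ_R p(D) − g(D)) V_T
    dV_ND/dt = g(D) V_T − η_cl V_ND

with p(D) = 1 − (T*/3T_m) χ(D), g(D) = χ(D)/(3T_m), and
χ(D) = αD(1 + D/(α/β)) the linear-quadratic lethality exponent;
η_cl = ln2/T_cl. After the window, p → 1, g → 0, λ resumes its decay, and
V_ND drains to zero. The observable (CEMRI / caliper) volume is V_T + V_ND,
continuous everywhere. The conventional instantaneous-kill model (V_T jumps
by the survival fraction e^{−χ} at t_R) is included as a comparator.

Fitting minimizes Σ(yᵢ − ŷᵢ)² over (α, θ, T_d, T_cl) by simulated
annealing; fits are scored by the mean squared relative difference
MSD = (1/N) Σ((ŷ−Y)/Y)² and AIC = N ln(MSD) + 2k. The post-treatment
endpoint R₄₀ is the total volume 40 days after irradiation over the volume
at irradiation.

## Worked example

```r
library(gomprad)

cfg <- clinical_case_configs()[[1]]   # GKSRS case 1: 38.3 Gy at day 34
cfg
#> <case_config 'gksrs-case-1'>
#> Growth params: v0 = 0.126 cm^3, Td(0) = 29 d, theta = 0.62
#> Radiobiology constants: alpha = 0.09 /Gy, alpha/beta = 10 Gy, T* = 1 d, Tm = 10 d
#> Treatment: 38.3 Gy at day 34, tau_rad = 8 d, T_cl = 13 d
#> Doubling-time override at t_R: 32.6 d

traj <- simulate_response(cfg, seq(0, 80, by = 0.5))
head(subset(as.data.frame(traj), t_days >= 34), 3)
#>    t_days   v_t_cm3   v_nd_cm3 lambda_per_day v_total_cm3
#> 69   34.0 0.2535186 0.00000000     0.02126218   0.2535186
#> 70   34.5 0.1929990 0.06071918     0.02126218   0.2537181
#> 71   35.0 0.1469265 0.10534620     0.02126218   0.2522727

case_metrics(cfg)
#>          label       r40 survival_after_effect td_at_treatment_days v_at_treatment_cm3
#> 1 gksrs-case-1 0.1539902            0.01273357             32.6              0.2535186
```

At irradiation the tumor is 0.254 cm³; only 1.3% of the dividing
compartment survives the 8-day effect window, and 40 days after treatment
the total volume is down to 15.4% of its value at treatment (printed
clinical value: 0.16) — a complete responder.

Fitting synthetic noisy data recovers the generating parameters:

```r
cfg <- rat_case_configs()[[4]]        # 30 Gy rat case: alpha=0.16, theta=0.795
obs <- synthesize_observations(cfg, seq(0, 40, length.out = 18),
                               noise_spec(cv = 0.05, seed = 101))
fit <- fit_simulated_annealing(obs, fit_spec(steps = 100000, seed = 201), cfg)
fit$best_params
#>     alpha     theta       td0      t_cl
#> 0.1795069 0.8255146 1.4613507 4.0086228
```

A command-line interface (`inst/cli/gomprad`) exposes `simulate`, `fit`,
`metrics`, `synth`, and `cases`; ready-to-run JSON configurations for all
ten bundled cases live in `inst/extdata/cases/`.

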