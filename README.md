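# packinetics

Kinetic modelling and parameter estimation for the batch enzymatic
production of (R)-phenylacetylcarbinol (PAC), the chiral precursor of
ephedrine. Pyruvate decarboxylase (PDC) couples benzaldehyde and
pyruvate by its carboligase side-activity; in phosphate (Gomori)
buffer the enzyme's decay is partly offset by a buffer-dependent
stabilisation. This package is for biochemical engineers and modellers
who want to simulate such batch biotransformations, estimate the rate
constants from time-course data, and validate them on held-out runs.

## The model

Six coupled ODEs describe PAC (`P`), pyruvate (`A`), benzaldehyde
(`B`), acetaldehyde (`Q`), acetoin (`R`) and the relative carboligase
activity (`E`, %):

```
dP/dt = V_p · [K_b·B^h / (1 + K_b·B^h)] · [A / (K_ma + A)] · E
dA/dt = -dP/dt - dQ/dt - 2·dR/dt
dB/dt = -dP/dt
dQ/dt = V_q·A·E - V_r·A·Q·E
dR/dt = V_r·A·Q·E
dE/dt = 0                                   for t <  t_lag
dE/dt = -(k_d1 + k_d2·B)·E + k_a·Ph_b       for t >= t_lag
```

PAC formation combines cooperative (Hill-type, h ≈ 2) benzaldehyde
binding with Michaelis–Menten pyruvate saturation, driven by the
enzyme activity. The enzyme deactivates at a first-order rate with a
benzaldehyde-dependent term, gains stability at a zeroth-order rate
`k_a·Ph_b` proportional to the phosphate buffer concentration, and is
fully stable during an initial refolding lag `t_lag`.

Trajectories are integrated by the explicit Euler–Cauchy scheme
(default step 0.6 min = 0.01 h, with the grid split exactly at
`t_lag`). Parameters are estimated by minimising the total residual
sum of squares `RSS_T` across all measured species and profiles with a
multiplicative grid search (coordinate sweeps over a multiplier
ladder, pattern-extrapolation moves, a profiled outer grid over the
weakly identified pyruvate affinity `K_ma`, and a <1 % relative
improvement stopping criterion). Fit quality is reported as `RSS_T`,
`MSE = RSS_T / DOF` with `DOF = 48 − 10 = 38` observations minus
parameters per profile, and `R² = 1 − RSS_T/TSS_T`.

## Worked example

Simulate the strongest condition pair (100/120 mM
benzaldehyde/pyruvate, 250 mM buffer) at the optimised constants,
then recover those constants from synthetic data:

```r
library(packinetics)

params <- pac_parameters_optimized()
cond   <- pac_study_conditions("100/120")
traj   <- simulate_pac(params, cond)
sampled_states(traj)
#>   time_min pac_mM pyruvate_mM benzaldehyde_mM ...
#> 1        0   0.01       116             100
#> 2       30  54.8         55.0            45.3
#> ...
#> 8      210  86.6         14.2            13.4
```

PAC climbs to ~86.6 mM while both substrates deplete and the enzyme
activity decays from 114 % to ~30 %. The full estimation workflow on
synthetic ground-truth data:

```r
truth <- pac_parameters_optimized()
profs <- list(generate_noiseless_profile(truth, pac_study_conditions("30/36")),
              generate_noiseless_profile(truth, pac_study_conditions("100/120")))
fit <- grid_search_fit(profs, start = pac_parameters_initial())
glance(fit)
#>       RSS_T         MSE   DOF    R2 RSS_T_start n_profiles converged
#> 1 0.0000160 0.000000421    76 1.000      50448.          2 TRUE
```

The search drives `RSS_T` from 50,448 down to 1.6e-5 (a ~3e9-fold
reduction) and returns `V_p`, `h`, `k_d1` within 1 % and `K_ma` within
8 % of the generating values (`tidy(fit)` lists all ten). Validation
against a held-out synthetic 50/60 profile:

```r
val <- generate_noiseless_profile(truth, pac_study_conditions("50/60"))
validate_fit(fit, val)
#>   profile     RSS_T   DOF         MSE    R2
#> 1 50/60   0.0000229    38 0.000000602 1.000
```

`autoplot()` methods draw trajectories, observed profiles and
observed-vs-fitted panels; `run_study()` orchestrates fit, validation
and a JSON report in one call.

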