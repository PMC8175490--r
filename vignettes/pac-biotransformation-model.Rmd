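---
title: "Modelling batch PAC biotransformation with phosphate-buffer enzyme activation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling batch PAC biotransformation with phosphate-buffer enzyme activation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(packinetics)
```

## The process and the model

(R)-phenylacetylcarbinol (PAC) is produced in batch by the carboligase
side-activity of pyruvate decarboxylase (PDC): one benzaldehyde and one
pyruvate condense to PAC, while direct decarboxylation of pyruvate
releases acetaldehyde, two units of which can further condense to
acetoin. The enzyme itself is a reagent that decays over the reaction,
and in phosphate (Gomori) buffer the buffering species partly stabilise
it. The package models one stirred batch run with six states — PAC
`P`, pyruvate `A`, benzaldehyde `B`, acetaldehyde `Q`, acetoin `R`
(all mM) and the relative carboligase activity `E` (% of a reference
volumetric activity):

$$\frac{dP}{dt} = V_p\,\frac{K_b B^h}{1 + K_b B^h}\,\frac{A}{K_{ma}+A}\,E,
\qquad \frac{dB}{dt} = -\frac{dP}{dt},$$

$$\frac{dQ}{dt} = V_q A E - V_r A Q E,\qquad
\frac{dR}{dt} = V_r A Q E,\qquad
\frac{dA}{dt} = -\frac{dP}{dt}-\frac{dQ}{dt}-2\frac{dR}{dt},$$

$$\frac{dE}{dt} = \begin{cases}
0 & t < t_{lag}\\[2pt]
-(k_{d1} + k_{d2} B)\,E + k_a\,\mathit{Ph}_b & t \ge t_{lag}.
\end{cases}$$

Assumptions worth stating explicitly:

* **Benzaldehyde binds cooperatively** (Hill exponent `h`, physically
  sensible range 1–3; values near 2 point to a dimeric operating
  form), pyruvate follows ordinary Michaelis–Menten saturation.
* **The enzyme is the driving force**: every formation rate is
  proportional to `E`, so simulated product curves flatten as the
  enzyme decays, not only as substrates deplete.
* **Stoichiometry is hard-wired**: `B + P` and `A + P + Q + 2R` are
  linear invariants of the equations. The explicit Euler scheme
  preserves them exactly (to floating-point round-off), which the test
  suite asserts at every step.
* **The activation term multiplies the buffer concentration**
  `Ph_b`, not a reaction species. `k_a` originates from
  buffer-stability experiments, its unit is % min⁻¹ mM⁻¹ of buffer,
  and only this reading reproduces the reported activation rate at
  250 mM buffer (9.38×10⁻⁶ × 250 = 2.345×10⁻³ % min⁻¹). A reading
  that multiplies the PAC concentration instead is dimensionally
  admissible but inconsistent with that arithmetic, so the package
  rejects it.
* **No volatilisation, no side oxidation**: losses of acetaldehyde or
  benzaldehyde to the gas phase and benzyl-alcohol side reactions are
  outside the model. Temperature, pH and cofactor (TPP/Mg²⁺) effects
  are absorbed into the constants.

## Parameters, units, defaults

| constant | meaning | unit | start | optimum |
|---|---|---|---|---|
| `V_p` | PAC formation rate constant | mM·min⁻¹·%⁻¹ | 1.55e-2 | 6.71e-2 |
| `K_b` | benzaldehyde binding constant | mM^(1−h) | 9.00e-5 | 1.01e-4 |
| `h` | Hill coefficient | — | 1.98 | 1.94 |
| `K_ma` | pyruvate affinity | mM | 4.84 | 0.70 |
| `V_q` | acetaldehyde formation | min⁻¹·%⁻¹ | 6.38e-6 | 1.68e-5 |
| `V_r` | acetoin formation | min⁻¹·mM⁻¹·%⁻¹ | 9.88e-7 | 6.06e-6 |
| `k_d1` | background deactivation | min⁻¹ | 8.89e-3 | 5.99e-3 |
| `k_d2` | benzaldehyde deactivation | min⁻¹·mM⁻¹ | 3.30e-5 | 1.33e-5 |
| `k_a` | buffer activation | %·min⁻¹·mM⁻¹ | 1.34e-5 | 9.38e-6 |
| `t_lag` | refolding lag | min | 1.00 | 0.42 |

`pac_parameters_initial()` is the literature-derived starting point of
the search; `pac_parameters_optimized()` is the optimum against the
30/36 and 100/120 mM benzaldehyde/pyruvate profiles in 250 mM buffer
and serves as ground truth for all synthetic experiments.
`pac_study_conditions()` carries the measured initial states of the
three condition pairs (e.g. `E₀` 89.4–114 %, `P₀` 0.01 mM, by-products
zero).

## Integration scheme

Trajectories use the explicit Euler–Cauchy scheme. The default step is
0.6 min — the study's stated increment of 0.01 h; all rate constants
are per minute, so a 0.01 *min* reading is also admissible and both
satisfy the convergence check below. Two scheme details matter:

* the integration grid is split exactly at `t_lag`, so the
  deactivation branch switches at the lag boundary rather than at the
  nearest grid node (with `t_lag` = 0.42 min and step 0.6 min the very
  first step is the one split);
* a state driven below zero by an Euler overshoot near substrate
  depletion is clamped to zero; a clamp larger than 0.1 mM raises a
  step-size warning. Clamping never triggers under the study
  conditions.

Verification is two-fold and runs in the test suite: halving the step
changes every sampled concentration by < 0.5 %, and all sampled states
of the three study conditions agree with an adaptive high-order
integrator (`deSolve::lsoda` at `rtol` 1e-10) within 1 % (worst case
0.94 %, benzaldehyde at 30 min of the 100/120 pair, where the
transient is fastest). A plain-R implementation of the same scheme is
kept alongside the compiled core (`simulate_pac(engine = "R")`) and
the two are cross-checked to 1e-12.

## The objective and its bookkeeping

`rss_breakdown()` sums unweighted squared residuals between replicate
means and the simulation, per species, at the sampling times. Three
conventions are deliberate:

* **PAC residuals are included by default.** The five-term form
  (substrates, by-products, enzyme) is available via
  `include_pac = FALSE`; the package defaults to including the product
  because the objective is described as covering product formation,
  and fitting a product model without product residuals is not
  defensible.
* **DOF = 48 − 10 = 38 per profile** (8 sampling times × 6 measured
  quantities minus 10 constants). All published per-profile RSS/MSE
  pairs are exactly consistent with this convention (936/24.6,
  2526/66.5, 662/17.4).
* **Combined MSE is the sum of per-profile MSEs** (24.6 + 66.5 =
  91.1), not the pooled ratio (which would give 40.3); the summed
  convention is the only one consistent with the published combined
  value, so the package adopts it for combined statistics.
* **R²** is nowhere defined in the source material; the package uses
  `1 − RSS_T/TSS_T` with the total sum of squares about each species'
  own mean, summed over species — the standard multi-response choice.
  Published R² values are not recomputable without the raw data, so
  they are not asserted anywhere.

Because residuals are unweighted, enzyme points (tens of %) and
concentration points (tens of mM) contribute on their natural scales —
this mirrors the original objective and is a known limitation, not an
accident.

## Grid-search design

The study describes its estimation as a grid search with a convergence
search criterion (CSC) of < 1 % relative `RSS_T` improvement, without
algorithmic detail. The package's `grid_search_fit()` is therefore its
own design, documented here and configurable via `search_control()`:

1. **Coordinate sweeps on a multiplier ladder.** Each parameter in
   turn is scanned over `value × {0.5, 0.8, 0.9, 0.95, 1.05, 1.1,
   1.25, 2}`; the best improving candidate is accepted. Candidates
   outside the bounds (default: three decades either side of the
   start, `h` restricted to (1, 3], `t_lag` to one sampling interval)
   are never evaluated.
2. **Pattern moves.** After every sweep the net log-scale displacement
   of the sweep — and of the last 5 and 20 sweeps — is amplified by
   factors {1, 2, 4, 8, 16} while it keeps improving. Axis-aligned
   sweeps alone zig-zag in the curved valleys this objective has
   (notably the `V_p`–`K_ma` and `K_b`–`h` compensations); pattern
   extrapolation is the classical pattern-search remedy.
3. **Ladder contraction and stopping.** When a sweep improves by less
   than `shrink_tol` the ladder contracts by square roots towards 1;
   the CSC (1 %) stops the search only once the ladder is fully
   contracted, so the criterion is judged at the finest grid rather
   than on a coarse-grid stall.
4. **Profile refinement of `K_ma`.** With pyruvate never falling near
   `K_ma` under the study conditions, the saturation factor stays
   ≈ 1 and `K_ma` is nearly unidentifiable pointwise — free searches
   reliably fall into a spurious `K_ma → 0` valley with `V_p`
   compensating. The fit therefore profiles `K_ma` over an absolute
   log-spaced grid (inner refits with `K_ma` clamped), refines the
   grid around the winner down to ~4 % spacing, and finishes with an
   all-free polish. This is still a purely evaluation-based grid
   method: no gradients, no stochastic moves.

On noiseless synthetic data generated at the optimised constants
(30/36 + 100/120 pairs), this procedure started from the literature
values reduces `RSS_T` by ~9 orders of magnitude and recovers `V_p`,
`h`, `k_d1` within 1 % and `K_ma` within 8 %; `K_b`, `V_q`, `V_r`
come back within a few percent, while `t_lag` is only determined to
within an integration step and `k_a` to within a few percent. These
problem sizes (two fitting profiles of 48 points, ~10⁵ objective
evaluations, ≈ half a minute) are the package's chosen test scale.

`validate_fit()` simulates with frozen parameters under a held-out
profile's conditions and reports the same statistics; on a noiseless
synthetic 50/60 profile the workflow yields R² > 0.999.

## Parameter standard errors

The original error-estimation procedure lives in an external reference
and is not reproducible from the available description. The package
substitutes a transparent scheme, clearly labelled in its reports:
refit against the observation sets shifted to `mean + SE` and
`mean − SE`, and report half the absolute range of each parameter's
two refitted values. This measures sensitivity to a *coherent* shift
of all observations. It tracks a parametric bootstrap for the
noise-dominated constants (`V_q`, `V_r`, `k_d2`, `k_a`; within a
factor of ~3 in the test suite) but *understates* the uncertainty of
the valley-coupled constants (`V_p`, `K_ma`, `h`, `K_b`), whose
bootstrap spread is dominated by the compensation directions rather
than by observation noise. Treat the reported errors as lower bounds
for those constants.

## The synthetic-data generator

No machine-readable observations ship with the package, so
`generate_noisy_dataset()` emulates the study design: three
benzaldehyde/pyruvate pairs (30/36, 50/60, 100/120 mM; nominal molar
ratio 1.2), 250 mM buffer for the kinetic profiles (the full buffer
series 20–1000 mM is carried as design metadata), eight sampling times
(0–210 min every 30 min), quintuplicate replicates, and initial
enzyme activity between 89 and 114 %. Replicates are drawn as
`truth + N(0, max(cv·truth, floor))` with CV 2 % and floors of 0.1 mM
(concentrations) and 0.5 % (activity) — the error bars of the original
profiles are described only as relatively small, so these magnitudes
are the package's own calibration, chosen once as a realistic HPLC /
enzymatic-assay regime and exposed in `noise_model()`. By default the
generator also zeroes the by-product observations, emulating levels
below the detection limit, as reported for the real runs. One master
seed derives per-profile child seeds by fixed offsets, and the global
RNG state is saved and restored, so datasets are pure functions of
`(params, design, noise, seed)`.

What passing tests on these data do **not** show: robustness to
benzaldehyde evaporation or acetaldehyde volatilisation, to
heteroscedastic or correlated assay errors beyond the CV-plus-floor
model, or to model misspecification — the generator draws from the
same equations the fit assumes.

## Degenerate inputs and tie-breaks

* `P_max` ties take the earliest sampling time (this matters for
  yields when the product plateaus); molar yields use substrate
  consumed *at that time*, not at the end of the run.
* The reaction time rounds `P_max / r_Pmax` to the nearest multiple of
  the sampling interval, half-up (180.42 → 180; a midpoint like 45/1
  with a 30-min grid rounds to 60).
* Zero substrate consumption with nonzero `P_max` is an explicit
  undefined-yield error; yields slightly above 1 (possible with the
  nonzero `P₀` of the measured initial states) are logged, and capped
  nowhere.
* Construction accepts zero-valued rate constants (a switched-off
  pathway is a legitimate simulation scenario); strict positivity and
  `1 < h ≤ 3` are enforced as *fitting bounds*.
* A `t_lag` of exactly 0 disables the lag branch from the first step.

## Known limitations

* Batch only: no fed-batch or continuous feeding, no two-phase or
  organic-solvent systems, no temperature/pH dependence, no
  mechanistic cofactor model.
* The fixed-step Euler scheme is the method of record here; it is
  accurate to ~1 % at the default step under the study conditions, but
  stiff parameter regions (very large rate constants) rely on the
  clamp-and-warn safeguard rather than on step adaptation.
* `K_ma` recovery depends on the profile-refinement stage; with
  substrate always ≫ `K_ma` the data simply carry little information
  about it, and on noisy data its reported error should be read with
  the caveats above.
* Statistical comparison of summary metrics across buffer/substrate
  groups (multiple-range testing) is out of scope.
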