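# vblpbpk

A physiologically based pharmacokinetic (PBPK) simulator for the vinca
alkaloid **vinblastine**, scaled across mouse (wild-type and Mdr1a/b(−/−)
knockout), dog and human. It is aimed at pharmacokineticists and
comparative-oncology researchers who want a mechanistic, parameter-level
handle on what drives vinblastine exposure — tissue tubulin binding, ABCB1
(P-glycoprotein) efflux, CYP3A metabolism, biliary excretion and glomerular
filtration — and at modellers who need a compact, fully scriptable PBPK
code base to calibrate against their own data.

## The model

Nine compartments: a central blood pool, lung (in series on the central
path), brain (vascular + tissue sub-compartments at the blood–brain
barrier), bone marrow, kidney, liver, gut, and slowly/rapidly perfused
lumped tissues. Except for the brain, tissues are flow-limited:

    dA_T/dt = Q_T (C_A − C_v),      C_T = C_v (PC + BC/(K_D + C_v))

so venous outflow carries the free concentration `C_v`, obtained from the
total tissue concentration `C_T` by inverting a saturable tubulin-binding
relation with capacity `BC` (nmol/kg), affinity `K_D` (nM) and a linear
partition coefficient `PC`. The brain is permeability-limited with a
PSA barrier term and ABCB1 efflux back to the vascular space:

    V_CNS dC_CNS/dt = PSA (C_BB − C_v,CNS) − SF_CNS V_CNS Vmax C_v,CNS/(Km + C_v,CNS)

Elimination is hepatic metabolism and biliary excretion (both
Michaelis–Menten, driven by the liver free concentration) plus glomerular
filtration (`GFR × Q_KID × C_A`). Scenarios switch the configuration:
`mdr1a1b_knockout` zeroes ABCB1 efflux and swaps in the knockout biliary
kinetics; `cyp3a_induction_2x` doubles metabolic capacity (omeprazole-type
induction). Monte Carlo virtual populations draw physiologic and
biochemical parameters from rank-correlated lognormals (sd of logs 0.2).

## Worked example

```r
library(vblpbpk)

phys <- default_physiology("mouse")               # 0.025 kg FVB mouse
wt   <- default_drug_parameters("mouse")          # wild-type parameter set
ko   <- apply_scenario(wt, "mdr1a1b_knockout")    # ABCB1 knockout
dose <- dose_event(mg_per_kg = 2)                 # single IV bolus

sim_wt <- simulate_iv_bolus(phys, wt, dose, t_end = 6)
sim_ko <- simulate_iv_bolus(phys, ko, dose, t_end = 6)

rbind(nca(sim_wt), nca(sim_ko))                   # serum NCA, 0-6 h
#>   tissue source t0 t1 auc_nM_h t_half_h n_terminal_points regression_r2
#> 1  blood  mouse  0  6     1805    2.031                 3             1
#> 2  blood  mouse  0  6     1844    2.464                 3             1

nca(sim_series(sim_ko, "brain_tissue"))
#>         tissue ... auc_nM_h t_half_h ... reason
#> 1 brain_tissue ...     7567       NA ... terminal phase not achieved: ...
```

Serum exposure barely changes between genotypes (1805 vs 1844 nM·h over
0–6 h, terminal half-lives 2.0 vs 2.5 h), while knockout brain tissue
accumulates steadily — no terminal phase within 6 h, and a
knockout:wild-type brain AUC ratio of 6.6. That order-of-magnitude brain
contrast at unchanged serum is the signature of barrier-restricted ABCB1
efflux. Mass balance closes to solver precision
(`mass_balance_error(sim_wt)` ≈ 2e-15).

Synthetic observations and predictive-performance metrics:

```r
obs <- generate_observations(sim_wt, default_schedule("mouse"),
                             noise_model(cv = 0.15),
                             tissues = c("blood", "kidney"), seed = 1)
performance_by_group(obs, sim_wt)
#>    group  n mape  mpe rmspe
#> 1  blood 18 8.94 3.91  14.0
#> 2 kidney 18 8.07 0.16  12.4
```

MAPE (median absolute prediction error) measures precision, MPE (median
signed error) bias, RMSPE accuracy; here they simply recover the 15%
generating noise with no bias, as they should when scoring a simulation
against data sampled from itself.

Calibration and virtual populations follow the same grammar: `fit_model()`
estimates selected parameters (dotted paths such as `"drug.PC.kidney"`) by
bounded nonlinear least squares through the simulator, and
`sample_population()` / `run_population()` generate and summarize
100-subject Monte Carlo cohorts. A thin CLI over simulate/NCA/metrics
lives in `inst/cli/vblpbpk.R`.

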