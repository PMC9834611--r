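---
title: "Methods: a physiologically based pharmacokinetic model of vinblastine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a physiologically based pharmacokinetic model of vinblastine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vblpbpk)
```

## The model

Vinblastine is a vinca-alkaloid microtubule poison whose disposition is
dominated by four processes: intracellular binding to tubulin, efflux by the
ABCB1 (P-glycoprotein) transporter, CYP3A-family metabolism in the liver,
and renal/biliary excretion. `vblpbpk` implements a whole-body
physiologically based pharmacokinetic (PBPK) model built around exactly
these processes, with nine compartments: a central blood pool, lung, brain
(split into vascular and tissue sub-compartments at the blood–brain
barrier), bone marrow, kidney, liver, gut, and lumped slowly and rapidly
perfused tissues. All tissue densities are taken as 1 kg/L, so a tissue's
volume in litres equals its mass in kilograms, and binding capacities
quoted per kilogram of tissue can be used directly as nmol/L.

### Flow-limited tissues with saturable tubulin binding

Every tissue except the brain is well stirred and flow limited: the drug
amount changes as

$$\frac{dA_T}{dt} = Q_T\,(C_A - C_{v,T}),$$

where $Q_T$ is the tissue blood flow, $C_A$ the arterial (blood-pool)
concentration, and $C_{v,T}$ the concentration in venous outflow. The
venous concentration equals the *free* tissue concentration, which is
linked to the total tissue concentration $C_T$ through a linear partition
coefficient $PC$ plus a saturable tubulin-binding site pool with capacity
$BC$ (nmol/kg) and dissociation constant $K_D$ (nM):

$$C_T = C_{v}\left(PC + \frac{BC}{K_D + C_{v}}\right).$$

`tissue_free_concentration()` solves this relation as a quadratic in
$C_v$, keeping the unique non-negative root. Two limits anchor the
behaviour: with $BC = 0$ the relation reduces to plain partitioning
($C_v = C_T/PC$), and as $C_T \to \infty$ the binding sites saturate and
the extra retention vanishes. The root is evaluated in a
cancellation-stable form (switching between the two equivalent quadratic
root expressions on the sign of the linear coefficient) so that it is
accurate from $10^{-3}$ to $10^{6}$ nM; the test suite checks it against
an independent fixed-point iteration to 1e-8 relative error across that
whole range.

### ABCB1 efflux

Gut and kidney carry a saturable efflux term
$SF_T\,V_T\,V_{max}\,C_v/(K_m + C_v)$, where $SF_T$ is the tissue's
relative ABCB1 expression (gut 0.14, kidney 0.78, brain 1.0, liver 0.28)
and $V_T$ the tissue volume — the volume factor makes a $V_{max}$ in
nmol/L/h yield nmol/h, dimensionally consistent with the brain equations.
Effluxed drug is routed by transporter physiology: gut efflux (intestinal
secretion) to the fecal sink, kidney efflux (tubular secretion) to urine.
Liver efflux *is* the biliary route and is handled by the elimination
terms below, which avoids double counting. Brain efflux returns drug from
brain tissue to the brain vascular space.

### Permeability-limited brain

The blood–brain barrier restricts exchange to a
permeability–surface-area product $PSA$ (0.379 ml/h by default):

$$V_{CNS}\frac{dC_{CNS,T}}{dt} = PSA\,(C_{BB} - C_{v,CNS})
  - SF_{CNS} V_{CNS} \frac{V_{max}C_{v,CNS}}{K_m + C_{v,CNS}},$$

with the complementary fluxes appearing in the vascular sub-compartment,
which is perfused by the brain's share of cardiac output. Brain volume is
split 97% tissue / 3% vascular. With efflux disabled
(the Mdr1a/b(−/−) knockout scenario) brain tissue accumulates steadily
over a 6 h window; with wild-type mouse efflux parameters the model keeps
brain exposure roughly an order of magnitude lower — the knockout:wild-type
brain AUC ratio in the shipped mouse configuration is ≈6.6, inside the
5–20 band asserted by the acceptance tests.

### Elimination

Three cumulative sinks close the mass balance:

* metabolism, $V_{LIV}\,V_{max,M}\,C_v/(K_{m,M}+C_v)$, driven by the
  liver free concentration and drawn from the liver amount;
* biliary excretion, the same Michaelis–Menten form with the biliary
  constants, scaled by the liver ABCB1 expression factor in wild-type
  configurations (where biliary transport is ABCB1-driven) and unscaled in
  the knockout (where the residual route is attributed to Mrp2);
* glomerular filtration, $GFR \cdot Q_{KID} \cdot C_A$, drawn from the
  blood pool, with $GFR = 0.11$ as the filtered fraction of renal blood
  flow.

Mass conservation — compartment contents plus the three sinks equal the
dose — holds to solver precision (~1e-13 relative) at every output time
and is asserted at 0.1% in the tests.

### The central path and the lung

The blood pool is a single well-mixed compartment; arterial and venous
mixing are not distinguished, and the reported serum concentration is the
blood-pool concentration (blood partition coefficient 1.0, no binding
capacity, no hematocrit correction). Tissue venous returns pass through
the lung — which carries total cardiac output in series and binds drug
with the lung tubulin capacity and a partition coefficient of 1.0 —
before re-entering the blood pool. Because the reference tissue-fraction
tables assign the lung no separate mass or flow share, its volume
(0.75% of body weight by default) is carved out of the rapidly perfused
pool, keeping total tissue volume conserved; `include_lung = FALSE` drops
the compartment entirely for sensitivity analyses.

## Parameters

Physiologies (`default_physiology()`) carry body weight (mouse 0.025 kg,
dog 25 kg, human 70 kg by default), hematocrit (stored as metadata only),
and per-tissue percent body weight and percent cardiac output. Cardiac
output defaults to the allometric law $16.5\,BW^{0.75}$ L/h — about
1.0 L/h for a mouse, 185 L/h for a dog and 400 L/h for a human — and can
be overridden per species. Drug parameters (`default_drug_parameters()`)
carry the tubulin $K_D$ (196.08 nM), per-tissue binding capacities and
partition coefficients, ABCB1/metabolism/biliary Michaelis–Menten
constants, $PSA$, and the GFR fraction; everything is converted at load
to a single internal unit system (nmol, L, h, nM). Tissues without an
optimized partition coefficient (lung, slowly and rapidly perfused)
default to 1.0, the same convention as the bone marrow and blood entries.
Plasma protein binding (~75%) is carried as metadata; an optional
unbound-fraction multiplier `fu` on the metabolic, filtration and barrier
driving concentrations is provided and defaults to 1, matching the base
equations.

Doses are IV bolus only, given per kg, absolute, or per m² of body
surface (converted with the canine relation $BSA = 0.101\,BW^{2/3}$), and
are implemented as an initial condition in the blood pool rather than an
impulse forcing, for solver robustness.

## Numerical choices

The ODE system is stiff immediately after a bolus (the blood pool starts
orders of magnitude above the binding and transport constants), so
integration uses `deSolve::ode` with `lsoda`, relative tolerance 1e-8 and
absolute tolerance 1e-10 nmol. Output grids are uniform with a fixed set
of 46 log-spaced early points always appended: the first minutes after a
bolus carry a concentration spike spanning several decades, and without
resolving it trapezoidal AUCs would change by tens of percent between a
101- and a 1001-point grid; with it they agree to better than 0.1%.

Noncompartmental analysis follows the linear-log trapezoidal convention:
log trapezoids on strictly declining positive segments, linear trapezoids
on rising, flat or zero-touching segments, with interval endpoints
interpolated consistently with the same rule so the AUC is exactly
additive. Terminal half-life is the log-linear regression slope over a
terminal window of positive concentrations after the observed maximum;
the default window is the last three points, with an adaptive best-r²
option and a trailing-fraction option. A non-negative fitted slope or an
insufficient point count yields an explicit "terminal phase not achieved"
result rather than an error, which is the correct outcome for
still-accumulating tissues such as the knockout brain.

Calibration (`fit_model()`) wraps bounded Levenberg–Marquardt
(`minpack.lm::nls.lm`) around the simulator, with residuals on the log
scale by default so that tissues whose concentrations span orders of
magnitude contribute comparably to a pooled objective. One subtlety is
essential: the finite-difference Jacobian step must sit well above the
integrator's noise floor, so `epsfcn` defaults to 1e-4 — with the library
default the gradient evaluates to zero and the optimizer reports
convergence at its starting values. Recovery runs are started from the
reference parameter values perturbed by a configurable factor (twofold in
the shipped tests). Model comparison uses
$AIC = n\ln(SSR/n) + 2k$ and $BIC = n\ln(SSR/n) + k\ln n$ on the fitting
scale. Michaelis–Menten fits of microsomal velocity data flag designs
whose fitted $K_m$ exceeds the tested substrate range as poorly
identified, since such designs pin only the ratio $V_{max}/K_m$.
Microsomal capacities are scaled to the liver with
$V_{max}$ [µmol/L liver/h] $= V_{max,mic} \cdot 60 \cdot
P_{mic}/(c_{protein} \cdot MW)$, i.e. per litre of liver, because the
elimination term multiplies by the liver volume itself.

Virtual populations draw each varied parameter from a lognormal centred
on its base value with `sd_log` 0.2 by default; a rank-correlation matrix
is imposed by Iman–Conover rank reordering against a correlated normal
reference, which fixes the Spearman correlation without touching the
marginals. The shipped varied-parameter set is body weight, cardiac
output, the optimized partition coefficients, metabolic $V_{max}$ and
$K_m$, ABCB1 $V_{max}$, and $PSA$, all independent; the set is
config-driven and the matrix defaults to identity. Draws are reproducible
from an integer seed. Envelope summaries (min, mean, SD, max) are
pointwise on the arithmetic scale.

## The synthetic-data generators

`generate_observations()` emulates the sampling structures of real
studies: destructive rodent designs (replicate animals per time point, six
times over 6 h, three animals each by default), longitudinal clinical
schedules (the shipped dog schedule samples 5 min–24 h), and sparse human
designs. Noise is lognormal with CV 0.15 for tissues and 0.10 for serum by
default — typical bioanalytical variability — and values below an
LLOQ-like floor are flagged censored rather than dropped, so the metrics
module can exercise its exclusion/substitution policies.
`generate_microsomal_dataset()` produces technical-doublet
velocity–substrate tables. The generators reproduce the *shape* of real
data (sampling design, multiplicative error, censoring); they do not
emulate inter-animal physiological variability, assay drift, or model
misspecification, so a passing recovery test demonstrates identifiability
under the stated design and noise, not accuracy on real animals.

## Problem sizes

The shipped tests and the acceptance script use 241-point output grids
(plus the early log refinement) for single simulations, 121-point grids
inside fitting loops and population runs, 100-subject Monte Carlo
populations, and parameter-recovery designs of 18 observations (6 times ×
3 replicates). These sizes were chosen so that grid-refinement changes
AUCs by well under 0.1% and population means are stable to a few percent
across seeds.

## Known limitations

* **Serum scale under flow-limited washout.** In a flow-limited model the
  tissue-to-serum AUC ratio at quasi-equilibrium cannot exceed
  $PC + BC/K_D$ (≈11 for kidney, ≈3 for bone marrow with the shipped
  parameters). Measured vinca-alkaloid tissue distributions routinely show
  late-time tissue:serum ratios far above this bound, because cellular
  retention of these drugs is effectively much stronger than rapid-
  equilibrium binding at these capacities implies (vinca alkaloids are
  retained by slowly dissociating, self-associating tubulin complexes and
  accumulate in platelets). The shipped parameter set therefore
  reproduces tissue exposures and serum terminal half-lives well while
  placing the absolute serum/plasma AUC scale several-fold above
  reference values; the structural alternatives we examined (a volume-free
  efflux term, blood-driven elimination, rescaled binding capacities)
  each repair part of this at the cost of breaking tissue exposures or
  half-lives, and were rejected. Users calibrating against their own serum
  data should treat the partition/binding block, or a kinetic
  (on/off-rate) binding extension, as the place to intervene.
* Metabolite kinetics (4-deacetylvinblastine), enterohepatic
  recirculation, oral absorption and multi-dose regimens are out of
  scope; all dosing is single IV bolus.
* Hematocrit is stored but unused: serum and whole-blood concentrations
  are identified with each other.
* The allometric cardiac-output law and the mouse body weight are
  conventional defaults, not fitted quantities; both are configurable.
* Population variability is parametric and independent by default; no
  covariate models are provided.
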