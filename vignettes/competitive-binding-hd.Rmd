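---
title: "Modelling competitive-binding augmented hemodialysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling competitive-binding augmented hemodialysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdbind)
```

## The problem

Hemodialysis removes only the free fraction of a solute: the membrane pores
pass small molecules but reject albumin, so a drug that is 85–90% bound
presents a very small diffusion gradient to the dialysate and clears
poorly. `hdbind` simulates an intervention for drug intoxications that are
normally considered poor dialysis candidates for exactly this reason: a
*binding competitor* — a second drug sharing the same albumin site — is
infused into the extracorporeal circuit just upstream of the dialyzer. In
the arterial line and along the fibers it displaces the toxic drug from
albumin, raising the free fraction where it matters (inside the dialyzer)
without raising the free concentration the patient's tissues see above its
pre-treatment value: whatever free drug is liberated is either dialysed out
or rebinds before the blood is returned.

The two reference intoxications are phenytoin (70 mg/L, Sudlow site I,
competitor 2000 mg aspirin in 500 mL saline) and carbamazepine (35 mg/L,
Sudlow site II, competitor 800 mg ibuprofen in 200 mL saline).

## Model structure

The model couples three sub-models, all tracking the same five species —
free toxic drug $T$, free competitor $D$, free albumin $P$, and the
complexes $PT$, $PD$ — with mass-action kinetics

$$P + T \rightleftharpoons PT, \qquad P + D \rightleftharpoons PD, \qquad
K_A = k_{on}/k_{off}.$$

**Patient.** Three well-mixed pools: plasma (3.5 L), interstitium (14 L),
intracellular water (28 L). Free drug exchanges plasma–interstitium with
coefficient $K_{ip}$ = 1200 mL/min and interstitium–cells with $K_{ic}$ =
100 mL/min; albumin and its complexes stay extracellular and do not cross
between pools. First-order elimination at rate $\lambda$ acts on *free
plasma* drug only (see calibration below). Compartment volumes are constant:
the poisoned patient has no fluid to remove, and the infused diluent volume
is taken back out along the dialyzer.

**Arterial tube segment.** Plasma leaving the patient at
$Q_{pl} = Q_b(1 - \mathrm{Hct})$ receives the infusion stream
($Q_D = $ diluent volume / session duration; bag concentration
$C_{inf}$ = dose/MW/volume) by flow-weighted mixing, then traverses the
segment by plug-flow advection while the binding equilibrium relaxes
(first-order upwind discretisation, 16 cells, no axial diffusion). The
infusion stream contains free competitor only.

**Dialyzer.** Counter-current hollow-fiber exchanger, method of lines with
64 axial cells. The plasma-side flow falls linearly from
$Q_{pl} + Q_D$ to $Q_{pl}$ (uniform ultrafiltration of the infused volume)
while the dialysate flow, entering solute-free at 500 mL/min, picks the
filtrate up. Transmembrane transport combines convection, weighted by
$(1-\sigma)$ with $\sigma = 0$ for free solutes and $0.999$ for albumin
species, and diffusion, $K_oA$ = 800 mL/min for free solutes and 0 for
albumin species, attenuated by the Péclet factor $Pe/(e^{Pe}-1)$. The
Péclet number is formed per axial segment as the ratio of convective to
diffusive transfer, $Pe = Q_D(1-\sigma)/K_oA$; with infusion rates around
1–2 mL/min against $K_oA = 800$, the factor is within a fraction of a
percent of unity, so the precise segment-vs-whole-device convention is
immaterial here. Binding reactions run in every cell on both sides.

The circuit starts solute-free (saline-primed) and fills from the patient
within the first transit; circuit holdup at session end is counted as
removed from the patient in the mass audit (rinse-back is not modelled).

## Parameters

| Parameter | Value | Origin |
|---|---|---|
| Compartments | 3.5 / 14 / 28 L, Hct 0.35 | reference 70 kg patient |
| Plasma albumin | 650 µM (4.3 g/dL) | reference scenario |
| Interstitial albumin | 260 µM (40% of plasma) | physiological default, see below |
| $K_{ip}$, $K_{ic}$ | 1200, 100 mL/min | reference values |
| $k_{on}$ | $10^8$ M⁻¹min⁻¹ both drugs | standard association rate; $k_{off}$ derived per drug |
| $K_A$ phenytoin / carbamazepine | derived: 1.56×10⁴ / 4.9×10³ M⁻¹ | from therapeutic binding (90% bound at 20 mg/L; 75% at 12 mg/L) |
| $K_A$ aspirin / ibuprofen | 1.90×10⁵ / 1.76×10⁵ M⁻¹ | literature constants |
| Half-lives (total) | 35 h / 25 h / 20 min / 2 h | literature values |
| Flows | $Q_b$ 250, $Q_d$ 500 mL/min | reference prescription |
| $K_oA$, membrane | 800 mL/min, 1.8 m² | high-flux dialyzer |
| Fiber geometry | 200 µm ID, 23 cm, ~12 456 fibers | assumed; area-consistent |
| Tube segment | 150 cm × 4 mm ID | typical arterial line |
| Molecular weights | 252.27 / 236.27 / 180.16 / 206.28 / 66 438 g/mol | standard references |

Affinities of the toxic drugs are *recomputed* from their therapeutic
binding fractions via `affinity_from_binding()` rather than taken as the
rounded printed constants; the rounded values agree to within 0.5% and
either choice passes every test.

Fiber geometry and the tube segment are not part of the published
prescription. They only set residence times: transport is governed by
$K_oA$ and the flows, and the test suite demonstrates that perturbing the
fiber dimensions by ±20% at fixed $K_oA$ and membrane area changes 60-min
removal by well under 1%.

### Interstitial albumin

The reference scenario specifies plasma albumin only. The package defaults
to an interstitial concentration of 40% of plasma (260 µM): with a 14 L
interstitial space this places roughly 1.5× the intravascular albumin mass
extravascularly, which is the standard whole-body albumin distribution.
This single unstated parameter matters more than any other assumed value:
it buffers the interstitial drug store, so it simultaneously lengthens the
body-wide drug burden used in half-life calibration and feeds the
post-dialytic rebound. Raising it to 50% of plasma shortens the calibrated
free half-lives by several percent and strengthens rebound enough to
lengthen minimal treatment times by ~5%; eliminating it entirely does the
reverse, by more. It is an explicit `patient_params()` field, and every
scenario config records it.

## Free half-life calibration

Published half-lives refer to *total* serum concentration, but only free
drug is metabolised; the bound pool and the inaccessible compartments
continuously re-supply free plasma drug, so the elimination rate applied to
free drug must be much faster than $\ln 2 / t_{1/2,\mathrm{total}}$.
`calibrate_free_half_life()` finds $\lambda$ such that, starting from a
patient equilibrated at the peak concentration, total plasma concentration
first halves exactly at the conventional half-life. The crossing time is
strictly decreasing in $\lambda$ (a property test), so the root is unique;
it is bracketed and solved by Brent's method on $\log\lambda$, with each
crossing located by the integrator's root finder.

The peak concentration at which the patient is equilibrated is not part of
the published procedure. For the toxic drugs the package uses the scenario
intoxication level (70 and 35 mg/L) — the patient's actual peak — and for
the competitors a standard therapeutic peak (aspirin 20 mg/L, ibuprofen
25 mg/L). Binding saturation makes $\lambda$ weakly dependent on this
choice (of order 10% across defensible peaks), which is why the calibrated
free half-lives are reproduced to a ±10% bar rather than exactly. The peak
is a per-drug field (`calibration_peak`) and an argument of the calibration
functions.

```{r calibration, eval = FALSE}
calibration_table()
#>   drug          t_half_total_min t_half_free_min lambda_free_per_min ...
#>   aspirin                     20           0.174               3.98
#>   carbamazepine             1500          73.0                 0.00950
#>   ibuprofen                  120           0.907               0.764
#>   phenytoin                 2100          59.8                 0.0116
```

## Session simulation and the minimal treatment time

`simulate_session()` integrates the full coupled system — 12 patient states,
5×16 tube states, 2×5×64 dialyzer states, plus 7 cumulative audit
integrals — monolithically with the sparse-Jacobian BDF solver
(`deSolve::lsodes`), with the right-hand side evaluated in C. A
quasi-steady-state treatment of the extracorporeal fields was considered
and rejected: the fully coupled integration of a 460-minute session runs in
well under a second at default grids, so an approximation layer would add
error and testing surface without benefit.

`find_min_duration()` returns the smallest duration on a 5-minute grid
(matching the precision of the reported treatment times) such that

1. the end-of-session total plasma concentration is at or below the maximum
   therapeutic concentration (MTC), **and**
2. the post-dialytic rebound peak — the maximum of the off-dialysis
   trajectory over the following 720 min — is also at or below the MTC.

The window's lower bound is reported but not enforced: elimination
continues after the session, so the concentration keeps falling once the
rebound has passed. The rebound horizon of 720 min is uncritical: rebound
peaks occur 300–360 min after the session in the reference scenarios, and a
test verifies the minimal duration is unchanged between 720 and
1440-minute horizons. During the duration search the infusion rate is
recomputed per candidate (`diluent_volume / duration`) so the full dose is
always delivered. The pass/fail criterion is monotone in duration, so
coarse bracketing followed by bisection on the grid is exact and
deterministic.

`rebound_trajectory()` keeps the competitor present in the patient during
the rebound phase — it continues displacing toxic drug there, which is
also why longer-lived competitors shorten treatment
(`sweep_competitor_half_life()`): they accumulate in the interstitial and
intracellular pools and keep the free toxic fraction elevated
systemically. Beyond a competitor half-life of about two hours the effect
saturates, a plateau the acceptance suite checks.

## Numerical choices

* **Discretisation.** First-order upwind finite volumes for both spatial
  models; the monotone scheme cannot generate spurious negative
  concentrations. Defaults `n_tube = 16`, `n_dz = 64`; doubling `n_dz`
  changes 60-minute removal by under 0.5% (tested), and the discretized
  dialyzer reproduces the closed-form counter-current clearance
  $K = Q_p(e^{\theta}-1)/(e^{\theta}-Q_p/Q_d)$,
  $\theta = K_oA(1/Q_p - 1/Q_d)$, within 1% at `n_dz = 64`.
* **Stiffness.** $k_{on} P \approx 6.5\times10^4\,\mathrm{min}^{-1}$ makes
  the kinetics stiff everywhere; all integrations use BDF methods. The
  coupled session uses `rtol = atol = 1e-6`, validated against 100-fold
  tighter runs (outputs agree to ~1e-6 relative; a test compares the two).
  Patient-only integrations (calibration, rebound) use `rtol 1e-8`,
  `atol 1e-10`. Solver output is asserted non-negative — never clipped —
  with a floor at tolerance level.
* **Equilibrium solver.** The competitive equilibrium is solved by scalar
  root-bracketing on free albumin in $[0, P_{tot}]$, where the objective is
  strictly increasing (unique root), followed by Newton polish to a 1e-10
  relative conservation residual. This is preferred over the closed-form
  cubic for robustness at extreme affinity ratios.
* **Mass audit.** Every session tracks cumulative dialysate outflow per
  species and cumulative elimination as additional ODE states, and the
  audit requires initial + infused = patient + circuit holdup + removed +
  eliminated to within 1e-6 relative, per conserved entity (toxic drug,
  competitor, albumin), at every output minute. This is an independent
  accuracy check on the integrator, not a re-statement of the equations.
* **Determinism.** The model has no stochastic component; identical
  scenarios and solver settings give bit-identical summaries.

## What the reference scenarios do and do not capture

The scenario generator (`scenario_phenytoin_aspirin()`,
`scenario_carbamazepine_ibuprofen()`, and YAML configs under
`inst/extdata/`) encodes idealised study conditions: constant compartment
volumes, a single shared binding site with 1:1 stoichiometry, constant
half-lives, a solute-free single-pass dialysate, no access recirculation,
no membrane adsorption, and no metabolite kinetics — aspirin is modelled as
the parent drug with its 20-minute half-life even though its salicylate
metabolite also competes at Sudlow site I with a longer half-life, making
the modelled competition conservative. Passing tests therefore demonstrate
internal correctness of the stated model and reproduction of the reference
simulation results, not clinical performance: secondary binding sites,
saturable metabolism, intradialytic hemodynamics and drug–drug interactions
beyond site competition are all outside the model.

## Known limitations

* Minimal treatment times inherit every unstated-parameter choice above;
  the carbamazepine/ibuprofen scenario is the most sensitive because its
  binding is weak and its rebound large — its minimal duration reproduces
  the reference value only to ~11%, with the rebound-peak criterion the
  binding constraint.
* Very short candidate sessions in a duration search imply very high
  infusion rates (full dose over the candidate duration); these can
  transiently push free toxic drug above its initial level, which the
  session flags with a warning. At the reference durations the cap holds
  with margin zero.
* The tube and dialyzer fields start solute-free; the first one or two
  minutes of a session therefore show a filling transient. Its mass is
  fully accounted for by the audit.
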