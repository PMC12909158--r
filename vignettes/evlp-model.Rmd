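---
title: "A lumped-parameter model of ventilation and perfusion on EVLP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lumped-parameter model of ventilation and perfusion on EVLP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evlpsim)
```

## The system being modelled

During ex vivo lung perfusion (EVLP) a donor lung is ventilated by a
mechanical ventilator and perfused by a pump circuit whose deoxygenator
fixes the pulmonary-artery gas tensions. The clinically interpretable
outputs are the left-atrial partial pressures of oxygen and carbon
dioxide, `P_LA_O2` and `P_LA_CO2`, measured in the perfusate draining
the lung. Standard protocols ignore graft-specific physiology, so the
same ventilator and pump settings can mean very different things for
different lungs: how much of the lung is ventilated but not perfused
(alveolar dead space, fraction `F_ds`), perfused but not ventilated
(intrapulmonary shunt, `F_sh`), and how large the conducting-airway
rebreathing volume is (anatomical dead space `V_D`) are not observable
directly. `evlpsim` implements a mechanistic, zero-dimensional model
that maps the monitored inputs plus these intrinsic parameters to the
left-atrial tensions, so that the intrinsic parameters can be estimated
from routine monitor data.

## Model structure

Eight ordinary differential equations are integrated per ventilator
cycle:

* **Ventilator.** Pressure ramps linearly from PEEP to the plateau
  pressure `P_plat = PEEP + Vt / C_stat` over the inspiratory time and
  drops instantaneously back to PEEP for the expiratory time. The drop
  is a true discontinuity; the integrator restarts at every phase
  boundary rather than stepping across it.
* **Mechanics.** A single airway resistance `R_aw` in series with a
  linear compliance `C_stat` (no chest wall or pleural pressure ex
  vivo): `dP_A/dt = (P_vent − P_A)/(R_aw C_stat)`, and the airflow
  `(P_vent − P_A)/R_aw` drives the tidal alveolar volume `V_A`.
* **Compartments.** The total alveolar volume `V_A0 + V_A` is
  partitioned into fixed fractions: shunt `F_sh` (perfused, not
  ventilated), alveolar dead space `F_ds` (ventilated, not perfused)
  and the gas-exchange remainder `1 − F_ds − F_sh`, which must be
  positive (`validate_config()` enforces `F_ds + F_sh < 1`).
* **Alveolar gas.** Species balances for the O2 and CO2 fractions in
  the gas-exchange volume: membrane diffusion, inspiratory refreshment
  with the dead-space-mixed inspirate, a total-molar-flux normalisation
  term, and lung metabolism (`VdotO2` consumption, `VdotCO2`
  production). Partial pressures are fractions times the dry-gas
  pressure (absolute alveolar pressure minus water vapour).
* **Capillary perfusate.** The acellular perfusate carries gas in
  physical solution only. Tensions relax toward the alveolar values at
  the rate `D'/(sigma · V_c_ge)` with `V_c_ge = (1 − F_sh) V_c_tot`,
  are refreshed by the pump flow `Q/V_c_tot` toward the
  pulmonary-artery tensions, and CO2 additionally exchanges with a
  bicarbonate pool `z` through carbonic-anhydrase-accelerated
  hydration/dehydration kinetics. The buffering flux in the CO2
  equation is exactly the negative of `dz/dt` converted to tension
  units by the CO2 solubility, so total CO2 is conserved between the
  dissolved and bicarbonate pools. The hydrogen-ion concentration is
  held at its measured value (`10^-pH`); the model has no acid-base
  feedback.
* **Left atrium.** `P_LA = F_sh · P_PA + (1 − F_sh) · P_c`, per gas —
  the shunt-weighted mix of unmodified pulmonary-artery perfusate and
  end-capillary perfusate (the lumped, well-mixed capillary compartment
  identifies end-capillary with compartment tensions; this closure is
  the only one consistent with a zero-dimensional model).

## Dead-space mixing: why the default is volume-weighted dilution

The inspirate that reaches the alveoli first traverses the anatomical
dead space, which at end-expiration is filled with alveolar gas. Two
idealisations are implemented in `mixed_inspired_fractions()`:

* `"dilution"` (default): the inspirate carries a constant
  volume-weighted composition over the whole breath,
  `F_D = (F_endexp · min(V_D, Vt) + F_i · max(Vt − V_D, 0)) / Vt`.
* `"plug"`: a sharp front — pure rebreathed gas until the cumulative
  inspired volume reaches `V_D`, pure fresh gas afterwards.

The choice matters because the ramp ventilator does **not** deliver the
set tidal volume when the mechanical time constant `R_aw·C_stat` is not
small against the inspiratory time: the delivered volume is
`C_stat·ΔP_A ≈ 0.27 L` at default settings (37% below the set 0.5 L),
because the ramp reaches the plateau pressure only at the instant the
expiratory valve opens. Under plug flow the delivered volume barely
exceeds — or falls below — the 0.25–0.29 L anatomical dead space, so
very little fresh gas reaches the alveoli: at defaults the steady
operating point shifts to ≈109/31.5 mmHg (the published values are
122.5/24.6), and with the calibrated parameter set (`V_D = 0.29 L`,
above the delivered volume) *no* fresh gas arrives at all — metabolic
consumption then drives the alveolar O2 fraction negative, the state
leaves the physically valid region, and an oxygenation challenge can
never approach its published ~450 mmHg plateau. The dilution model,
equally compatible with the idea that mixing depends on the dead-space
size and the set inspired fractions, reproduces both the steady-state
operating point (≈119/25 mmHg at defaults) and the challenge plateau
(≈473 mmHg with the calibrated parameter set). Plug
flow is retained for comparison; the delivered-volume identity itself
is tested in the fast-mechanics regime where it actually holds.

## Numerical treatment

The solver targets absolute and relative tolerances of `1e-9` with a
maximal step of 0.1 s, restarted at each ventilator phase boundary.
Two steppers share one adaptive driver:

* an explicit Dormand–Prince 5(4) pair for the routine regime, and
* an L-stable SDIRK4 (five stages, diagonal 1/4, embedded third-order
  error estimate, simplified Newton with a numerical Jacobian) for
  stiff regimes.

The switch is decided per run from the analytically known fastest rate,
`max(D'/(sigma·V_c_ge), delta·r2, delta·l2·h)`: the capillary O2
equilibration rate is ~209 s⁻¹ at defaults but grows like
`1/(1 − F_sh)` and exceeds 1e4 s⁻¹ in high-shunt sensitivity corners,
where an explicit pair is stability-limited at any tolerance. The
threshold (400 s⁻¹) is an internal numerical choice; the test suite
cross-checks the two steppers against a fine fixed-step RK4 reference
on both sides of it, and verifies the SDIRK tableau against all
order-4 conditions and L-stability numerically.

Some parameter-space corners are *physically degenerate*: with extreme
shunt fractions the gas-exchange compartment becomes so small that
metabolic oxygen demand exceeds what ventilation and perfusion can
supply, and the exact solution runs to negative fractions and tensions
without bound. The integrator aborts with a descriptive error as soon
as the state leaves a generous validity envelope; study drivers catch
these errors and report the affected rows as excluded.

**Steady state** is declared when the cycle means of both left-atrial
tensions change by less than 0.05 mmHg (an order of magnitude below
the sensor accuracy) between successive cycles, capped at 600 s of
simulated time by default. The sensitivity study raises the cap to
3600 s because slow-washout corners (small `Vt`, large `V_D`)
legitimately take far longer than routine settings.

**Nearest-neighbour resampling** onto the 3-s monitor grid breaks
exact ties toward the earlier sample, matching how monitor records are
aligned with simulations.

## Synthetic records — what they emulate and what they do not

The paper's clinical registry is not public, so `generate_record()`
produces a synthetic stand-in: a simulated oxygenation challenge
(15-min epoch, FiO2 stepped from 0.21 to 1.0 at minute 3, all channels
sampled every 3 s) with independent Gaussian sensor noise per channel
and sample at the reported sensor accuracies, and the pulmonary-artery
accuracy (5.1 mmHg) reused for the left-atrial O2 sensor, whose own
accuracy is not reported. The generator's defaults are the stated
study conditions; they were chosen once and not revisited.

A synthetic record emulates sensor noise on an otherwise
model-consistent lung. It does **not** emulate model error: drift,
recruitment/derecruitment, temperature effects, or any physiology the
model lacks. A green parameter-recovery test therefore establishes
identifiability of `F_sh` and `F_ds` under sensor noise — not clinical
validity. `R_aw` and `V_D` are more weakly identified (several
combinations produce near-identical left-atrial O2 traces); the
calibration returns its full search trace so this non-uniqueness can
be inspected, and only the shunt and dead-space fractions are asserted
in recovery tests.

## Calibration

`tune_intrinsic()` minimises the RMSE between measured and simulated
left-atrial PO2 on the record grid over
`(R_aw, V_D, F_ds, F_sh)` within their normal ranges: a seeded
Latin-hypercube global stage followed by Nelder–Mead refinement, with
out-of-range and infeasible (`F_ds + F_sh ≥ 0.98`) proposals
penalised. This replaces the visual manual tuning used in the original
study with a reproducible procedure. Record inputs are taken as
channel medians (robust to sensor noise); the FiO2 step is located by
thresholding at the midpoint of the observed extremes.

The mono-exponential response fit (`fit_mono_exponential()`) describes
the baseline-shifted left-atrial PO2 after an FiO2 step as
`P_bar (1 − e^{−t/τ})`. As printed, the response form forces a zero
initial value, so the package fits the rise above the pre-step
baseline — the quantity actually plotted in challenge figures. For
fixed `τ` the amplitude enters linearly, so the fit is a 1-D profile
search over `τ` (log-spaced bracketing plus golden-section
refinement): deterministic, with no starting-value sensitivity. The
fit window is post-step only; `R²` is reported clipped to [0, 1] with
the raw value retained.

## Sensitivity analysis

Morris elementary-effects screening over all 30 parameters and
constants: clinical and intrinsic parameters on their normal ranges,
constants at ±50% of their defaults, hydrogen-ion concentration
linearly on its printed concentration range (an explicitly flagged
choice — the table gives the range in concentration, not pH, units).
The design uses a 10-level grid with step `Δ = p/(2(p−1)) = 5/9` and
randomised one-at-a-time trajectories; trajectories containing an
infeasible `F_ds + F_sh ≥ 1` point are redrawn whole, so every design
row is simulable. Three outputs are screened: the steady cycle-mean
left-atrial tensions, and the challenge time constant `τ` — for which
every design point runs the same FiO2 0.21→1.0 step (the design's own
FiO2 coordinate is overridden for this output, making its elementary
effects on `τ` exactly zero by construction).

Two departures from convention are deliberate. First, an elementary
effect is dropped only when one of its own two outputs is missing;
dropping whole trajectories would discard nearly the entire design
here, because slow or degenerate corners are common at 30 parameters.
Second, `σ` is the standard deviation of *signed* effects (classic
Morris), and per-output scores are min–max scaled to [0, 1].

A structural finding worth knowing before interpreting results: in
this model the challenge time constant is dominated by the fresh-gas
washout rate, so `Vt`, `V_D` and `F_ds` lead its ranking; PEEP
influences `τ` only through the baseline-volume term
`C_stat·ΔPEEP` (≈40% of `τ` across the PEEP range) and lands
mid-table rather than at the top as in the original study's figure.
The steady-output rankings (FiO2 and `F_sh` for oxygen; `P_PA_CO2`
for carbon dioxide) reproduce the published ordering.

## Uncertainty quantification

Monte-Carlo propagation of sensor noise: each monitored input is drawn
from a normal distribution centred on its configured value with the
reported sensor-accuracy SD (pH noise applied on the pH scale; static
compliance has no reported accuracy and is not perturbed). Draws are
truncated only at physical-validity bounds (positivity, FiO2 ≤ 1) —
**not** at the normal-range bounds, because the FiO2 default sits
exactly on its range boundary and range-truncation would halve the
dominant noise source, biasing the ensemble mean upward by ≈4 mmHg and
shrinking its SD well below the reported value. At the given SDs the
physical truncation leaves all means unchanged to well within 1%.

Static UQ runs each draw to cyclic steady state (10,000 draws at full
scale, ~1,000 at desk scale) and summarises the cycle-mean tensions.
Dynamic UQ simulates a whole challenge epoch per draw, applying each
draw's FiO2 sensor error as an offset to both the pre- and post-step
levels (capped at 1.0), and reports per-time-point mean ± SD bands
plus 2.5/97.5 percentiles — the published band widths are single
numbers interpreted as SDs, so mean ± SD is the primary band.

## Tunable parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `Vt` | 0.5 | L | set tidal volume; with `V_D` controls fresh-gas washout |
| `T_insp`/`T_exp` | 3/6 | s | cycle timing; `T_insp` vs `R_aw·C_stat` sets delivered volume |
| `PEEP` | 6 | cmH2O | baseline pressure; shifts lung volume by `C_stat·ΔPEEP` |
| `FiO2` | 0.21 | — | inspired O2; dominant determinant of `P_LA_O2` |
| `C_stat` | 80 | mL/cmH2O | compliance; delivered volume and baseline volume |
| `Q` | 1.5 | L/min | perfusate flow; refreshes the capillary toward PA tensions |
| `F_ds`, `F_sh` | 0.25 | — | dead-space/shunt fractions; the intrinsic V/Q mismatch |
| `V_D` | 0.25 | L | anatomical dead space; rebreathed fraction `V_D/Vt` |
| `V_A0` | 1.5 | L | unstressed volume; sets the washout time constant scale |
| `R_aw` | 15 | cmH2O·s/L | airway resistance; delivered volume, mechanics lag |

## Known limitations

Everything the conceptual model excludes: temperature dependence,
regional heterogeneity and intratidal recruitment, blood-gas-driven
vasoregulation, hemoglobin carriage (acellular perfusate by
construction), acid-base feedback on pH, and non-Toronto ventilation
or perfusion modes. The delivered tidal volume is below the set value
at routine settings — a property of the ramp ventilator model, not a
bug. Intrinsic parameters other than `F_sh`/`F_ds` are weakly
identified from a single oxygenation challenge.
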