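---
title: "Bond-graph lumped-parameter hemodynamics: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bond-graph lumped-parameter hemodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemobond)
```

## The model

`hemobond` represents the circulation as an energy-conserving network of
lumped compartments. The bond-graph formalism fixes the bookkeeping: every
connection carries a potential–flow pair whose product is power — in the
fluid domain the potential μ is pressure (Pa ≡ J m⁻³) and the flow υ is
volumetric flow (m³ s⁻¹). Storage and dissipation live in three one-port
elements: a resistor (μ = υR, viscous loss), a capacitor (μ = q/C with
q̇ = υ, wall distension) and an inductor (υ = p/I with ṗ = μ, blood
inertia). Conservation lives in the junctions: a 0-junction imposes one
common pressure and zero signed flow sum (mass conservation at a branch), a
1-junction imposes one common flow and zero signed pressure sum around the
loop (momentum balance along a segment). Because every compartment is built
only from these pieces, mass and energy conservation are structural
properties of the assembled ODE system, not numerical aspirations — the
test suite checks the flow-sum identities algebraically at random states.

A vessel segment is one C (wall compliance) in parallel with a series R–I
pair. Its lumped values come from geometry under the standard assumptions:
Newtonian blood, laminar fully developed (Poiseuille) flow, a thin-walled
linear-elastic cylindrical wall of uniform properties, so

* R = 8νl/(πr⁴)  (Pa s m⁻³),
* C = 2πr³l/(hE)  (m³ Pa⁻¹),
* I = ρl/(πr²)  (Pa s² m⁻³),

with blood viscosity ν = 0.004 Pa s and density ρ = 1040 kg m⁻³ by default.
The momentum stored by the inductor is never kept explicitly: the flow
state υ = p/I is integrated instead, so each capacitor contributes one
pressure state and each 1-junction one flow state.

### Segment causality

A lumped compartment cannot choose what its neighbours hand it: at each end
it either receives a pressure and returns a flow, or vice versa. The
library therefore carries one segment type per causality pattern —
pressure-in/flow-out (μυ), flow-in/pressure-out (υμ), pressure at both ends
(μμ, with R and I split equally across the two ends and the single C in the
middle), and flow at both ends (υυ, with C split equally across the two
ends). Splitting junctions use a μυ-split parent whose 0-junction absorbs
the daughter flows; merging junctions use a υυ-merge parent fed by μμ
daughters. Terminals are a μυ segment fused with an RCR Windkessel
(proximal resistance RTP in series with parallel CT and RTD) that stands in
for the truncated distal bed. Only the μυ and μμ equations are canonical;
the υμ/υυ forms are their mirror images, which we validate through the
structural-equivalence check below rather than by fiat.

Junction compatibility is enforced as data-producing validation (not
exceptions): a pressure-supplying outlet may only feed pressure-demanding
inlets, a flow-supplying outlet cannot split, merge feeders must be μμ
segments, terminals must be leaves, and the root's type must match the
boundary attachment (a prescribed-flow inflow needs a flow-demanding root).
Split and merge elements generalize from two daughters to n by summing
flows — the 0-junction law dictates the generalization — and n = 1 is
permitted, reducing exactly to the plain type.

### Viscoelastic walls

Wall viscoelasticity uses the Voigt model (spring C parallel to dashpot
Rv): the total wall pressure becomes algebraic, μ = μv + (net C inflow)·Rv,
while the stored state is the elastic part, μ̇v = (net C inflow)/C. We
deliberately keep the state-vector width unchanged: μv *replaces* μ as the
integrated state and μ is emitted as a derived output column. The dashpot
resistance comes from the stress-relaxation time constant, Rv = f/C; the
generalized (Westerhof–Noordergraaf) wall model is out of scope as
disproportionately expensive for a real-time-oriented 0D code. For the
two-capacitor (υυ) types each half-capacitor C/2 carries a dashpot 2Rv so
that the per-capacitor relaxation time stays f. One restriction follows
from keeping the system an explicit ODE: a segment fed directly by a heart
valve may not be viscoelastic, because the orifice flow would then enter
its own pressure algebraically (an implicit loop we choose not to close);
validation rejects such configs.

### Heart, valves and the closed loop

Each chamber is a time-varying elastance: μ = (q − q0)·E(t),
E(t) = EB + e(t)·EA, with q the chamber volume, q0 its dead volume, and
e(t) a piecewise-cosine activation — a raised-cosine upstroke over the
contraction interval and decay over the relaxation interval for the
ventricles, and a four-branch version for the atria whose relaxation tail
may wrap past the end of the cycle. For continuity the atrial relaxation
onset defaults to the end of atrial contraction. Valves follow the orifice
model: flow = α·coeff·Φ(Δμ) with the two-state opening coefficient α = 1
iff the upstream pressure exceeds the downstream pressure. We read Φ as the
square-root orifice law Φ(Δμ) = √(max(Δμ, 0)) — the pressure–flow relation
is explicitly nonlinear, which rules out a plain linear diode — and the
valve coefficient then has units m³ s⁻¹ Pa⁻½; a linear-diode mode is kept
behind a config switch for sensitivity checks. Inside the integrator the
hard 0/1 switch would present the BDF method with a discontinuous
right-hand side, so the opening coefficient is smoothed to a logistic in Δμ
of width 1 Pa (configurable) and the square root is regularized at the same
scale; flow remains non-negative in both the smoothed and the hard form,
and reported valve states always use the hard rule. The pulmonary arteries
and veins and the systemic veins are single υμ compartments with
config-supplied R/C/I; terminals drain into the venous compartment, whose
pressure replaces their open-loop venous reference.

## Parameters and defaults

All internal computation is strict SI (Pa, m³ s⁻¹, m³, s); clinical-unit
strings ("80 mmHg", "1.5 ml", "0.05 mmHg.s/ml") are converted once, on
config load. Defaults that matter:

| parameter | default | why |
|---|---|---|
| blood ν, ρ | 0.004 Pa s, 1040 kg m⁻³ | standard human blood values |
| thickness fit (a, b, c, d) | 0.09, −2000 m⁻¹, 0.11, −5 m⁻¹ | gives h/r ≈ 0.10–0.15 over radii 0.5–15 mm, the arterial range; used only when h is not explicit (an explicit h always wins) |
| LV/RV elastance EA | 2.4 / 1.05 mmHg ml⁻¹ | textbook ventricular elastance amplitudes |
| chamber EB | 0.10–0.15 mmHg ml⁻¹ | diastolic stiffness |
| timing (T = 1 s) | Tvc 0.30, Tvr 0.15, tac 0.80, Tac 0.17, Tar 0.17 s | systole ≈ 0.3 s at 60 bpm; atrial kick in late diastole, relaxation wrapping into the next cycle |
| valve coefficients | 3.0–3.5 × 10⁻⁵ m³ s⁻¹ Pa⁻½ | ≈ 350–400 ml s⁻¹ mmHg⁻½, standard orifice values |
| solver | BDF, rtol 1e-7, output step 1 ms | stiff multistep with per-unit absolute tolerances (1e-6 Pa, 1e-12 m³/s, 1e-12 m³); the 1 ms step is the reporting grid of a variable-step method, not an integration step |
| periodicity tolerance | 1e-3 relative L2 per cycle | loose enough to detect the attractor within ~10–20 cycles, tight enough that cycle summaries are stable |

The heart, pulmonary and venous defaults are physiologically standard
values in the style of the lumped heart–valve literature; they are design
choices of this package, not a calibration to any particular dataset, and
every one of them is overridable through the `heart` block of the config.

## Numerical choices

*Initial conditions.* Closed loop: 80 mmHg on the arterial side, 5 mmHg in
the pulmonary/venous compartments, chambers at dead volume plus a filling
volume, all flows zero; the simulation then runs to its periodic attractor,
which for this dissipative system does not depend on the initialization.
Open loop: zero pressure and flow everywhere, so that the lumped model and
the 1D reference start from the same unstressed state; per-state overrides
are available in the config.

*Periodicity detection.* Cycles are compared on the output grid; for each
state the RMS of the cycle-to-cycle difference is normalized by that
state's overall magnitude (with a floor to keep identically-zero states
harmless), and the maximum over states must fall below the tolerance. The
returned index is the first cycle that matches its predecessor, so a
vacuous tolerance returns cycle 2 — the first comparable one.

*Degenerate inputs.* Zero viscosity gives zero resistance (the inviscid
limit is legal); zero stress-relaxation time gives a purely elastic wall;
a thickness fit that evaluates non-positive errors out; split/merge with a
single daughter degrade to the plain types; chamber volumes are monitored
and a negative excursion warns rather than aborts (it signals a
non-physiological parameterization, not a solver failure). Non-finite
states abort naming the first offending state.

*Conservation.* Total stored blood volume is an exact linear functional of
the state (chamber volumes plus compliance times pressure for every
capacitor); in the closed loop its drift over ten cycles is below 0.1% at
default tolerances — in practice at the 1e-14 level, because conservation
is structural and the only error source is the integrator.

## The structural-equivalence and battery checks

The μμ segment must equal the chain "μυ element + υμ element coupled with
the single C in the middle, R and I halved on each side". The literal chain
cannot be wired through the network assembler — both half-elements demand
the flow covariable at the shared node, which is precisely why the fused μμ
type exists — so the equivalence is checked by building the chain directly
from the two primitive derivative functions sharing the middle capacitor
state, and comparing trajectories against the assembled μμ segment. The two
right-hand sides are algebraically identical, so this validates the
assembler's plumbing and the mirrored υμ equations at once.

`analytic_battery()` bundles the closed-form checks: RC discharge of an
isolated terminal capacitor against exp(−t/(RTD·CT)) (error < 0.1%), steady
Poiseuille flow υ = Δμ/R (to solver tolerance), Windkessel steady-state
drop υ·(RTP + RTD) and diastolic decay constant RTD·CT (< 1%, measured by
log-linear fit with the vessel capacitor three orders of magnitude smaller
than CT so the two-capacitor correction stays below the tolerance), the
chain equivalence, and the closed-loop volume drift.

## The 1D reference solver and the 0D/1D comparison

The in-package oracle discretizes the standard 1D mass/momentum equations
in conservative (A, Q) form with a linear-elastic tube law whose compliance
per unit length 2πr³/(hE) matches the lumped C, and a flat-profile friction
term −8πνQ/(ρA) consistent with the Poiseuille resistance per unit length.
The scheme is a first-order Rusanov finite-volume method under explicit CFL
control (CFL 0.45), with linearized-characteristic boundary treatment:
prescribed inflow at the root, an RCR closure at the leaves (the terminal
capacitor pressure integrating alongside), and at junctions a common
pressure solved from the outgoing characteristics plus mass conservation.
It is deliberately minimal — self-convergent at first order (verified by
grid refinement) and adequate as a desk-scale reference; it makes no claim
to production 1D accuracy, and viscoelastic 1D walls are out of scope.

The matched cases are a 3 cm single vessel (r = 5 mm, h = 0.75 mm,
E = 0.8 MPa) with an RCR outlet and a symmetric bifurcation (daughters
2.5 cm, r = 3.7 mm) with RCR outlets, both driven by a half-sine systolic
pulse (peak 60 ml/s, 0.3 s ejection, 1 s period) for 10 cycles — enough for
the RCR time constants (≈ 0.9–1.7 s) to forget the common zero initial
state. Probe convention (the lumped state is a single point, the 1D
solution a field): the 0D pressure probe is the segment's capacitor
pressure — for the two-capacitor υυ type the mean of its two end
capacitors — compared against the 1D midpoint-cell pressure; the 0D flow
probe is the segment's 1-junction flow against the 1D midpoint flow. RMSE
is taken over the last cycle on a shared 512-point resampled grid and
normalized by the reference systolic (per-cycle maximum) value, reported
separately per quantity and probe. At these scales the vessels are a small
fraction of a wavelength (c ≈ 7.6 m/s, so cT ≫ l), which is exactly the
regime where lumping is defensible; the observed disagreement is a fraction
of a percent for the single vessel and below one percent for the
bifurcation, against a 5% acceptance bound.

## What the synthetic fixtures do and do not show

`generate_tree_fixture()` emulates an anatomically detailed arterial tree
only in structure: a symmetric binary tree with geometric radius/length
tapering (default ratio 0.75 per generation), equal-split RCR terminals
scaled so the total peripheral conductance matches a template, and a
flow-inlet root. Real arterial trees are asymmetric, have
generation-dependent elasticity, curved and tapering vessels, and
calibrated per-territory peripheral beds; none of that is represented, so
passing tests demonstrate correctness of the element equations, assembly,
conservation and solver behavior — not anatomical fidelity. Reproducing a
specific anatomical model's waveforms would require its geometry and
calibration tables, which are external data.

Problem sizes throughout the suite are desk-scale by design: trees of ≤ 15
segments, a depth-1 closed loop (23 states), 10–20 cardiac cycles, 32-cell
1D vessels. They exercise every code path; larger networks only grow the
(sparse) ODE system linearly.

## Known limitations

* Linear elastic C: no pressure-dependent (collagen-recruitment) stiffening,
  so predictions degrade far from the pressure range the parameters were
  chosen for.
* No nonlinear junction losses (bends, stenoses), no non-Newtonian
  viscosity, no valve inertia or regurgitation.
* No autoregulation, baroreflex or metabolic coupling — the network is
  autonomous apart from its boundary drives.
* The smoothed valve switch (1 Pa width) trades a ~1 Pa pressure-scale
  blur at the opening instant for integrability; narrow it if the opening
  transient itself is under study.
* The 1D oracle is first-order; its role is self-convergent reference at
  desk scale, not a wave-propagation benchmark.
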