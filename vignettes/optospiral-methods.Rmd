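---
title: "Models and methods behind optospiral"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind optospiral}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

optospiral simulates a 2.5 cm x 2.5 cm sheet of optogenetically modified
mouse ventricular tissue and the control of a spiral wave (re-entrant
arrhythmia) by globally uniform, sub-threshold blue light.  This vignette
documents the models, the numerical choices, and the judgement calls a
maintainer should know about.  Nothing here states an empirical result that
the package's tests or `scripts/acceptance.R` do not themselves compute.

## The electrophysiological model

Each node carries the Bondarenko mouse ventricular myocyte model: membrane
voltage $V$, Markov chains for the fast Na$^+$ channel (9 states), the
L-type Ca$^{2+}$ channel (8 states) and I$_{Kr}$ (5 states),
Hodgkin–Huxley gates for the transient-outward, ultrarapid, slow and
steady-state K$^+$ currents, ryanodine-receptor Ca$^{2+}$ release with
subspace/SR compartments, and Na$^+$/K$^+$/Ca$^{2+}$ concentration
bookkeeping — 41 ordinary differential equations per cell, with

$$\frac{dV}{dt} = -\frac{\sum I_{ion} + I_{ChR2} + I_{stim}}{C_m},\qquad
\sum I_{ion} = I_{Na} + I_{CaL} + I_{pCa} + I_{Kto,f} + I_{Kto,s} + I_{Kr}
 + I_{Kur} + I_{Kss} + I_{K1} + I_{Ks} + I_{NaCa} + I_{NaK} + I_{Cl,Ca}
 + I_{Cab} + I_{Nab}.$$

Currents are densities in pA/pF; inward currents are negative, so a
depolarizing applied stimulus has negative sign.  The apical
parameterization is the default (`cell_params("apical")`); the septal
variant differs in the transient-outward and ultrarapid conductances.  The
model was reconstructed from the published description and validated
in-package: the published initial conditions sit on the model's resting
fixed point (net current $< 0.01$ pA/pF), the cell settles to $-82.4$ mV,
and a suprathreshold pulse elicits the characteristic brief murine action
potential with $\sim +30$ mV overshoot.

**One deliberate correction.**  During tissue validation the as-published
Na-chain rates turned out to admit a second *stable* equilibrium near
$-33$ mV: in detailed balance the open probability
$O_{Na} = I_{F}\,\alpha_{13}\alpha_3/(\beta_{13}\beta_3)$ remains
$\sim 2.5\times10^{-3}$ at plateau voltages, and the resulting
$\sim -2.4$ pA/pF persistent inward current exceeds the weak murine K$^+$
repolarization reserve there.  Isolated cells shoot through this window,
but tissue in the wake of premature (S2 or spiral) beats is held near it
electrotonically and freezes — making re-entry impossible, which
contradicts the phenomenon the simulator exists to reproduce.  We therefore
gate the Na recovery-from-inactivation rate with
$\alpha_3 \mapsto \alpha_3 / (1 + e^{(V+45)/5})$: recovery happens only at
diastolic potentials (textbook Na-channel behavior), the resting-state
occupancies (validated against the published initial conditions) and the
upstroke are untouched, and the spurious equilibrium disappears.

## The ChR2 photocurrent

The four-state channelrhodopsin-2 model has closed states $C_1, C_2$ and
open states $O_1, O_2$:

$$I_{ChR2} = g_{ChR2}\, G(V)\, (O_1 + \gamma O_2)\, (V - E_{ChR2}), \qquad
G(V) = \frac{10.6408 - 14.6408\, e^{-V/42.7671}}{V},$$

with $\gamma = 0.1$ and $E_{ChR2} = 0$ mV.  Two notational pitfalls are
resolved the standard way: the $O_1$ balance is implemented with the
occupancy-conserving signs
($dO_1/dt = k_1 C_1 - (G_{d1}+e_{12})O_1 + e_{21}O_2$), and
$G(V)(V - E_{ChR2})$ is evaluated jointly so that $V = 0$ is a removable
singularity (the product tends to $-4\,g_{ChR2}(O_1+\gamma O_2)$).

The kinetic constants follow the published ChR2(H134R) four-state model at
470 nm: voltage-dependent $G_{d1}(V) = 0.075 + 0.043\tanh(-(V+20)/20)$,
$G_{d2} = 0.05$, recovery $G_r(V) = 4.34\times10^{-5} e^{-0.0211539 V}$
(all ms$^{-1}$), inter-open rates growing logarithmically with irradiance,
and light-activation rates proportional to photon flux,
$k_1 = 1.8637\times10^{-4} E_e$ and $k_2 = 3.0569\times10^{-5} E_e$
ms$^{-1}$ with $E_e$ in µW/mm² (retinal cross-section
$1.2\times10^{-19}$ m², quantum efficiencies 0.8535/0.14, loss factor 1.3,
photon energy at 470 nm).

**Calibration of $g_{ChR2}$.**  The source study does not print the
photocurrent magnitude, so the maximal conductance is the one calibrated
quantity (default $0.3$ mS/µF, fixed once and not revisited).  Constraints
used, in order: (i) a 33 ms, 20 µW/mm² global pulse on resting tissue must
stay sub-threshold (at 0.3 mS/µF it depolarizes rest by $\sim 6$ mV; above
$\sim 0.6$ mS/µF it fires an action potential); (ii) 20 µW/mm²
illumination must slow the rotor into the reported illuminated band
(sustained light: $\sim 12$ Hz; pulsed at 44% duty: $\sim 13.1$–$13.4$ Hz
across the three pacing frequencies), with 13.33 Hz pacing inside the
resonant locking range so that the drift-to-boundary termination the study
reports can occur.  The sub-threshold and slowing checks are enforced by
the test suite.

## Tissue, numerics, and one erratum-level parameter decision

Tissue is the isotropic monodomain sheet
$\partial V/\partial t = D \nabla^2 V - (I_{ion}+I_{ChR2}+I_{stim})/C_m$
on a 100 × 100 grid, $dx = 0.025$ cm, five-point stencil, no-flux
boundaries via mirrored ghost nodes (boundary conditions are not stated in
the source; no-flux is the standard choice for an isolated sheet and is
required for boundary-collision termination to be meaningful).

**Diffusion coefficient.**  The source prints $D = 0.00014$ cm²/ms *and* a
conduction velocity of 43.9 cm/s on the same grid.  These are mutually
inconsistent: monodomain CV scales as $\sqrt{D}$, and at the printed $D$
this model conducts at $\sim 10$ cm/s in a saltatory, near-failure regime,
while the printed CV, the 66 ms rotation period and the single-spiral
wavelength ($43.9\,\mathrm{cm/s} \times 66\,\mathrm{ms} \approx 2.9$ cm
$\approx$ domain size) all cohere at $D = 0.0014$ cm²/ms = 0.14 mm²/ms —
the standard cardiac value.  We treat the printed figure as missing a zero
and default to `D = 0.0014`; `measure_cv()` then yields $\approx 45$ cm/s,
within 3% of the printed velocity.

**Time stepping.**  The reference scheme is classical RK4 on the full
coupled ODEs (`scheme = "rk4"`), as in the source (dt $= 10^{-4}$ ms); the
subspace-Ca/RyR subsystem is stiff (relaxation rates of order $10^3$
ms$^{-1}$ during the Ca transient), so this scheme requires dt
$\lesssim 10^{-3}$ ms and is used for oracle tests, not production runs.
The production path (`scheme = "split"`, default) uses Strang splitting
between explicit diffusion and a tabulated reaction substep: Rush–Larsen
exponential updates for Hodgkin–Huxley gates, exponential-Euler updates for
Markov states and the subspace Ca concentration, a 3 × 3 backward-Euler
solve for the very stiff RyR chain, and linear interpolation in a
voltage-indexed rate table (0.05 mV resolution).  It is stable at
dt = 0.005–0.02 ms; dt = 0.005 ms is the package default and long
(acceptance-scale) runs use dt = 0.01 ms, a choice validated by the
self-convergence test (halving dt moves planar activation times by
< 0.5%) and by the D = 0 equivalence test against the RK4 integrator.
The diffusion substep enforces the explicit stability bound
dt < dx²/(4D) ≈ 0.11 ms as a hard error.

## Spiral initiation

The initiation protocol is not described in the source (it only shows an
established rotor), so both standard options are provided:

* `method = "phase_seed"` (default): one paced action-potential cycle is
  sampled at 0.5 ms resolution and distributed as an Archimedean spiral
  phase field around the domain center, then healed for 200 ms.  This is
  deterministic, places the core at the center, and in this medium yields a
  stationary rotor with a tight circular core (radius $\approx 0.09$ cm)
  at $\approx 15$ Hz / 66 ms — the regime of the source's unilluminated
  spiral.
* `method = "cross_field"`: planar S1 from the left edge, quadrant S2 at a
  coupling interval inside the vulnerable window (default 45 ms).  It also
  produces a sustained single rotor here, with a boundary-adjacent core
  (and hence a slightly lower observed frequency); mistimed S2 raises an
  informative initiation-failure error.

The wavelength ($\approx 2.9$ cm) barely exceeds the domain, which is why
cross-field placement is delicate in this medium and the centered seed is
the default.

## Protocols

*Open-loop*: global pulses of width 33 ms (half a rotation period) and
intensity 20 µW/mm² at pacing frequency $f_p$; onsets are exactly periodic,
and the first pulse is anchored to the next predicted upstroke at the
reference recording point (the pacing phase is otherwise free; it rotates
the drift direction but not the regime).

*Resonant feedback*: a sensing electrode (nearest grid node to the
configured position) fires one global pulse per upward crossing of
$V_c = -40$ mV, with hysteresis re-arm below $V_c$ and a single-pulse
channel (no overlapping pulses).  The train stops by itself once no
activity reaches the electrode.

*Termination* is declared when the grid maximum voltage stays below
$-70$ mV for a sustained 100 ms.  Samples taken while a light pulse is on
are judged against $-55$ mV instead: sub-threshold light holds resting
tissue several mV depolarized, and without the relaxed lit threshold an
unlimited open-loop train (dark gaps < 100 ms) could never satisfy the
detector even on a fully quiescent domain.  Pulse counts "until
termination" exclude pulses delivered inside the trailing detection window.

## Analysis

The spiral tip is the intersection of the $V = -40$ mV isoline with the
temporal zero-change line ($\Delta V = 0$ between consecutive frames),
located sub-grid by intersecting the two contour polylines;
$-40$ mV is also the sensing threshold, which keeps one fewer free
parameter.  Rotation frequency is estimated from upward $-40$ mV crossings
(`f = 1000 (n-1)/(t_n - t_1)`), with a zero-padded periodogram as the
spectral cross-check.

Meander classification segments the trajectory into modulation cycles at
the light-pulse onsets (robust to petal overlap), computes per-cycle mean
positions, and labels: near-zero net displacement with a closed orbit =
`circular`; consistent displacement with small turning = `linear_drift`;
otherwise the petal direction decides between `hypocycloid_outward`
($f_p > f_s$) and `epicycloid_inward` ($f_p < f_s$).  Petal direction is
measured at the petal apices — the maximum-curvature point of each cycle —
as the signed radius relative to the cycle's median radius about the
pattern centroid (or about the electrode, for feedback runs).  An earlier
cusp-versus-midpoint criterion was discarded because it silently depends
on the phase of the pulse onsets within a petal.

## What the tests do and do not establish

The property suite (conservation laws, RK4 order, stencil/matrix oracle,
heat-kernel variance growth, D = 0 single-cell equivalence, sub-threshold
guarantee, synthetic-movie tip tracking, analytic petal fixtures) validates
the machinery independently of the ionic model's quantitative fidelity.
The acceptance-level numbers (CV, dark and illuminated rotor frequencies,
pulse counts to termination) additionally depend on the reconstructed
Bondarenko parameterization and on the two documented corrections above;
they reproduce the source values to within a few percent, but they are
properties of *this* reconstruction, not proof of equation-level identity
with the authors' code.  Light-decay with depth, heterogeneous ChR2
expression, anisotropic conduction and 3-D geometry are out of scope.
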