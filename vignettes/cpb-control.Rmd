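---
title: "Modelling and control of CPB perfusion: methods and design record"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and control of CPB perfusion: methods and design record}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpbsim)
```

This vignette is the package's account of its science: the plant model
and its assumptions, the controller structure and how it was tuned, what
the synthetic-data generators do and do not emulate, and the choices
made where the design was genuinely open. It states no empirical result
that the test suite or `scripts/acceptance.R` do not themselves compute.

## The plant

A CPB circuit driven at constant centrifugal-pump speed delivers a flow
set by the hydraulic resistance of the lines; the motorized arterial
occluder throttles that flow by crushing the tubing. The statics are

$$Q(O') = \frac{(1 + \Delta R_0/R)\,Q_0\,R A E}{1 + R A E + \Delta R_0 A E},
\qquad E = e^{K O'} - 1,$$

which is zero at a closed occluder, strictly increasing, and saturates
below the full-open flow $Q_0$. The occluder mechanism responds to its
command through first-order-plus-dead-time dynamics $e^{-Ls}/(1+Ts)$.
The venous reservoir's level — expressed throughout as a *volume* in
liters, since the target is stated as 0.45 L and no vessel geometry is
modelled — integrates the flow imbalance
$\dot V = (Q_\mathrm{ven} - Q_\mathrm{art} + D)/60$, with flows in L/min
and time in seconds. Venting/suction of operative-field blood enters
purely as the reservoir inflow disturbance $D$; the venous line itself
is unchanged.

Assumptions worth keeping in mind: the statics are memoryless (no
tubing hysteresis or creep), the pump head is absorbed into constant
$R$, $\Delta R_0$, $Q_0$ (no pressure–flow pump curve, no backflow
physics at very low flow), and perfusate rheology enters only through
the parameter values. The two presets — `"glycerin"` and `"blood"` —
are *synthetic stand-ins*: no fitted parameter table was available, so
values were chosen once to give a realistic adult circuit (full-open
flow ≈ 5 L/min, a typical 4 L/min flow at ~74 % opening, actuator dead
time 0.3–0.35 s and lag 1.5–1.8 s) and are not revisited.

### Discretization

Everything advances at a fixed $\Delta t$ = 0.01 s, the protocol's
sampling interval: the actuator lag by forward Euler, the dead time as a
ring buffer of $\mathrm{round}(L/\Delta t)$ commands, the reservoir by a
rectangular rule. A convergence test integrates the actuator at
$\Delta t/100$ and requires agreement within 0.5 % opening, so the
coarse step is known to be inside its asymptotic regime. At
$T \ge 1.5$ s the forward-Euler pole error is $O(\Delta t/T) < 1\%$.

### Sensors

Flow measurements add Gaussian noise (default sd 0.05 L/min) and pass
through a first-order low-pass filter; the filter pole is matched to the
continuous one, $\alpha = 1 - e^{-2\pi f_c \Delta t}$, so the −3 dB
point sits at the configured cutoff (default 1 Hz — a cutoff is known to
exist but its value is not published, and 1 Hz keeps the physiological
band while removing most flowmeter noise). The camera-based level
readout is emulated as Gaussian noise (sd 0.002 L) followed by
quantisation to 0.005 L, a plausible pixel resolution for a webcam
watching a reservoir; the image-processing pipeline itself is out of
scope. All noise is drawn from a seeded stream, so every trial is
bit-reproducible from its `(config, seed)` pair.

## Identification

The five static parameters are fit by bounded nonlinear least squares
on the flow residuals (`stats::nlminb` on log-parameters, which
enforces positivity and evens the scales). The map is structurally
over-parameterised — $R$, $\Delta R_0$ and $A$ appear only in products —
so point recovery of every parameter is *not* the contract; predictive
equivalence of the fitted flow curve is (sup-norm within 1 % of $Q_0$
from a ±50 % perturbed start, in the tests). A 5-start seeded
multi-start guards against the local minima this trade-off creates.
Dynamics $(L, T)$ are fit jointly with the step endpoints on the whole
recorded transient rather than by the classical two-point 63.2 % method,
which is noticeably noise-sensitive; the dead time is seeded from a
small grid because the loss has a kink in $L$. Non-convergence and
degenerate data (constant flow, no transient) are flagged, never
silent.

## The controller

Two nested loops, in the classic cascade arrangement:

**Inner (flow) loop — two-degree-of-freedom model matching.** The raw
reference (measured venous flow plus the level correction) is shaped by
a first-order matching model with $\tau_m$ = 1 s into $Q_m$. The
feedforward inverts the plant at $Q_m$: the statics exactly (closed
form), and the lag by the realisable lead
$(1 + Ts)/(1 + \tau_f s)$ with $\tau_f$ = 0.1 s. The dead time cannot be
inverted, so it — together with the lead residual $1/(1+\tau_f s)$ — is
folded into the matching target the feedback PID compares against.
This was a genuinely open design point (whether the feedforward inverts
the dynamics or only the statics): static-only inversion leaves the
open-loop pole ($T$ = 1.5 s) dominating the inner loop, whose 2 %
settling then takes ~7.5 s and destroys the time-scale separation the
cascade needs; with dynamic inversion the inner loop settles in under
1 s for modest reference steps (the bandwidth-separation test measures
both loops). The feedback PID is IMC-tuned from the identified FOPDT
($K_p = T/(k(\lambda+L))$, $K_i = K_p/T$, $K_d = 0$, $\lambda = \tau_m$)
with the representative gain $k$ taken as the static-map slope at half
flow; because the error is measured against the *achievable* matched
response, the integrator does not wind up during reference transients
and the feedback is left to its proper job of rejecting mismatch and
disturbances.

**Outer (level) loop — I-PD.** The correction is
$u = K_{i,L}\!\int (Y_L - R_L)\,dt + K_{p,L}(Y_L - Y_0) +
K_{d,L}\dot Y_{L,f}$, clamped at ±1 L/min. Only the integral sees the
target, so target changes enter without proportional or derivative
kick — the defining I-PD property. The sign follows the physics: a
positive correction raises arterial outflow and *drains* the reservoir,
so the integral must act on $(Y_L - R_L)$, and a level below target
yields a negative correction. (A formulation with the opposite integral
sign is internally inconsistent with that convention; the physics
settles it.) $Y_0$ anchors the P term at the first measured level — a
bumpless start that avoids an 0.45 L × $K_{p,L}$ DC offset devouring
the ±1 L/min range. The derivative is filtered at 0.5 s, chosen against
the 0.005 L level quantisation: raw differentiation of a quantised
signal at 100 Hz would inject ±0.5 L/s spikes.

With the linearised reservoir ($\dot Y = (D - u)/60$), the closed outer
loop is $(60 + K_d)\ddot Y + K_p\dot Y + K_i (Y - R_L) = \dot D$;
the defaults $K_{i,L}=4$, $K_{p,L}=28$, $K_{d,L}=5$ place
$\omega_n \approx 0.25$ rad/s, $\zeta \approx 0.87$ — a ~19 s settling
time, inside the intended 10–20 s band and more than five times slower
than the inner loop. Because $K_i$ is the coefficient of the error, a
step disturbance of magnitude $d$ leaves zero asymptotic level error
(final-value theorem; the tests verify the deviation falls below
$10^{-3}$ L) and a transient absolute-deviation area of about $d/K_i$
— ~0.125 L·s per 0.5 L/min edge, which is what keeps `J_L%` small in
the disturbance protocol.

**Anti-windup** is conditional integration: each integrator freezes
while its output is clamped in the direction the error pushes.
Back-calculation would also work and re-enters faster after deep
saturation; conditional integration was chosen as the simpler scheme
whose invariant ("integrator constant while clamped") is directly
testable.

**Ablation.** Disabling the level unit zeroes the correction, reducing
the controller to pure venous-flow tracking — the configuration used to
demonstrate why level control matters: any nonzero-net disturbance then
shifts the level by exactly its integrated volume and nothing brings it
back.

## Scenarios and the stated world

Two protocols are built in, mirroring the published experimental
design: a 400 s perfusion run (flow-up/flow-down) and a 200 s
disturbance run, both at $\Delta t$ = 0.01 s with target level 0.45 L.
The venous profile of the perfusion run (0.5 → 4.0 L/min over 150 s,
hold, back to 0.5 by 400 s) and the disturbance shape (two +0.5 L/min,
20 s suction episodes starting at 50 s and 150 s) are plausible
reconstructions: the published protocol supplements were unavailable,
so magnitudes follow adult perfusion practice (peak ≈ 4 L/min) and the
annotated episode timing. They were fixed before the evaluation metrics
were first computed and have not been adjusted since. Trial counts (10
perfusion, 5 disturbance) and the min/2.5 %/median/97.5 %/max summary
follow the published boxplot convention.

Metrics are computed over the full record, transients included (no
published warm-up exclusion exists; a `skip_initial` option defaults to
0). The relative flow error is singular where $Q_m \to 0$, which the
flow-up start approaches; samples with $|Q_m| < 0.1$ L/min are excluded
from `J_Q%` and counted — with the default profiles no sample is ever
excluded, but the guard keeps the metric defined for user scenarios
that start from zero flow.

### What a green test does and does not establish

The generators emulate: the nonlinear statics, FOPDT actuation,
reservoir mass balance, filtered noisy flowmeters, and a quantised
level readout. They do not emulate: perfusate rheology beyond parameter
presets, pump backflow at low flow, tubing compliance/hysteresis,
camera image analysis, venous-side coupling of suction, or operator
variability. Meeting the published error ceilings in silico therefore
establishes that the *control architecture* achieves them on the stated
plant model — a necessary condition and a tuning testbed, not a claim
of physical replication. The ablation contrast (level error explodes
without the level unit, flow error indifferent) is direction-faithful
to the rig results; its magnitude depends on disturbance volume, which
is a free parameter here.

## Numerical choices, degenerate inputs, limitations

* Fixed-step forward Euler everywhere, guarded by a $\Delta t/100$
  convergence test; no adaptive stepping, so pathological configs
  (e.g. $T \ll \Delta t$) are rejected by validation rather than
  integrated badly.
* An empty reservoir floors at zero and raises a flag on the trial
  (the clinically relevant hazard marker) instead of aborting, so
  ablation runs remain comparable.
* Infeasible flow references (at or above the static supremum $Q_0$)
  saturate the feedforward at 100 % and flag; the static inverse itself
  refuses them with an explicit error.
* `exp(K O')` overflow (absurd shape parameters) is an explicit error,
  not a silent `Inf`.
* The matching-model, lead and derivative filters are first-order
  discrete filters with poles matched or backward-difference based;
  their states initialise at the first observed value (bumpless), so
  step one of a trial carries no artificial kick.
* Known limitations: single-occluder control only (the venous occluder
  stays manual), no hemolysis or pressure modelling, no statistical
  comparison machinery beyond quantile summaries, and the controller's
  robustness is only exercised against the disturbance family modelled
  here.

## Reproducing the headline evaluation

```{r eval = FALSE}
plant <- plant_preset("glycerin")
perf <- run_batch(perfusion_scenario(), plant, n_trials = 10, base_seed = 1)
dist <- run_batch(disturbance_scenario(), plant, n_trials = 5, base_seed = 1)
perf$summary
dist$summary
```

`scripts/acceptance.R --seed 1 --out results/acceptance.json` runs
exactly this and writes the four medians as JSON.
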