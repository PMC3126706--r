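---
title: "lysisflow: a virtual pulsatile-flow rig for pressure-decline thrombolysis monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lysisflow: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lysisflow)
```

## The measurement idea

In-vitro thrombolysis experiments usually quantify clot dissolution by
weighing the clot or assaying wash-out, which means interrupting the
experiment and touching the clot. An alternative is hydraulic: hold the clot
in a carrier inside a flow loop driven with a physiological pulsatile
velocity profile, and record the pressure decline across the carrier,
`dP = P1 - P2`. The carrier's hydrodynamic resistance is monotone in how much
of its cavity the clot occupies, so `dP` (at known flow) is a non-contact,
time-continuous readout of clot size. `lysisflow` is a digital twin of such a
rig: every component — pump, tube, valve, carrier, flow meter, pressure
sensors, clot — is a model with explicit, documented parameters, so the whole
simulate → calibrate → analyze workflow can be exercised and tested end to
end.

## Hydraulic model

The circuit is lumped and quasi-steady: at each instant
`P1 = (R_carrier + R_valve + R_tube) Q` and `P2 = (R_valve + R_tube) Q`,
with `Q = v * pi * d^2 / 4` for the 6 mm tube. No inertance or compliance is
modelled; the analysis chain treats pressure declines as instantaneous
functions of flow, and adding inductive terms would change nothing
observable at the 1 Hz analysis grid while adding unidentifiable parameters.

The carrier's resistance surface is the parametric family

```
R(V, L) = R_empty + A_scale * g(L) * (1 + V^beta),
g(L) = 0                          for L <= L_knee
g(L) = exp(k_L * (L - L_knee)) - 1  otherwise
```

chosen as the minimal form with the three observed regimes: a
flow-independent floor at low filling, exponential growth in the filling
level, and power-law growth in velocity at high filling (eddying flow around
a nearly occluding clot). It is continuous in both arguments, nondecreasing
in `L`, bounded below by `R_empty > 0`, and identifiable from a triplicate
calibration grid. The empty carrier's own resistance is why a normalized
decline can never reach zero: complete dissolution plateaus at
`R_empty Q / <R(V, 1) Q>`, about 0.14 at the default working point.

The true carrier geometry is not dimensioned, so no Poiseuille-style
first-principles derivation is attempted, and the default surface parameters
(`R_empty = 1e8 Pa s/m^3`, `A_scale = 5e7`, `k_L = 3`, `beta = 1.5`,
`L_knee = 0.2`) are synthetic: they give a full-clot decline of ≈ 67 mmHg
and an empty-carrier decline of ≈ 8 mmHg at the default working point,
plausible for a bench loop of this scale. The family is deliberately exposed
as a fitted object (`fit_calibration()`), not a constant: anyone with real
calibration tables replaces the defaults by fitting.

### Working point

The carotid-like waveform is an analytic template (wrapped Gaussians for the
systolic peak, dicrotic notch and diastolic shoulder) affinely pinned so its
sampled minimum and maximum are exactly the commanded diastolic/systolic
velocities, 0.29 and 0.64 m/s by default (cycle mean 0.362 m/s). The heart
period defaults to 0.9 s; any plausible period works because all averaged
quantities are taken over integer cycle counts. The modulating valve is a
single lumped series resistance solved once by `calibrate_valve()` so the
cycle-mean upstream pressure is 130 mmHg with the carrier *empty* — on the
bench, flow and pressure are adjusted before the carrier is filled.

## Virtual sensors

Flow is measured by transit-time ultrasound velocimetry:
`v = (d/2)(1/t_plus - 1/t_minus)` with `t_pm = d/(c pm v)`, which makes the
meter exact in the absence of timing noise; the path length (0.01 m) and
sound speed (1520 m/s) cancel out of every accuracy statement by
construction. Sensor imperfections are emulated, not derived from acoustics:

* per-sample Gaussian timing jitter (default sd 0.5 ps, the scale a
  correlation-based meter achieves) puts the 5-minute mean's relative error
  well inside the 0.04 % accuracy bound;
* a slow multiplicative pump decay (amplitude drawn per run, at most 2 %,
  saturating with a 2 h time constant) plus a smooth sub-percent flow/
  temperature fluctuation keeps 4-h drift inside the 2.34 % stability bound;
* a pump load sensitivity (0.6 % velocity sag at full carrier load) keeps the
  filling-level dependence inside the 0.81 % bound.

These three bounds are reproduced as first-class experiments
(`flowmeter_accuracy_experiment()`, `pump_stability_experiment()`,
`load_independence_experiment()`). The pressure channels get iid Gaussian
noise (0.3 mmHg) plus a smooth drift *shared* by both channels; the drift of
the decline itself enters physically through the pump model, not through
independent sensor offsets, which is what makes the control-arm correction
below meaningful. Ultrasound attenuation is the scalar decibel law
`A = 10 log10(I0/I1)`; no beam physics is modelled.

## Clot dynamics

The clot state is two numbers: the filling fraction `L` of the cavity and a
compaction factor `c >= 1` multiplying the clot's resistance. The kinetics
are the minimal first-order structure reproducing the qualitative bench
observations:

```
dc/dt = (1 + a*s - c) / tau_c
dL/dt = -[ k_mech (1 - s) v + k_enz C(t) (g_us if US on else 1) ] L
```

`s` in (0, 1] is the incubation strength: a fully incubated, firm clot
(`s` near 1) compacts more and sheds less under flow; a briefly incubated
clot is softer and erodes faster. `C(t)` is the local rt-PA concentration in
the cavity, a single-time-constant rise toward the 60 kU/ml infusate during
the 60–120 min infusion (well-mixed 2.7 ml cavity against the 80 ml/h
infusion, time constant ≈ 2 min) and exponential washout afterwards.
Ultrasound multiplies the enzymatic channel by `g_us` (default 2) while on.
Mechanical and enzymatic channels are deliberately kept separate and both
active in the sonothrombolysis arm: the available observations cannot
attribute the late decline to one mechanism, so the model exposes both
rather than asserting a split.

Defaults were fitted once at the default working point so that the
noise-free normalized decline of a 2-h-incubation clot under flow alone ends
near 0.98 (after a transient rise above 1 while compaction outruns
attrition) and a 1-h-incubation clot under flow + rt-PA/ultrasound ends near
0.91: `k_mech = 1.385e-4 /s per (m/s)`, `k_enz = 2.92e-8 /s per (kU/ml)`,
compaction amplitude 0.021 with a 300 s time constant, `s = 0.98` (2 h) and
`0.96` (1 h). Under this constant-rate law the sonothrombolysis arm's
decline is spread over the whole 4 h rather than concentrated in the first
hour; a rate law with surface hardening could sharpen that, but would add
parameters nothing here constrains. Integration is explicit Euler at the
10 Hz pressure clock (`dt = 0.1 s`; both ODEs are slow, and halving `dt`
moves the final filling by far less than 0.1 %). `integrate_lysis()`
evaluates the identical recursion in vectorised form, which the tests check
against the per-step `step_clot_state()`.

## Analysis chain

For each group, the five rigid-POM control arms estimate the *biased error*
— the slow drift of the decline caused by flow and temperature fluctuation —
as the control-mean's excursion from its own starting value,
`D(t) = <dP_POM>(t) - <dP_POM>(0)`. Anchoring `D(0) = 0` makes the
correction drift-only: subtracting the full control level would also remove
the carrier's static offset and break the two structural properties the
readout is built on (the normalized decline starts at exactly 1, and it
cannot reach 0 while the empty carrier still resists flow). Each clot
replicate is then adjusted, `adj(t) = dP(t) - D(t)`, normalized by its own
initial value, and the five replicates are aggregated pointwise as mean ±
SEM (`sd/sqrt(n)`). The 10 Hz pressure streams are block-averaged into 1-s
bins first; that is the common grid with the 1 Hz flow stream, and it
averages over most of a cardiac cycle. A consequence worth knowing: 1-s bins
beat against the 0.9-s cycle, so individual bins wobble by a few percent
around the cycle mean — visible in single noise-free arms, irrelevant after
replicate averaging. The whole pipeline is invariant to any drift added in
common to clot and control arms, which the tests assert with random smooth
drifts.

When experiments at different velocities must be compared, or when lysis is
large enough that the empty-carrier floor matters, the normalized decline is
replaced by rating-curve conversion: the (fitted) resistance surface is
tabulated per velocity on a dense filling grid above the knee (below it the
map is flat and not invertible), inverted with a monotone piecewise-cubic
(Fritsch–Carlson) interpolant, and each measured decline is mapped to a
filling level, with out-of-range samples clipped and flagged. For pulsatile
recordings the cycle-mean velocity is used. For a velocity between tabulated
curves, a virtual curve is first interpolated linearly *in decline space*
and then inverted — interpolating the inverted levels instead is biased
wherever one bracketing curve saturates at full filling.

### Calibration fitting

`fit_calibration()` converts each calibration row to a resistance by Ohm's
law and fits the surface by nonlinear least squares on log-resistance
(multiplicative errors, as generated). The four smooth parameters are
profiled out with Levenberg–Marquardt on a log scale (positivity for free);
the knee, which enters non-smoothly, is scanned over candidate levels and
refined by 1-D minimisation of the profiled RSS. On a noise-free grid every
parameter is recovered to machine precision; at 2 % relative noise on the
default 5 × 11 × 3 grid the median error of every parameter over 100
simulated tables stays below 10 %, with `beta` and `A_scale` the least
certain (they trade off against each other along the velocity axis).

## What the generator does and does not emulate

The synthetic arms carry the statistical structure the analysis assumes:
pulsatile hydraulics, slow shared drift, iid sensor noise, independently
seeded replicates (a stated splitting rule derives each arm's seed from the
master seed and the arm labels, so any arm is reproducible in isolation).
They do *not* emulate donor-to-donor clot variability, non-Gaussian sensor
artefacts, partial clot detachment events, or any acoustic field structure —
so passing tests validate the measurement mathematics and the pipeline's
contracts, not biological realism. Replicate spread in the synthetic study
comes only from drift and noise, which makes the synthetic SEMs narrower
than bench SEMs; conclusions about statistical power on the bench should not
be drawn from them.

## Numerical choices and degenerate inputs

* Units: SI internally; mmHg (1 mmHg = 133.322 Pa) at every user-facing
  boundary.
* Zero flow: the decline is 0 and resistance is reported indeterminate
  (error) rather than 0/0.
* A non-positive initial adjusted decline makes a recording unusable and is
  rejected, since normalization divides by it.
* Rating curves refuse non-monotone tabulations (impossible within the
  family, possible for a hand-edited model).
* Problem sizes in the tests: full-length (4 h) simulations are used where
  the quantity under test demands them (drift, end-to-end recovery);
  structural checks run on 5–15 min designs, whose validity is
  duration-independent.

## Known limitations

* The constant-rate attrition law cannot produce a genuine late plateau in
  the treated arm; the modelled trajectory keeps creeping down slowly where
  a bench trace flattens.
* The compaction factor inflates the apparent filling recovered through
  rating curves by up to ~1 % of the cavity (compaction raises resistance
  without adding volume); the end-to-end recovery tolerance accounts for it.
* Significance testing between groups is intentionally out of scope: results
  are reported descriptively as mean ± SEM, and the test choice is left to
  the user.
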