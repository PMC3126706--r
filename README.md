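# lysisflow

A digital twin of an in-vitro pulsatile-flow thrombolysis rig, for anyone
who monitors clot lysis hydraulically: a clot is held in a custom carrier
inside a flow loop driven with a carotid-like pulsatile velocity profile,
and the pressure decline across the carrier, **ΔP = P1 − P2**, serves as a
non-contact, time-continuous readout of clot size. The package simulates the
whole rig — pump, tube, modulating valve, carrier, transit-time ultrasonic
flow meter, pressure sensors, and the clot itself — and implements the full
analysis chain that turns raw pressure recordings into lysis measurements.

The core pieces:

* **Carrier resistance surface.** `R(V, L) = R_empty + A·g(L)·(1 + V^β)`
  with `g(L) = e^{k_L (L − L_knee)} − 1` above a knee and 0 below: flow-
  independent when nearly empty, exponential in filling level `L`, power-law
  in velocity `V`. Fitted from triplicate calibration tables
  (`fit_calibration()`), inverted into per-velocity monotone **rating
  curves** (`build_rating_curves()`, `decline_to_lysis()`).
* **Virtual sensors.** Transit-time velocimetry
  `v = (d/2)(1/t₊ − 1/t₋)`, attenuation `A = 10·log₁₀(I₀/I₁)`, and
  noise/drift models sized to the bench reliability bounds (flow-meter
  accuracy ≤ 0.04 %, 4-h stability ≤ 2.34 %, load independence ≤ 0.81 %).
* **Clot dynamics.** Filling decays by flow-driven attrition plus
  rt-PA/ultrasound-enhanced enzymatic lysis,
  `dL/dt = −[k_mech(1−s)v + k_enz C(t) g_us]·L`, while a compaction factor
  transiently raises the clot's resistance.
* **Analysis chain.** Biased-error (drift) estimation from rigid-POM control
  arms, `D(t) = ⟨ΔP_POM⟩(t) − ⟨ΔP_POM⟩(0)`; error adjustment
  `adj(t) = ΔP(t) − D(t)`; the **normalized pressure decline**
  `ñ(t) = adj(t)/adj(0)` (exactly 1 at t = 0, bounded above 0 by the empty
  carrier's resistance); replicate aggregation as mean ± SEM.

## Worked example

Simulate the default four-arm study (groups A: flow only, 2-h incubation;
B: flow + sonothrombolysis at 60–120 min, 1-h incubation; each with 5
clot-filled and 5 POM-control arms, 4 h at 10 Hz pressure / 1 Hz flow) and
run the analysis chain:

```r
library(lysisflow)

study <- generate_study(study_design(seed = 1))
res <- analyze_study(study)
for (g in names(res)) {
  r <- res[[g]]
  cat(sprintf("group %s: n(60 min) = %.3f +/- %.3f   n(4 h) = %.3f +/- %.3f\n",
    g, r$mean[r$time_s == 3600], r$sem[r$time_s == 3600],
    r$mean[r$time_s == 14399], r$sem[r$time_s == 14399]))
}
#> group A: n(60 min) = 1.006 +/- 0.001   n(4 h) = 0.974 +/- 0.002
#> group B: n(60 min) = 0.998 +/- 0.001   n(4 h) = 0.910 +/- 0.002
```

Group A's decline first *rises* above 1 (the streaming fluid compacts the
clot into the carrier) and then settles just below 1 — a firm 2-h-incubation
clot barely lyses under flow alone. Group B's softer 1-h clot erodes faster
and, with rt-PA and ultrasound, ends near 0.91 of its initial decline.
`plot_normalized_decline(res)` draws the two mean ± SEM time courses.

Calibration and rating-curve conversion:

```r
tab <- generate_calibration_data(seed = 1)       # 5 velocities x 11 levels x 3
fit <- fit_calibration(tab)
unlist(fit[c("k_L", "beta", "L_knee")])
#>    k_L   beta L_knee
#>  3.007  1.433  0.199     # truth: 3, 1.5, 0.2 (2 % measurement noise)

curves <- build_rating_curves(fit)
decline_to_lysis(c(60, 50, 40), curves, velocity = 0.38)$filling
#> [1] 1.000 0.946 0.866    # mmHg -> filling fraction at 0.38 m/s
```

A thin command-line wrapper over the same functions lives at
`inst/cli/lysisflow.R` (subcommands `simulate`, `calibrate-data`,
`calibrate`, `analyze`, `report`).

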