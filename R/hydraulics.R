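# Lumped-parameter model of the flow circuit: pump -> tube -> clot carrier
# (P1 upstream, P2 downstream) -> modulating valve -> reservoir. Quasi-steady:
# pressures are instantaneous functions of flow and resistance, no
# inertance/compliance.

#' Circuit configuration
#'
#' Lumped description of the tube system: a 6 mm inner-diameter PVC tube, two
#' pressure taps 0.07 m up- and downstream of the clot carrier, a series tube
#' resistance and an adjustable modulating-valve resistance, Ringer solution
#' at 37 degrees C. Resistances are hydraulic (Pa.s/m^3).
#'
#' @param tube_inner_diameter m.
#' @param sensor_offset m, distance of each pressure tap from the carrier.
#' @param tube_resistance Pa.s/m^3, fixed series resistance of the tubing.
#' @param valve_resistance Pa.s/m^3, adjustable; see [calibrate_valve()].
#' @param fluid_density kg/m^3.
#' @param fluid_viscosity Pa.s.
#' @param temperature degrees C.
#' @param sound_speed m/s in the working fluid (used by the flow meter).
#' @return object of class `circuit_config`.
#' @export
circuit_config <- function(tube_inner_diameter = 0.006, sensor_offset = 0.07,
                           tube_resistance = 5e7, valve_resistance = 1.28e9,
                           fluid_density = 1000, fluid_viscosity = 7e-4,
                           temperature = 37, sound_speed = 1520) {
  vals <- c(tube_inner_diameter, sensor_offset, tube_resistance,
            valve_resistance, fluid_density, fluid_viscosity, temperature,
            sound_speed)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all circuit quantities must be finite and strictly positive",
         call. = FALSE)
  structure(list(tube_inner_diameter = tube_inner_diameter,
                 sensor_offset = sensor_offset,
                 tube_resistance = tube_resistance,
                 valve_resistance = valve_resistance,
                 fluid_density = fluid_density,
                 fluid_viscosity = fluid_viscosity,
                 temperature = temperature,
                 sound_speed = sound_speed),
            class = "circuit_config")
}

#' Parametric resistance model of the clot carrier
#'
#' Hydrodynamic resistance surface
#' `R(V, L) = R_empty + A_scale * g(L) * (1 + V^beta)` with
#' `g(L) = 0` for `L <= L_knee` and `exp(k_L * (L - L_knee)) - 1` above: a
#' flow-independent empty-carrier floor, exponential growth in filling level,
#' and power-law growth in velocity at high filling.
#'
#' @param R_empty Pa.s/m^3, resistance of the empty carrier.
#' @param k_L exponential filling coefficient (per unit filling fraction).
#' @param beta velocity power-law exponent.
#' @param A_scale Pa.s/m^3, coupling amplitude.
#' @param L_knee filling fraction below which resistance is flow-independent.
#' @return object of class `carrier_model`.
#' @export
carrier_model <- function(R_empty = 1e8, k_L = 3.0, beta = 1.5,
                          A_scale = 5e7, L_knee = 0.2) {
  if (!(R_empty > 0 && A_scale >= 0 && k_L >= 0 && beta > 0 &&
        L_knee >= 0 && L_knee < 1))
    stop("invalid carrier model parameters", call. = FALSE)
  structure(list(R_empty = R_empty, k_L = k_L, beta = beta,
                 A_scale = A_scale, L_knee = L_knee),
            class = "carrier_model")
}

#' @rdname carrier_model
#' @export
default_carrier <- function() carrier_model()

# filling-level gain g(L), 0 at/below the knee, vectorised
.carrier_gain <- function(model, filling) {
  ifelse(filling <= model$L_knee, 0,
         expm1(model$k_L * (filling - model$L_knee)))
}

#' Hydrodynamic resistance of the clot carrier
#'
#' Evaluates the parametric surface `R(V, L)`; nondecreasing in `L` at fixed
#' `V`, flow-independent for `L <= L_knee`, and never below `R_empty`.
#'
#' @param model a [carrier_model()].
#' @param filling filling fraction in `[0, 1]` (vectorised).
#' @param velocity flow velocity in m/s, within `[0, 0.95]` (vectorised).
#' @return hydraulic resistance in Pa.s/m^3.
#' @export
carrier_resistance <- function(model, filling, velocity) {
  stopifnot(inherits(model, "carrier_model"))
  if (any(!is.finite(filling)) || any(filling < 0) || any(filling > 1))
    stop("`filling` must lie in [0, 1]", call. = FALSE)
  if (any(!is.finite(velocity)) || any(velocity < 0) || any(velocity > 0.95))
    stop("`velocity` must lie in [0, 0.95]", call. = FALSE)
  model$R_empty +
    model$A_scale * .carrier_gain(model, filling) * (1 + velocity^model$beta)
}

#' Pressure decline across the clot carrier
#'
#' Ohm's-law quasi-steady decline `dP = R(V, L) * compaction * Q(v)`,
#' returned in mmHg. Zero velocity gives zero decline.
#'
#' @param circuit a [circuit_config()].
#' @param model a [carrier_model()].
#' @param filling filling fraction in `[0, 1]`.
#' @param velocity m/s (vectorised).
#' @param compaction multiplicative resistance factor (>= 1 for clots, 1
#'   otherwise).
#' @return pressure decline `P1 - P2` in mmHg.
#' @export
pressure_decline <- function(circuit, model, filling, velocity,
                             compaction = 1) {
  stopifnot(inherits(circuit, "circuit_config"))
  q <- velocity_to_flow(velocity, circuit$tube_inner_diameter)
  r <- carrier_resistance(model, filling, velocity) * compaction
  pa_to_mmhg(r * q)
}

#' Resistance from Ohm's law
#'
#' `R = dP / Q`; the exact inverse of [pressure_decline()] given the flow.
#' Zero or negative flow leaves the resistance indeterminate and is a domain
#' error.
#'
#' @param delta_p pressure decline in mmHg (vectorised).
#' @param flow volumetric flow in m^3/s (vectorised, > 0).
#' @return hydraulic resistance in Pa.s/m^3.
#' @export
resistance_from_ohm <- function(delta_p, flow) {
  if (any(!is.finite(flow)) || any(flow <= 0))
    stop("`flow` must be strictly positive; resistance is indeterminate at zero flow",
         call. = FALSE)
  mmhg_to_pa(delta_p) / flow
}

#' Mean pressure of a pulsatile series
#'
#' Time average of a pressure series sampled uniformly over an integer number
#' of cardiac cycles (the caller guarantees the integer-cycle coverage).
#'
#' @param pressure numeric vector in mmHg.
#' @return mean pressure in mmHg.
#' @export
mean_pressure <- function(pressure) {
  if (length(pressure) == 0L || any(!is.finite(pressure)))
    stop("`pressure` must be a non-empty finite series", call. = FALSE)
  mean(pressure)
}

#' Instantaneous sensor pressures of the circuit
#'
#' Quasi-steady pressures at the two taps relative to the reservoir:
#' `P2 = (R_tube + R_valve) * Q` and `P1 = P2 + R_carrier * Q`.
#'
#' @inheritParams pressure_decline
#' @return data.frame with columns `p1_mmHg`, `p2_mmHg`.
#' @export
circuit_pressures <- function(circuit, model, filling, velocity,
                              compaction = 1) {
  stopifnot(inherits(circuit, "circuit_config"))
  q <- velocity_to_flow(velocity, circuit$tube_inner_diameter)
  r_c <- carrier_resistance(model, filling, velocity) * compaction
  p2 <- pa_to_mmhg((circuit$tube_resistance + circuit$valve_resistance) * q)
  p1 <- p2 + pa_to_mmhg(r_c * q)
  data.frame(p1_mmHg = p1, p2_mmHg = p2)
}

#' Calibrate the modulating valve to a target mean pressure
#'
#' Solves for the valve resistance at which the cycle-averaged upstream
#' pressure equals `target_mp` for the given waveform and carrier filling.
#' This mirrors the bench procedure of adjusting flow and pressure before the
#' carrier is filled, so the default calibration uses `filling = 0`.
#'
#' @param circuit a [circuit_config()]; its valve resistance is replaced.
#' @param model a [carrier_model()].
#' @param waveform a [make_ica_waveform()] cycle.
#' @param target_mp target mean upstream pressure in mmHg.
#' @param filling carrier filling during calibration.
#' @return the circuit with `valve_resistance` set.
#' @export
calibrate_valve <- function(circuit, model, waveform, target_mp = 130,
                            filling = 0) {
  stopifnot(inherits(waveform, "pulsatile_waveform"))
  v <- waveform$velocities[-length(waveform$velocities)]
  f <- function(rv) {
    circuit$valve_resistance <- rv
    mean_pressure(circuit_pressures(circuit, model, filling, v)$p1_mmHg) -
      target_mp
  }
  sol <- stats::uniroot(f, lower = 1, upper = 1e12, tol = 1e-6)
  circuit$valve_resistance <- sol$root
  circuit
}

#' Default circuit, valve-calibrated to 130 mmHg mean pressure
#'
#' The shipped working point: default tube and carrier, carotid waveform
#' pinned to 0.29/0.64 m/s, valve solved so the mean upstream pressure over a
#' cycle is 130 mmHg with the carrier empty (pressures are adjusted before the
#' carrier is filled).
#'
#' @param target_mp mean upstream pressure in mmHg.
#' @return a calibrated `circuit_config`.
#' @export
default_circuit <- function(target_mp = 130) {
  calibrate_valve(circuit_config(), default_carrier(), make_ica_waveform(),
                  target_mp = target_mp, filling = 0)
}
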