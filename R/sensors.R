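# Virtual measurement chain: transit-time ultrasonic flow meter, pressure
# sensors, and the noise/drift models that emulate the bench rig's measured
# reliability (flow-meter accuracy, 4-h pump stability, load independence).

#' Transit-time ultrasound path geometry
#'
#' Two transducers facing each other, aligned parallel to the flow; the
#' time-of-flight is shorter with the flow (`t+`) than against it (`t-`).
#'
#' @param path_length transducer separation along the flow axis, m.
#' @param sound_speed speed of sound in the working fluid, m/s.
#' @return object of class `transit_time_path`.
#' @export
transit_time_path <- function(path_length = 0.01, sound_speed = 1520) {
  if (path_length <= 0 || sound_speed <= 0)
    stop("`path_length` and `sound_speed` must be positive", call. = FALSE)
  structure(list(path_length = path_length, sound_speed = sound_speed),
            class = "transit_time_path")
}

#' Sensor and pump noise/drift model
#'
#' Defaults are sized so the virtual rig sits inside the bench-measured
#' reliability bounds: per-sample timing jitter of the flow meter (accuracy
#' bound 0.04% on 5-min means), a slow multiplicative pump decay over 4 h
#' (stability bound 2.34%), and a pump load sensitivity to carrier filling
#' (bound 0.81%). Pressure channels get iid Gaussian noise plus a smooth
#' shared drift; the pressure-decline drift enters through the pump, not
#' through independent sensor offsets.
#'
#' @param timing_jitter_sd s, sd of per-sample time-of-flight jitter.
#' @param pressure_noise_sd mmHg, iid noise per pressure channel and sample.
#' @param pressure_drift_amplitude mmHg, bound on the smooth shared drift over
#'   a 4-h recording.
#' @param pump_drift_max_fraction maximum fractional slow decay of the pump
#'   output over 4 h.
#' @param pump_load_sensitivity fractional velocity loss at full carrier
#'   load.
#' @param seed optional integer; when set, simulation helpers seed the RNG.
#' @return object of class `sensor_noise_model`.
#' @export
sensor_noise_model <- function(timing_jitter_sd = 5e-13,
                               pressure_noise_sd = 0.3,
                               pressure_drift_amplitude = 1.5,
                               pump_drift_max_fraction = 0.02,
                               pump_load_sensitivity = 0.006,
                               seed = NULL) {
  vals <- c(timing_jitter_sd, pressure_noise_sd, pressure_drift_amplitude,
            pump_drift_max_fraction, pump_load_sensitivity)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("noise parameters must be finite and non-negative", call. = FALSE)
  structure(list(timing_jitter_sd = timing_jitter_sd,
                 pressure_noise_sd = pressure_noise_sd,
                 pressure_drift_amplitude = pressure_drift_amplitude,
                 pump_drift_max_fraction = pump_drift_max_fraction,
                 pump_load_sensitivity = pump_load_sensitivity,
                 seed = seed),
            class = "sensor_noise_model")
}

#' Transit-time velocimetry
#'
#' Velocity from the time-of-flight difference of the two emitting
#' directions: `v = (d/2) * (1/t+ - 1/t-)`. This is the exact inverse of
#' [times_from_velocity()]. If `t+ > t-` the (negative) reverse-flow velocity
#' is returned with a warning.
#'
#' @param t_plus time of flight in the flow direction, s.
#' @param t_minus time of flight against the flow, s.
#' @param path a [transit_time_path()].
#' @return velocity in m/s.
#' @export
transit_time_velocity <- function(t_plus, t_minus, path = transit_time_path()) {
  stopifnot(inherits(path, "transit_time_path"))
  if (any(t_plus <= 0) || any(t_minus <= 0))
    stop("times of flight must be positive", call. = FALSE)
  if (any(t_plus > t_minus))
    warning("t_plus > t_minus: reverse flow, returning negative velocity")
  (path$path_length / 2) * (1 / t_plus - 1 / t_minus)
}

#' Forward model of the transit times
#'
#' `t+- = d / (c +- v)`; requires `|v| < c`.
#'
#' @param velocity m/s (vectorised).
#' @inheritParams transit_time_velocity
#' @return list with components `t_plus`, `t_minus` (s).
#' @export
times_from_velocity <- function(velocity, path = transit_time_path()) {
  stopifnot(inherits(path, "transit_time_path"))
  if (any(abs(velocity) >= path$sound_speed))
    stop("|velocity| must be below the sound speed", call. = FALSE)
  list(t_plus = path$path_length / (path$sound_speed + velocity),
       t_minus = path$path_length / (path$sound_speed - velocity))
}

#' Simulate the ultrasonic flow meter
#'
#' Applies independent Gaussian timing jitter to each time of flight and
#' inverts with the transit-time formula; unbiased to first order and exact
#' when the jitter is zero.
#'
#' @param true_velocity numeric vector of true velocities, one per output
#'   sample (nominally 1 Hz).
#' @param path a [transit_time_path()].
#' @param noise a [sensor_noise_model()].
#' @param seed optional integer overriding `noise$seed`.
#' @return measured velocity vector, m/s.
#' @export
simulate_flowmeter <- function(true_velocity, path = transit_time_path(),
                               noise = sensor_noise_model(), seed = NULL) {
  stopifnot(inherits(noise, "sensor_noise_model"))
  seed <- if (is.null(seed)) noise$seed else seed
  if (!is.null(seed)) set.seed(seed)
  tt <- times_from_velocity(true_velocity, path)
  n <- length(true_velocity)
  tp <- tt$t_plus + stats::rnorm(n, 0, noise$timing_jitter_sd)
  tm <- tt$t_minus + stats::rnorm(n, 0, noise$timing_jitter_sd)
  (path$path_length / 2) * (1 / tp - 1 / tm)
}

#' Ultrasound attenuation in decibels
#'
#' `A = 10 * log10(I0 / I1)` between the unshielded reference intensity and
#' the intensity received inside the clot carrier; non-negative whenever
#' `I1 <= I0`, additive over cascaded stages.
#'
#' @param intensity_reference reference intensity `I0`, W/cm^2.
#' @param intensity_received received intensity `I1`, W/cm^2.
#' @return attenuation in dB.
#' @examples
#' attenuation_db(1, 0.186)  # ~7.3 dB
#' @export
attenuation_db <- function(intensity_reference, intensity_received) {
  if (any(intensity_reference <= 0) || any(intensity_received <= 0))
    stop("intensities must be strictly positive", call. = FALSE)
  10 * log10(intensity_reference / intensity_received)
}

# smooth zero-anchored drift: sum of slow sinusoids with random phases,
# rescaled so max |drift| over the window equals `amplitude`; drift(0) need
# not be 0 -- it is a shared offset wander, common to both channels
.smooth_drift <- function(t, amplitude, periods = c(14400, 9000, 5400)) {
  if (amplitude == 0 || length(t) == 0L) return(numeric(length(t)))
  raw <- rowSums(vapply(periods, function(p) {
    a <- stats::runif(1, 0.5, 1)
    phi <- stats::runif(1, 0, 2 * pi)
    a * sin(2 * pi * t / p + phi)
  }, numeric(length(t))))
  m <- max(abs(raw))
  if (m == 0) return(raw)
  amplitude * raw / m
}

# slow multiplicative pump decay: amplitude drawn once per run, saturating
# with a 2-h time constant (monotone decrease, <= pump_drift_max_fraction)
.pump_drift_factor <- function(t, noise, tau = 7200) {
  a <- noise$pump_drift_max_fraction * stats::runif(1, 0.6, 1)
  1 - a * (1 - exp(-t / tau))
}

# smooth multiplicative flow fluctuation ("small fluctuations of the flow
# velocity and temperature"); amplitude tied to the pump drift scale
.flow_fluctuation <- function(t, noise) {
  .smooth_drift(t, 0.15 * noise$pump_drift_max_fraction,
                periods = c(10800, 6600, 3000))
}

#' Simulate the two pressure sensors
#'
#' Adds iid Gaussian noise per channel plus a smooth drift shared by both
#' channels (so it cancels from the decline `P1 - P2`); drift of the decline
#' itself enters upstream through the pump/temperature model.
#'
#' @param p1,p2 true channel pressures in mmHg, sampled at `rate`.
#' @param noise a [sensor_noise_model()].
#' @param rate sampling rate, Hz.
#' @param seed optional integer overriding `noise$seed`.
#' @return data.frame `time_s`, `p1_mmHg`, `p2_mmHg`.
#' @export
simulate_pressure_sensors <- function(p1, p2, noise = sensor_noise_model(),
                                      rate = 10, seed = NULL) {
  stopifnot(inherits(noise, "sensor_noise_model"), length(p1) == length(p2))
  seed <- if (is.null(seed)) noise$seed else seed
  if (!is.null(seed)) set.seed(seed)
  n <- length(p1)
  t <- (seq_len(n) - 1L) / rate
  drift <- .smooth_drift(t, noise$pressure_drift_amplitude)
  data.frame(
    time_s = t,
    p1_mmHg = p1 + drift + stats::rnorm(n, 0, noise$pressure_noise_sd),
    p2_mmHg = p2 + drift + stats::rnorm(n, 0, noise$pressure_noise_sd)
  )
}
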