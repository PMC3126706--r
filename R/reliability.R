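# Virtual reproductions of the rig's three flow-reliability experiments:
# (1) flow-meter accuracy against the commanded velocity, (2) four-hour
# temporal stability of constant pump velocities, (3) independence of the
# delivered velocity from the carrier's filling level. Each returns the
# figure of merit the bench experiment reported.

#' Virtual flow-meter accuracy experiment
#'
#' Simulates constant-velocity runs across the pump's range, averages each
#' run's 1 Hz flow-meter readings, and returns the maximum relative error of
#' the mean reading versus the true velocity (bench bound: 0.04%).
#'
#' @param velocities commanded velocities, m/s.
#' @param duration s per run (5 min on the bench).
#' @param noise a [sensor_noise_model()].
#' @param path a [transit_time_path()].
#' @param seed optional integer seed.
#' @return maximum relative error of the mean, in percent.
#' @export
flowmeter_accuracy_experiment <- function(velocities = seq(0.095, 0.95,
                                                           length.out = 10),
                                          duration = 300,
                                          noise = sensor_noise_model(),
                                          path = transit_time_path(),
                                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  errs <- vapply(velocities, function(v) {
    m <- mean(simulate_flowmeter(rep(v, duration), path, noise, seed = NULL))
    abs(m - v) / v
  }, numeric(1))
  100 * max(errs)
}

#' Virtual four-hour pump stability experiment
#'
#' Simulates long constant-velocity runs under the default pump-drift model,
#' smooths the measured 1 Hz series with a 1-minute moving mean, and returns
#' the maximum percentage decrease from the initial smoothed value over the
#' runs (bench bound: 2.34%).
#'
#' @param velocities commanded velocities, m/s (bench: the diastolic and
#'   systolic working points 0.29 and 0.64).
#' @param duration s per run.
#' @inheritParams flowmeter_accuracy_experiment
#' @return maximum percentage decrease.
#' @export
pump_stability_experiment <- function(velocities = c(0.29, 0.64),
                                      duration = 14400,
                                      noise = sensor_noise_model(),
                                      path = transit_time_path(),
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dec <- vapply(velocities, function(v) {
    t <- seq_len(duration) - 1
    fac <- .pump_drift_factor(t, noise) * (1 + .flow_fluctuation(t, noise))
    meas <- simulate_flowmeter(v * fac, path, noise, seed = NULL)
    sm <- stats::filter(meas, rep(1 / 60, 60), sides = 1)
    sm <- sm[!is.na(sm)]
    100 * (sm[1] - min(sm)) / sm[1]
  }, numeric(1))
  max(dec)
}

#' Virtual load-independence experiment
#'
#' For each commanded velocity, simulates short runs at carrier filling
#' levels from 0 to 100% under the pump's load-sensitivity model and returns
#' the maximum relative deviation of the run means from the zero-filling
#' mean (bench bound: 0.81%).
#'
#' @param velocities commanded velocities, m/s.
#' @param levels filling fractions.
#' @param duration s per run (1 min on the bench).
#' @param carrier a [carrier_model()] (sets the load shape).
#' @inheritParams flowmeter_accuracy_experiment
#' @return maximum relative deviation, in percent.
#' @export
load_independence_experiment <- function(velocities = seq(0.19, 0.95,
                                                          length.out = 5),
                                         levels = seq(0, 1, by = 0.1),
                                         duration = 60,
                                         carrier = default_carrier(),
                                         noise = sensor_noise_model(),
                                         path = transit_time_path(),
                                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g1 <- .carrier_gain(carrier, 1)
  devs <- vapply(velocities, function(v) {
    means <- vapply(levels, function(L) {
      g <- .carrier_gain(carrier, L) / g1
      v_del <- v * (1 - noise$pump_load_sensitivity * g)
      mean(simulate_flowmeter(rep(v_del, duration), path, noise, seed = NULL))
    }, numeric(1))
    max(abs(means - means[1]) / means[1])
  }, numeric(1))
  100 * max(devs)
}
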