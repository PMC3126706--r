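# Carotid-like pulsatile velocity waveform: an analytic template of one
# cardiac cycle (systolic upstroke, dicrotic notch, diastolic decay) built from
# circularly wrapped Gaussians so the cycle is exactly periodic, then affinely
# pinned to the requested diastolic/systolic velocities.

# wrapped squared distance on the unit circle
.wrap_gauss <- function(tau, centre, width) {
  d <- abs(tau - centre)
  d <- pmin(d, 1 - d)
  exp(-(d / width)^2)
}

# dimensionless template over phase tau in [0, 1]
.ica_template <- function(tau) {
  1.10 * .wrap_gauss(tau, 0.13, 0.062) +
    0.45 * .wrap_gauss(tau, 0.42, 0.130) -
    0.18 * .wrap_gauss(tau, 0.31, 0.040) +
    0.10 * .wrap_gauss(tau, 0.55, 0.090)
}

#' Build an internal-carotid-like pulsatile velocity waveform
#'
#' One cardiac cycle of a smooth carotid velocity envelope (systolic upstroke,
#' dicrotic notch, diastolic decay), affinely scaled so the sampled minimum
#' equals `v_diastolic` and the maximum equals `v_systolic` exactly. The first
#' and last samples are equal, so the cycle tiles periodically.
#'
#' @param v_diastolic diastolic (minimum) velocity in m/s.
#' @param v_systolic systolic (maximum) velocity in m/s; equal values give a
#'   constant waveform.
#' @param period cardiac period in s.
#' @param n number of intervals per cycle (`n + 1` samples including both
#'   endpoints).
#' @return an object of class `pulsatile_waveform` with fields `period`,
#'   `sample_times`, `velocities`, `v_diastolic`, `v_systolic`.
#' @examples
#' wf <- make_ica_waveform(0.29, 0.64)
#' range(wf$velocities)
#' @export
make_ica_waveform <- function(v_diastolic = 0.29, v_systolic = 0.64,
                              period = 0.9, n = 256L) {
  if (!(v_diastolic > 0 && v_systolic <= 0.95 && v_diastolic <= v_systolic))
    stop("require 0 < v_diastolic <= v_systolic <= 0.95", call. = FALSE)
  if (period <= 0) stop("`period` must be positive", call. = FALSE)
  tau <- seq(0, 1, length.out = n + 1L)
  s <- .ica_template(tau)
  s[n + 1L] <- s[1L]  # exact periodicity (template already symmetric at wrap)
  if (v_diastolic == v_systolic) {
    v <- rep(v_diastolic, n + 1L)
  } else {
    v <- v_diastolic + (v_systolic - v_diastolic) *
      (s - min(s)) / (max(s) - min(s))
  }
  structure(
    list(period = period, sample_times = tau * period, velocities = v,
         v_diastolic = v_diastolic, v_systolic = v_systolic),
    class = "pulsatile_waveform"
  )
}

#' Evaluate a waveform at arbitrary times
#'
#' Returns a vectorised function of time that linearly interpolates the cycle
#' and wraps periodically.
#'
#' @param waveform a `pulsatile_waveform`.
#' @return `function(t)` giving velocity in m/s.
#' @export
waveform_fun <- function(waveform) {
  stopifnot(inherits(waveform, "pulsatile_waveform"))
  ts <- waveform$sample_times
  vs <- waveform$velocities
  p <- waveform$period
  function(t) stats::approx(ts, vs, xout = t %% p, rule = 2)$y
}

#' Cycle-mean velocity of a waveform
#'
#' Time average over one cycle (uniform grid; the duplicated endpoint is
#' dropped so the mean is the exact trapezoidal average of the periodic
#' signal).
#'
#' @param waveform a `pulsatile_waveform`.
#' @return mean velocity in m/s.
#' @export
mean_velocity <- function(waveform) {
  stopifnot(inherits(waveform, "pulsatile_waveform"))
  mean(waveform$velocities[-length(waveform$velocities)])
}

#' @export
print.pulsatile_waveform <- function(x, ...) {
  cat(sprintf(
    "pulsatile_waveform: period %.3g s, %d samples, %.3g-%.3g m/s (mean %.3g)\n",
    x$period, length(x$velocities), x$v_diastolic, x$v_systolic,
    mean_velocity(x)))
  invisible(x)
}
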