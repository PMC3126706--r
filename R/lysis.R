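# Phenomenological clot-state model. Two state variables: the filling
# fraction L of the carrier cavity and a multiplicative compaction factor on
# the clot's resistance. Compaction captures the early mechanically induced
# tightening of the occlusion; filling decays by flow-driven attrition and by
# enzymatic (rt-PA) lysis, the latter amplified while ultrasound is on.

#' Clot state
#'
#' @param filling fraction of the carrier cavity occupied, in `[0, 1]`.
#' @param compaction multiplicative resistance factor, `>= 1`.
#' @return object of class `clot_state`.
#' @export
clot_state <- function(filling = 1, compaction = 1) {
  if (!(filling >= 0 && filling <= 1)) stop("`filling` must be in [0, 1]",
                                            call. = FALSE)
  if (compaction < 1) stop("`compaction` must be >= 1", call. = FALSE)
  structure(list(filling = filling, compaction = compaction),
            class = "clot_state")
}

#' Lysis kinetics parameters
#'
#' First-order two-channel kinetics:
#' `dL/dt = -[k_mech * (1 - s) * v + k_enz * C * (us_gain if US else 1)] * L`,
#' where `s` is the incubation strength (1 = fully incubated, mechanically
#' robust clot; smaller values mean less compact clots with more surface
#' attrition) and `C` the local rt-PA concentration. Compaction relaxes toward
#' `1 + compaction_amplitude * s` with time constant `compaction_tau`.
#'
#' Defaults were fitted once at the default working point (carotid waveform
#' pinned to 0.29/0.64 m/s, mean velocity 0.362 m/s) so that the noise-free
#' normalized pressure decline ends near 0.98 for a 2-h-incubation clot under
#' flow alone and near 0.91 for a 1-h-incubation clot under flow plus
#' rt-PA/ultrasound in the 60-120 min window; they are emulation defaults,
#' not biological constants.
#'
#' @param k_mech attrition rate, 1/s per (m/s).
#' @param k_enz enzymatic rate, 1/s per (kU/ml).
#' @param us_gain multiplier (>= 1) on `k_enz` while ultrasound is on.
#' @param compaction_amplitude dimensionless compaction rise at `s = 1`.
#' @param compaction_tau s, compaction relaxation time constant.
#' @param incubation_strength in `(0, 1]`; 0.98 for 2-h incubation (group-A
#'   style), 0.96 for 1-h incubation (group-B style).
#' @param compaction_max upper clip for the compaction factor.
#' @return object of class `lysis_params`.
#' @export
lysis_params <- function(k_mech = 1.385e-4, k_enz = 2.92e-8, us_gain = 2,
                         compaction_amplitude = 0.021, compaction_tau = 300,
                         incubation_strength = 0.98, compaction_max = 1.5) {
  vals <- c(k_mech, k_enz, compaction_amplitude, compaction_tau)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("rates and compaction parameters must be non-negative", call. = FALSE)
  if (us_gain < 1) stop("`us_gain` must be >= 1", call. = FALSE)
  if (!(incubation_strength > 0 && incubation_strength <= 1))
    stop("`incubation_strength` must lie in (0, 1]", call. = FALSE)
  structure(list(k_mech = k_mech, k_enz = k_enz, us_gain = us_gain,
                 compaction_amplitude = compaction_amplitude,
                 compaction_tau = compaction_tau,
                 incubation_strength = incubation_strength,
                 compaction_max = compaction_max),
            class = "lysis_params")
}

#' @rdname lysis_params
#' @param group `"A"` (2-h incubation, flow only) or `"B"` (1-h incubation,
#'   sonothrombolysis arm).
#' @export
default_lysis_params <- function(group = c("A", "B")) {
  group <- match.arg(group)
  lysis_params(incubation_strength = if (group == "A") 0.98 else 0.96)
}

#' rt-PA infusion schedule
#'
#' 80 ml of an rt-PA/plasma mixture (60 kU/ml) infused at a constant rate
#' over one hour starting at t = 60 min, into the carrier cavity of dead
#' volume `carrier_dead_volume` which is continuously washed out through the
#' cavity-connected channels.
#'
#' @param start s, infusion start.
#' @param duration s, infusion duration.
#' @param total_volume ml infused.
#' @param concentration kU/ml of the infusate.
#' @param carrier_dead_volume ml, well-mixed cavity volume.
#' @return object of class `drug_schedule`.
#' @export
drug_schedule <- function(start = 3600, duration = 3600, total_volume = 80,
                          concentration = 60, carrier_dead_volume = 2.7) {
  vals <- c(start, duration, total_volume, concentration, carrier_dead_volume)
  if (any(!is.finite(vals)) || any(vals[-1] <= 0) || start < 0)
    stop("invalid drug schedule", call. = FALSE)
  structure(list(start = start, duration = duration,
                 total_volume = total_volume, concentration = concentration,
                 carrier_dead_volume = carrier_dead_volume,
                 tau = carrier_dead_volume / (total_volume / duration)),
            class = "drug_schedule")
}

#' Local rt-PA concentration in the carrier cavity
#'
#' Well-mixed cavity against washout: zero before the infusion starts, a
#' single-time-constant rise toward the infusate concentration during the
#' infusion, exponential decay after it stops.
#'
#' @param t time in s (vectorised).
#' @param schedule a [drug_schedule()].
#' @return concentration in kU/ml.
#' @export
local_drug_concentration <- function(t, schedule = drug_schedule()) {
  stopifnot(inherits(schedule, "drug_schedule"))
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  stop_t <- schedule$start + schedule$duration
  c_stop <- schedule$concentration * (1 - exp(-schedule$duration / schedule$tau))
  out <- numeric(length(t))
  during <- t >= schedule$start & t <= stop_t
  after <- t > stop_t
  out[during] <- schedule$concentration *
    (1 - exp(-(t[during] - schedule$start) / schedule$tau))
  out[after] <- c_stop * exp(-(t[after] - stop_t) / schedule$tau)
  out
}

#' Advance the clot state by one time step
#'
#' Explicit Euler step of the compaction relaxation and the two-channel
#' filling decay; the state invariants (`filling` in `[0, 1]`, `compaction`
#' in `[1, compaction_max]`) are enforced by clipping.
#'
#' @param state a [clot_state()].
#' @param params a [lysis_params()].
#' @param velocity instantaneous flow velocity, m/s (shear proxy).
#' @param drug local rt-PA concentration, kU/ml.
#' @param ultrasound_on logical flag.
#' @param dt time step, s, in `(0, 1]`.
#' @return the advanced `clot_state`.
#' @export
step_clot_state <- function(state, params, velocity, drug = 0,
                            ultrasound_on = FALSE, dt = 0.1) {
  stopifnot(inherits(state, "clot_state"), inherits(params, "lysis_params"))
  if (!(dt > 0 && dt <= 1)) stop("`dt` must be in (0, 1]", call. = FALSE)
  s <- params$incubation_strength
  target <- 1 + params$compaction_amplitude * s
  comp <- state$compaction +
    dt * (target - state$compaction) / params$compaction_tau
  rate <- params$k_mech * (1 - s) * velocity +
    params$k_enz * drug * (if (isTRUE(ultrasound_on)) params$us_gain else 1)
  filling <- state$filling * (1 - dt * rate)
  clot_state(min(max(filling, 0), 1),
             min(max(comp, 1), params$compaction_max))
}

#' Integrate the clot state over an experiment
#'
#' Explicit time stepping at `dt` with the velocity either sampled from the
#' waveform or supplied per step; drug concentration follows the schedule
#' (if any) and ultrasound is on inside `ultrasound_window`. The returned
#' series is aligned to the stepping clock (`time = 0, dt, ..., horizon`).
#'
#' @param initial a [clot_state()].
#' @param params a [lysis_params()].
#' @param waveform a [make_ica_waveform()]; ignored when `velocities` given.
#' @param schedule a [drug_schedule()] or `NULL` for no drug.
#' @param horizon s, total duration (typically 14400).
#' @param dt s, step size in `(0, 1]`.
#' @param ultrasound_window `c(start, stop)` in s, or `NULL`.
#' @param velocities optional velocity per step (length `horizon/dt + 1`).
#' @return data.frame `time_s`, `filling`, `compaction`.
#' @export
integrate_lysis <- function(initial, params, waveform = make_ica_waveform(),
                            schedule = NULL, horizon = 14400, dt = 0.1,
                            ultrasound_window = NULL, velocities = NULL) {
  stopifnot(inherits(initial, "clot_state"), inherits(params, "lysis_params"))
  if (!(dt > 0 && dt <= 1)) stop("`dt` must be in (0, 1]", call. = FALSE)
  t <- seq(0, horizon, by = dt)
  n <- length(t)
  if (is.null(velocities)) velocities <- waveform_fun(waveform)(t)
  if (length(velocities) != n)
    stop("`velocities` must have one value per step", call. = FALSE)
  drug <- if (is.null(schedule)) numeric(n) else
    local_drug_concentration(t, schedule)
  us <- if (is.null(ultrasound_window)) rep(FALSE, n) else
    (t >= ultrasound_window[1] & t < ultrasound_window[2])

  # vectorised explicit-Euler solution of the same recursion step_clot_state
  # performs: both ODEs are linear in the state at each step
  s <- params$incubation_strength
  rate <- params$k_mech * (1 - s) * velocities +
    params$k_enz * drug * ifelse(us, params$us_gain, 1)
  filling <- initial$filling *
    cumprod(c(1, pmax(1 - dt * rate[-n], 0)))
  filling <- pmin(pmax(filling, 0), 1)
  target <- 1 + params$compaction_amplitude * s
  a <- 1 - dt / params$compaction_tau
  comp <- target + (initial$compaction - target) * a^(seq_len(n) - 1L)
  comp <- pmin(pmax(comp, 1), params$compaction_max)
  if (any(!is.finite(filling)) || any(!is.finite(comp)))
    stop("non-finite clot state during integration (dt too large?)",
         call. = FALSE)
  data.frame(time_s = t, filling = filling, compaction = comp)
}
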