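# Synthetic-study generator: drives hydraulics + lysis dynamics + virtual
# sensors end-to-end to produce the four-arm study (groups A/B x CLOT/POM,
# n = 5 each, 4 h, dual pressure at 10 Hz and flow at 1 Hz) and the
# triplicate calibration tables.

ARM_GROUPS <- c("A", "B")
ARM_FILLINGS <- c("CLOT", "POM")

#' Study design
#'
#' Two groups (A: flow only, 2-h incubation; B: flow plus rt-PA/ultrasound in
#' the 60-120 min window, 1-h incubation), each with `replicates` clot-filled
#' runs and `replicates` rigid-POM control runs; POM arms hold filling = 1
#' with zero lysis rates throughout.
#'
#' @param replicates runs per arm (>= 2 so the SEM is defined).
#' @param duration s, recording length.
#' @param ultrasound_window `c(start, stop)` in s, applied in group B.
#' @param seed master seed; per-arm seeds derive from it (see
#'   [arm_seed()]).
#' @return object of class `study_design`.
#' @export
study_design <- function(replicates = 5, duration = 14400,
                         ultrasound_window = c(3600, 7200), seed = 1L) {
  if (replicates < 2) stop("`replicates` must be >= 2 (SEM)", call. = FALSE)
  if (duration <= 0) stop("`duration` must be positive", call. = FALSE)
  structure(list(groups = ARM_GROUPS, fillings = ARM_FILLINGS,
                 replicates = as.integer(replicates), duration = duration,
                 ultrasound_window = ultrasound_window,
                 seed = as.integer(seed)),
            class = "study_design")
}

#' Derive a per-arm seed from the master seed
#'
#' Splitting rule: arms are enumerated in the fixed order (group, filling,
#' replicate) and `seed_arm = (master + 7919 * (index + 1)) mod (2^31 - 1)`,
#' so every arm is independently reproducible from `(master, arm)`.
#'
#' @param master master integer seed.
#' @param group `"A"` or `"B"`.
#' @param filling `"CLOT"` or `"POM"`.
#' @param replicate replicate index (1-based).
#' @param replicates replicates per arm in the enumeration.
#' @return integer seed.
#' @export
arm_seed <- function(master, group, filling, replicate, replicates = 5) {
  gi <- match(group, ARM_GROUPS) - 1L
  fi <- match(filling, ARM_FILLINGS) - 1L
  if (is.na(gi) || is.na(fi)) stop("unknown group or filling", call. = FALSE)
  idx <- gi * 2L * replicates + fi * replicates + (replicate - 1L)
  as.integer((as.numeric(master) + 7919 * (idx + 1)) %% 2147483647)
}

#' Simulate one experimental arm end-to-end
#'
#' Drives the pump (waveform x slow drift x load sensitivity), the clot
#' dynamics (CLOT arms only; POM controls hold filling = 1, compaction = 1),
#' the quasi-steady circuit pressures, and the virtual sensors, producing a
#' 10 Hz dual-pressure recording and a 1 Hz flow recording. Fully
#' reproducible from `(design$seed, group, filling, replicate)`.
#'
#' @param group `"A"` or `"B"`.
#' @param filling `"CLOT"` or `"POM"`.
#' @param replicate replicate index.
#' @param design a [study_design()].
#' @param circuit a [circuit_config()].
#' @param carrier a [carrier_model()].
#' @param params a [lysis_params()]; defaults to the group's defaults.
#' @param schedule a [drug_schedule()] (applied in group B only).
#' @param noise a [sensor_noise_model()].
#' @param waveform a [make_ica_waveform()].
#' @return object of class `experiment_recording`: list with `pressure`
#'   (data.frame `time_s`, `p1_mmHg`, `p2_mmHg` at 10 Hz), `flow`
#'   (data.frame `time_s`, `v_mps` at 1 Hz), and `meta`; the noise-free truth
#'   (filling, compaction, delivered velocity, true decline) is attached as
#'   attribute `"truth"`.
#' @export
simulate_experiment <- function(group, filling, replicate = 1L,
                                design = study_design(),
                                circuit = default_circuit(),
                                carrier = default_carrier(),
                                params = default_lysis_params(group),
                                schedule = drug_schedule(),
                                noise = sensor_noise_model(),
                                waveform = make_ica_waveform()) {
  stopifnot(inherits(design, "study_design"))
  seed <- arm_seed(design$seed, group, filling, replicate, design$replicates)
  set.seed(seed)
  dt <- 0.1
  t10 <- seq(0, design$duration, by = dt)
  v_cmd <- waveform_fun(waveform)(t10)
  drift_mult <- .pump_drift_factor(t10, noise) * (1 + .flow_fluctuation(t10, noise))
  v_pump <- v_cmd * drift_mult

  if (filling == "CLOT") {
    traj <- integrate_lysis(
      clot_state(), params, schedule = if (group == "B") schedule else NULL,
      horizon = design$duration, dt = dt,
      ultrasound_window = if (group == "B") design$ultrasound_window else NULL,
      velocities = v_pump)
    L <- traj$filling
    comp <- traj$compaction
  } else {
    L <- rep(1, length(t10))
    comp <- rep(1, length(t10))
  }

  # pump load sensitivity: delivered velocity sags with the carrier load
  g_norm <- .carrier_gain(carrier, L) / .carrier_gain(carrier, 1)
  v_del <- pmin(v_pump * (1 - noise$pump_load_sensitivity * g_norm), 0.95)

  pr <- circuit_pressures(circuit, carrier, L, v_del, comp)
  pressure <- simulate_pressure_sensors(pr$p1_mmHg, pr$p2_mmHg, noise,
                                        rate = 1 / dt, seed = NULL)
  i1 <- seq(1L, length(t10), by = as.integer(1 / dt))
  flow <- data.frame(
    time_s = t10[i1],
    v_mps = simulate_flowmeter(v_del[i1],
                               transit_time_path(sound_speed = circuit$sound_speed),
                               noise, seed = NULL))
  rec <- structure(
    list(pressure = pressure, flow = flow,
         meta = list(group = group, filling = filling,
                     replicate = as.integer(replicate), seed = seed,
                     duration = design$duration,
                     pressure_rate_hz = 1 / dt, flow_rate_hz = 1)),
    class = "experiment_recording")
  attr(rec, "truth") <- data.frame(
    time_s = t10, filling = L, compaction = comp, v_mps = v_del,
    delta_p_mmHg = pr$p1_mmHg - pr$p2_mmHg)
  rec
}

#' @export
print.experiment_recording <- function(x, ...) {
  m <- x$meta
  cat(sprintf(
    "experiment_recording %s/%s replicate %d: %d pressure rows @%g Hz, %d flow rows\n",
    m$group, m$filling, m$replicate, nrow(x$pressure), m$pressure_rate_hz,
    nrow(x$flow)))
  invisible(x)
}

#' Generate the full four-arm study
#'
#' All `2 groups x 2 fillings x replicates` recordings, deterministically
#' seeded per arm.
#'
#' @inheritParams simulate_experiment
#' @param keep_truth keep the per-arm noise-free truth attribute (drop to
#'   save memory).
#' @return named list of [simulate_experiment()] recordings, names
#'   `"<group>_<filling>_<replicate>"`.
#' @export
generate_study <- function(design = study_design(),
                           circuit = default_circuit(),
                           carrier = default_carrier(),
                           schedule = drug_schedule(),
                           noise = sensor_noise_model(),
                           waveform = make_ica_waveform(),
                           keep_truth = TRUE) {
  arms <- expand.grid(replicate = seq_len(design$replicates),
                      filling = ARM_FILLINGS, group = ARM_GROUPS,
                      stringsAsFactors = FALSE)
  out <- vector("list", nrow(arms))
  names(out) <- sprintf("%s_%s_%d", arms$group, arms$filling, arms$replicate)
  for (i in seq_len(nrow(arms))) {
    rec <- simulate_experiment(arms$group[i], arms$filling[i],
                               arms$replicate[i], design, circuit, carrier,
                               params = default_lysis_params(arms$group[i]),
                               schedule = schedule, noise = noise,
                               waveform = waveform)
    if (!keep_truth) attr(rec, "truth") <- NULL
    out[[i]] <- rec
  }
  out
}

#' Generate a triplicate calibration table
#'
#' Emulates the bench calibration of the carrier: for each commanded velocity
#' and filling level, `replicates` independent pressure-decline measurements
#' (the rig was fully disassembled and reassembled between repeats, so
#' replicate errors are independent) with multiplicative Gaussian noise.
#'
#' @param model a [carrier_model()] (the truth being measured).
#' @param circuit a [circuit_config()].
#' @param velocities commanded velocities, m/s, in `(0, 0.95]`.
#' @param levels filling fractions in `[0, 1]`.
#' @param replicates repeats per cell.
#' @param noise_sd relative (coefficient-of-variation) measurement noise.
#' @param seed optional integer seed.
#' @return data.frame `velocity_mps`, `level_pct`, `replicate`,
#'   `delta_p_mmHg` of class `calibration_table`.
#' @export
generate_calibration_data <- function(model = default_carrier(),
                                      circuit = default_circuit(),
                                      velocities = seq(0.19, 0.95, length.out = 5),
                                      levels = seq(0, 1, by = 0.1),
                                      replicates = 3, noise_sd = 0.02,
                                      seed = NULL) {
  if (length(velocities) == 0L || length(levels) == 0L)
    stop("empty calibration grid", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(replicate = seq_len(replicates), level = levels,
                      velocity = velocities)
  dp <- pressure_decline(circuit, model, grid$level, grid$velocity)
  obs <- dp * (1 + stats::rnorm(nrow(grid), 0, noise_sd))
  structure(
    data.frame(velocity_mps = grid$velocity, level_pct = 100 * grid$level,
               replicate = grid$replicate, delta_p_mmHg = obs),
    class = c("calibration_table", "data.frame"))
}
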