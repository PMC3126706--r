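mk_series <- function(dp, t = seq_along(dp) - 1) {
  data.frame(time_s = t, delta_p_mmHg = dp)
}

test_that("biased error is the control mean's excursion from its own start", {
  t <- 0:99
  flat <- list(mk_series(rep(50, 100)), mk_series(rep(52, 100)))
  expect_true(all(biased_error(flat)$drift_mmHg == 0))
  # linear ramp controls give a linear drift anchored at zero
  ramp <- list(mk_series(50 + 0.1 * t), mk_series(52 + 0.3 * t))
  d <- biased_error(ramp)
  expect_equal(d$drift_mmHg[1], 0)
  expect_equal(d$drift_mmHg, 0.2 * t)
  expect_error(biased_error(flat[1]), ">= 2")
  expect_error(biased_error(list(mk_series(rep(1, 10)),
                                 mk_series(rep(1, 11)))), "grid")
})

test_that("error adjustment subtracts drift and preserves the start", {
  t <- 0:99
  clot <- mk_series(60 - 0.05 * t)
  zero <- data.frame(time_s = t, drift_mmHg = rep(0, 100))
  expect_equal(error_adjust(clot, zero)$delta_p_mmHg, clot$delta_p_mmHg)
  # a ramp added to clot and controls alike cancels exactly
  ramp <- 0.2 * t
  controls <- list(mk_series(50 + ramp), mk_series(52 + ramp))
  adj <- error_adjust(mk_series(clot$delta_p_mmHg + ramp),
                      biased_error(controls))
  expect_equal(adj$delta_p_mmHg, clot$delta_p_mmHg)
  expect_equal(adj$delta_p_mmHg[1], clot$delta_p_mmHg[1])
})

test_that("normalization starts at exactly 1 and rejects unusable series", {
  expect_true(all(normalize_decline(mk_series(rep(42, 10))) == 1))
  n <- normalize_decline(mk_series(c(50, 45, 40)))
  expect_identical(n[1], 1)
  expect_error(normalize_decline(mk_series(c(0, 1, 2))), "positive")
  expect_error(normalize_decline(mk_series(c(-5, 1, 2))), "positive")
})

test_that("aggregation returns pointwise mean and sd/sqrt(n)", {
  reps <- list(rep(1, 5), rep(1, 5), rep(1, 5))
  agg <- aggregate_replicates(reps)
  expect_true(all(agg$sem == 0))
  expect_equal(aggregate_replicates(list(0.9, 1.1))$mean, 1.0)
  expect_error(aggregate_replicates(list(1:3)), "2 replicates")
  # SEM agrees with a brute-force resampling estimate of the SE of the mean
  set.seed(21)
  reps <- replicate(5, 1 + rnorm(50, 0, 0.05), simplify = FALSE)
  agg <- aggregate_replicates(reps)
  m <- do.call(cbind, reps)
  boot <- replicate(4000, {
    i <- sample(5, replace = TRUE)
    rowMeans(m[, i, drop = FALSE])
  })
  # bootstrap SE carries the n/(n-1) small-sample factor
  boot_se <- apply(boot, 1, sd) * sqrt(5 / 4)
  expect_equal(mean(agg$sem), mean(boot_se), tolerance = 0.1)
})

test_that("pipeline output is invariant to drift shared by clot and controls", {
  des <- short_design(duration = 400)
  base <- quiet_noise()
  clot <- decline_series(simulate_experiment("A", "CLOT", 1, des,
                                             test_circuit, test_carrier,
                                             noise = base))
  controls <- lapply(1:2, function(i)
    decline_series(simulate_experiment("A", "POM", i, des, test_circuit,
                                       test_carrier, noise = base)))
  norm0 <- normalize_decline(error_adjust(clot, biased_error(controls)))
  set.seed(31)
  for (k in 1:5) {
    # random smooth drift: low-order polynomial + slow sinusoid
    t <- clot$time_s
    drift <- runif(1, -2, 2) * (t / max(t)) +
      runif(1, -1, 1) * (t / max(t))^2 +
      runif(1, -1, 1) * sin(2 * pi * t / runif(1, 200, 600))
    clot_d <- mk_series(clot$delta_p_mmHg + drift, t)
    ctrl_d <- lapply(controls, function(s)
      mk_series(s$delta_p_mmHg + drift, t))
    norm_d <- normalize_decline(error_adjust(clot_d, biased_error(ctrl_d)))
    expect_equal(norm_d, norm0, tolerance = 1e-9)
  }
})

test_that("analyze_study yields exact unit starts and coherent group curves", {
  des <- short_design(duration = 300, replicates = 3)
  study <- generate_study(des, test_circuit, test_carrier,
                          noise = sensor_noise_model(), keep_truth = FALSE)
  res <- analyze_study(study)
  expect_setequal(names(res), c("A", "B"))
  for (g in names(res)) {
    reps <- attr(res[[g]], "replicates")
    expect_true(all(reps[1, ] == 1))
    expect_identical(res[[g]]$mean[1], 1)
    expect_equal(res[[g]]$n[1], 3)
    expect_true(all(res[[g]]$mean > 0))
  }
})

test_that("complete dissolution plateaus at the empty-carrier floor", {
  # crank the enzymatic rate so the clot fully dissolves, without noise; the
  # normalized decline must land on R_empty / R(full) rather than 0
  des <- study_design(replicates = 2, duration = 1800,
                      ultrasound_window = c(0, 1800), seed = 2L)
  par <- lysis_params(k_enz = 2e-4, incubation_strength = 0.98,
                      compaction_amplitude = 0)
  sch <- drug_schedule(start = 0, duration = 1800, carrier_dead_volume = 0.5)
  rec <- simulate_experiment("B", "CLOT", 1, des, test_circuit, test_carrier,
                             params = par, schedule = sch,
                             noise = quiet_noise())
  expect_lt(tail(attr(rec, "truth")$filling, 1), 1e-3)
  d <- decline_series(rec)
  norm <- normalize_decline(d)
  # closed-form floor: cycle-averaged empty-carrier decline over the
  # cycle-averaged full-clot decline (the pulsatile averages, not the
  # resistances at the mean velocity)
  v <- test_waveform$velocities[-length(test_waveform$velocities)]
  q <- velocity_to_flow(v, test_circuit$tube_inner_diameter)
  floor_ratio <- test_carrier$R_empty * mean(q) /
    mean(carrier_resistance(test_carrier, rep(1, length(v)), v) * q)
  # average the last 10 full 1-s bins (the trailing bin holds a single
  # diastolic sample and is not a cycle average)
  late <- mean(norm[(length(norm) - 10):(length(norm) - 1)])
  expect_gt(late, 0)
  expect_equal(late, floor_ratio, tolerance = 0.02)
})
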