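test_that("local drug concentration follows infusion and washout", {
  sch <- drug_schedule()
  expect_equal(local_drug_concentration(c(0, 1800, 3599), sch), rep(0, 3))
  # with washout much shorter than the infusion, the plateau reaches the
  # infusate concentration of 60 kU/ml
  expect_equal(local_drug_concentration(7200, sch), 60, tolerance = 1e-3)
  # decays after stop
  post <- local_drug_concentration(c(7200, 7500, 9000), sch)
  expect_true(all(diff(post) < 0))
  # area under the curve is proportional to the infused concentration
  t <- seq(0, 14400, by = 1)
  auc1 <- sum(local_drug_concentration(t, sch))
  sch2 <- drug_schedule(concentration = 120)
  auc2 <- sum(local_drug_concentration(t, sch2))
  expect_equal(auc2 / auc1, 2, tolerance = 1e-9)
})

test_that("zero rates are a fixed point of the clot dynamics", {
  p0 <- lysis_params(k_mech = 0, k_enz = 0, compaction_amplitude = 0)
  s <- clot_state(0.8, 1)
  s2 <- step_clot_state(s, p0, velocity = 0.5, drug = 60,
                        ultrasound_on = TRUE, dt = 1)
  expect_equal(s2$filling, 0.8)
  expect_equal(s2$compaction, 1)
  traj <- integrate_lysis(s, p0, horizon = 100, dt = 0.5)
  expect_true(all(traj$filling == 0.8))
  expect_true(all(traj$compaction == 1))
  expect_error(step_clot_state(s, p0, 0.5, dt = 0), "dt")
})

test_that("vectorised integration reproduces the per-step recursion", {
  p <- default_lysis_params("B")
  sch <- drug_schedule(start = 10, duration = 30)
  dt <- 0.5
  t <- seq(0, 60, by = dt)
  v <- waveform_fun(test_waveform)(t)
  traj <- integrate_lysis(clot_state(), p, schedule = sch, horizon = 60,
                          dt = dt, ultrasound_window = c(10, 40),
                          velocities = v)
  s <- clot_state()
  for (k in seq_len(length(t) - 1)) {
    s <- step_clot_state(s, p, v[k], local_drug_concentration(t[k], sch),
                         t[k] >= 10 && t[k] < 40, dt)
  }
  expect_equal(tail(traj$filling, 1), s$filling, tolerance = 1e-12)
  expect_equal(tail(traj$compaction, 1), s$compaction, tolerance = 1e-12)
})

test_that("integration converges under step halving", {
  p <- default_lysis_params("B")
  run <- function(dt) tail(integrate_lysis(clot_state(), p,
                                           schedule = drug_schedule(start = 600, duration = 600),
                                           horizon = 3600, dt = dt,
                                           ultrasound_window = c(600, 1200),
                                           velocities = NULL,
                                           waveform = test_waveform)$filling, 1)
  expect_lt(abs(run(1) / run(0.5) - 1), 0.001)
})

test_that("filling is non-increasing and monotone in every rate parameter", {
  base <- lysis_params(compaction_amplitude = 0)
  traj <- integrate_lysis(clot_state(), base, schedule = drug_schedule(start = 60, duration = 120),
                          horizon = 600, dt = 0.5, ultrasound_window = c(60, 180),
                          waveform = test_waveform)
  expect_true(all(diff(traj$filling) <= 0))
  final <- function(par) tail(integrate_lysis(clot_state(), par,
                                              schedule = drug_schedule(start = 60, duration = 120),
                                              horizon = 600, dt = 0.5,
                                              ultrasound_window = c(60, 180),
                                              waveform = test_waveform)$filling, 1)
  # final filling decreases along each parameter axis
  for (nm in c("k_mech", "k_enz", "us_gain")) {
    vals <- lapply(c(1, 2, 4), function(f) {
      par <- base; par[[nm]] <- par[[nm]] * f
      final(par)
    })
    expect_true(all(diff(unlist(vals)) < 0), info = nm)
  }
  # doubling the enzymatic rate lowers filling at every time after the start
  tr1 <- integrate_lysis(clot_state(), base, schedule = drug_schedule(start = 60, duration = 120),
                         horizon = 600, dt = 0.5, ultrasound_window = c(60, 180),
                         waveform = test_waveform)
  b2 <- base; b2$k_enz <- 2 * base$k_enz
  tr2 <- integrate_lysis(clot_state(), b2, schedule = drug_schedule(start = 60, duration = 120),
                         horizon = 600, dt = 0.5, ultrasound_window = c(60, 180),
                         waveform = test_waveform)
  # never above, and strictly below once the cavity concentration has risen
  # (the washout time constant delays the drug by a few seconds)
  expect_true(all(tr2$filling <= tr1$filling))
  after <- tr1$time_s > 80
  expect_true(all(tr2$filling[after] < tr1$filling[after]))
})

test_that("group-B defaults lyse faster than group-A defaults", {
  run <- function(g) {
    sch <- if (g == "B") drug_schedule() else NULL
    win <- if (g == "B") c(3600, 7200) else NULL
    integrate_lysis(clot_state(), default_lysis_params(g), schedule = sch,
                    horizon = 7200, dt = 1, ultrasound_window = win,
                    waveform = test_waveform)
  }
  a <- run("A"); b <- run("B")
  expect_lt(tail(b$filling, 1), tail(a$filling, 1))
})
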