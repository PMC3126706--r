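test_that("waveform pins the printed diastolic/systolic values exactly", {
  wf <- make_ica_waveform(0.29, 0.64)
  expect_identical(min(wf$velocities), 0.29)
  expect_identical(max(wf$velocities), 0.64)
  # periodic: first and last sample equal
  expect_identical(wf$velocities[1], wf$velocities[length(wf$velocities)])
  expect_true(all(wf$velocities >= 0 & wf$velocities <= 0.95))
  # equal targets give a constant waveform
  expect_true(all(make_ica_waveform(0.4, 0.4)$velocities == 0.4))
  # scaling is affine: two differently pinned cycles correlate perfectly
  w2 <- make_ica_waveform(0.10, 0.90)
  expect_equal(cor(wf$velocities, w2$velocities), 1)
  expect_error(make_ica_waveform(0.5, 0.3), "v_diastolic")
  expect_error(make_ica_waveform(0.3, 0.99), "0.95")
})

test_that("POM control arms are stationary over repeated cycles without noise", {
  des <- short_design(duration = 90)
  rec <- simulate_experiment("A", "POM", 1, des, test_circuit, test_carrier,
                             noise = quiet_noise())
  dp <- rec$pressure$p1_mmHg - rec$pressure$p2_mmHg
  # one cycle is 0.9 s = 9 samples at 10 Hz; compare successive cycles
  n_cyc <- 9
  m <- matrix(dp[1:(n_cyc * 90)], nrow = n_cyc)
  expect_lt(max(abs(m - m[, 1])), 1e-9)
})

test_that("clot and control arms share hydraulics and differ only by lysis", {
  des <- short_design(duration = 300)
  clot <- simulate_experiment("A", "CLOT", 1, des, test_circuit, test_carrier,
                              noise = quiet_noise())
  pom <- simulate_experiment("A", "POM", 1, des, test_circuit, test_carrier,
                             noise = quiet_noise())
  dpc <- clot$pressure$p1_mmHg - clot$pressure$p2_mmHg
  dpp <- pom$pressure$p1_mmHg - pom$pressure$p2_mmHg
  # identical at t = 0 (same full carrier, compaction 1)
  expect_equal(dpc[1], dpp[1], tolerance = 1e-9)
  # later the clot's compaction has raised its decline above the control's
  expect_gt(mean(dpc[2500:3000]), mean(dpp[2500:3000]))
})

test_that("study generation is deterministic and correctly sized", {
  des <- short_design(seed = 5L)
  study <- generate_study(des, test_circuit, test_carrier, keep_truth = FALSE)
  expect_length(study, 4 * des$replicates)
  for (rec in study) {
    expect_equal(nrow(rec$pressure), des$duration * 10 + 1)
    expect_equal(nrow(rec$flow), des$duration + 1)
    expect_true(all(rec$pressure$p1_mmHg - rec$pressure$p2_mmHg > -1))
  }
  # replicates are distinct, regeneration is bit-identical
  expect_false(identical(study[["A_CLOT_1"]]$pressure$p1_mmHg,
                         study[["A_CLOT_2"]]$pressure$p1_mmHg))
  study2 <- generate_study(des, test_circuit, test_carrier, keep_truth = FALSE)
  expect_identical(study, study2)
  # a different master seed changes the data
  study3 <- generate_study(short_design(seed = 6L), test_circuit,
                           test_carrier, keep_truth = FALSE)
  expect_false(identical(study[["A_CLOT_1"]]$pressure,
                         study3[["A_CLOT_1"]]$pressure))
})

test_that("per-arm seeds are unique under the splitting rule", {
  arms <- expand.grid(g = c("A", "B"), f = c("CLOT", "POM"), i = 1:5,
                      stringsAsFactors = FALSE)
  seeds <- mapply(arm_seed, 1L, arms$g, arms$f, arms$i)
  expect_equal(length(unique(seeds)), nrow(arms))
  expect_true(all(seeds > 0 & seeds < 2^31))
})

test_that("calibration tables have the bench layout and invert exactly", {
  tab <- generate_calibration_data(test_carrier, test_circuit, noise_sd = 0)
  # 5 velocities x 11 levels x 3 replicates
  expect_equal(nrow(tab), 165)
  expect_setequal(names(tab),
                  c("velocity_mps", "level_pct", "replicate", "delta_p_mmHg"))
  expect_equal(tab$delta_p_mmHg,
               pressure_decline(test_circuit, test_carrier,
                                tab$level_pct / 100, tab$velocity_mps))
  # replicate coefficient of variation matches the requested noise
  tabn <- generate_calibration_data(test_carrier, test_circuit,
                                    velocities = 0.5, levels = 0.8,
                                    replicates = 3000, noise_sd = 0.02,
                                    seed = 2)
  expect_equal(sd(tabn$delta_p_mmHg) / mean(tabn$delta_p_mmHg), 0.02,
               tolerance = 0.05)
})

test_that("synthetic group-A declines rise transiently in the first minutes", {
  # compaction outruns attrition early: max over the first 10 min exceeds
  # the t = 0 value
  des <- study_design(replicates = 2, duration = 600, seed = 3L)
  rec <- simulate_experiment("A", "CLOT", 1, des, test_circuit, test_carrier,
                             noise = quiet_noise())
  d <- decline_series(rec)
  norm <- normalize_decline(d)
  expect_gt(max(norm), norm[1])
})
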