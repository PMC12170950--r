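test_that("rendered frames realise the requested geometry", {
  f <- small_frame(posture_spec(90, 50, 10, 10))
  # CA 90: tragus centre directly above the C7 centre
  expect_equal(f$truth$tragus[["x"]], f$truth$c7[["x"]])
  expect_lt(f$truth$tragus[["y"]], f$truth$c7[["y"]])
  # rendered marker centres reproduce the requested angles to sub-pixel
  expect_lt(abs(craniovertebral_angle(f$truth$c7, f$truth$tragus) - 90), 0.5)
  expect_lt(abs(shoulder_angle(f$truth$acromion, f$truth$c7) - 50), 0.5)
})

test_that("set-point frames are recovered by the full pipeline within 1 degree", {
  for (spec in list(fhp_posture(), nhp_posture())) {
    s <- process_stream(list(small_frame(spec)$image))
    expect_lt(abs(s$ca_deg - spec$ca_deg), 1.0)
    expect_lt(abs(s$sa_deg - spec$sa_deg), 1.0)
  }
})

test_that("geometry that does not fit the canvas is a layout error", {
  expect_error(render_posture_frame(fhp_posture(), canvas = c(200, 200),
                                    baseline_px = 300),
               "layout")
})

test_that("simulated accelerometer streams invert the tilt computation", {
  s <- simulate_accel_stream(30, 50, noise_sd_deg = 0)
  tilt <- tilt_from_acceleration(s$ax_g, s$ay_g, s$az_g)
  expect_equal(tilt, rep(30, 50), tolerance = 1e-6)
  # unit norm throughout
  expect_equal(sqrt(s$ax_g^2 + s$ay_g^2 + s$az_g^2), rep(1, 50))

  flat <- simulate_accel_stream(0, 10, noise_sd_deg = 0)
  expect_true(all(flat$ax_g == 0))

  expect_error(simulate_accel_stream(95, 10), "invalid spec")
})

test_that("noisy stream mean tilt converges to the target (fixed seed)", {
  s <- simulate_accel_stream(25, 1000, noise_sd_deg = 0.2, seed = 7)
  tilt <- tilt_from_acceleration(s$ax_g, s$ay_g, s$az_g)
  expect_lt(abs(mean(tilt) - 25), 0.05)
  expect_gt(stats::sd(tilt), 0.1)   # noise actually present
})

test_that("protocol truth has the documented phase structure", {
  p <- protocol_spec()
  truth <- posturekit:::.protocol_truth(p)
  expect_identical(nrow(truth), 240L)
  expect_identical(truth$phase, c(rep("phase1", 120), rep("transition", 5),
                                  rep("phase2", 115)))
  expect_true(all(truth$true_ca[truth$phase == "phase1"] == 40))
  expect_true(all(truth$true_ca[truth$phase == "phase2"] == 55))
  # linear interpolation across the 5 s transition
  expect_equal(diff(truth$true_ca[121:126]), rep(3, 5))

  step <- posturekit:::.protocol_truth(
    protocol_spec(total_s = 10, phase1_s = 5, transition_s = 0))
  expect_identical(step$true_ca, c(rep(40, 5), rep(55, 5)))
})

test_that("protocol bundles are deterministic under a fixed seed", {
  p <- protocol_spec(total_s = 12, phase1_s = 5, transition_s = 2,
                     jitter_sd_deg = 0.3, seed = 99L)
  d1 <- file.path(withr::local_tempdir(), "a")
  d2 <- file.path(withr::local_tempdir(), "b")
  b1 <- generate_protocol(p, outdir = d1)
  b2 <- generate_protocol(p, outdir = d2)
  for (f in c("upper_back.csv", "mid_back.csv", "ground_truth.csv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  # and a different seed actually changes the noise
  b3 <- generate_protocol(protocol_spec(total_s = 12, phase1_s = 5,
                                        transition_s = 2, seed = 100L))
  expect_false(identical(b1$upper$ax_g, b3$upper$ax_g))
})

test_that("a short protocol bundle feeds the whole pipeline coherently", {
  p <- protocol_spec(total_s = 8, phase1_s = 4, transition_s = 0, seed = 5L)
  dir <- withr::local_tempdir()
  b <- generate_protocol(p, outdir = dir, canvas = c(520, 760),
                         marker_px = 30, baseline_px = 150)
  expect_identical(length(b$frames), 8L)
  cam <- process_stream(file.path(dir, "frames"))
  expect_identical(nrow(cam), 8L)
  expect_equal(cam$t_s, b$truth$t_s)  # sample-for-sample time alignment
  expect_true(all(abs(cam$ca_deg - b$truth$true_ca) < 1.0))
  ks <- pair_streams(read_sensor_csv(file.path(dir, "upper_back.csv"),
                                     "upper_back"),
                     read_sensor_csv(file.path(dir, "mid_back.csv"),
                                     "mid_back"))
  expect_equal(ks$t_s, b$truth$t_s)
  expect_true(all(abs(ks$ka_deg -
                        (b$truth$true_alpha + b$truth$true_beta)) < 1.0))
})
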