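test_that("build-up curve basics: zero at t=0, reference rate identity", {
  p <- default_params()
  expect_equal(simulate_buildup(3.0, p, grid = c(0, 50))[1], 0)
  expect_equal(transfer_rate(p$r_ref, p), p$k_ref)
  expect_error(simulate_buildup(-1, p), "positive")
  expect_error(simulate_buildup(2, p, grid = numeric()), "empty")
})

test_that("intensity is strictly decreasing in distance at every t > 0", {
  p <- default_params()
  grid <- default_mixing_grid()
  ## non-increasing over the full range (short distances saturate to the
  ## same plateau within double precision, so ties are tolerated there)
  rs <- seq(1.5, 6.5, by = 0.25)
  curves <- sapply(rs, simulate_buildup, params = p, grid = grid)
  for (i in seq_along(grid)) {
    expect_true(all(diff(curves[i, ]) <= 0), info = sprintf("t = %g", grid[i]))
  }
  ## strictly decreasing wherever the transfer is unsaturated
  rs2 <- seq(3, 6.5, by = 0.25)
  curves2 <- sapply(rs2, simulate_buildup, params = p, grid = grid)
  for (i in seq_along(grid)) {
    expect_true(all(diff(curves2[i, ]) < 0), info = sprintf("t = %g", grid[i]))
  }
})

test_that("normalization fixes the control plateau at one and is idempotent", {
  p <- buildup_params(amp = 7.3)
  tab <- generate_buildup_dataset(calibration_geometry(), p, noise_rms = 0)
  norm <- normalize_to_control(tab, "C12-C20")
  expect_equal(attr(norm, "control_plateau"), 7.3, tolerance = 1e-6)
  ## fitted plateau of the normalized control is 1
  cal <- calibrate_buildup(norm, calibration_geometry())
  expect_equal(cal$amp, 1, tolerance = 1e-6)
  ## idempotence
  norm2 <- normalize_to_control(norm, "C12-C20")
  expect_equal(norm2$intensity, norm$intensity, tolerance = 1e-9)
  ## scale invariance
  tab2 <- tab
  tab2$intensity <- tab2$intensity * 2
  norm_b <- normalize_to_control(tab2, "C12-C20")
  expect_equal(norm_b$intensity, norm$intensity, tolerance = 1e-9)
})

test_that("normalization requires the control at every mixing time", {
  tab <- generate_buildup_dataset(calibration_geometry(), noise_rms = 0)
  drop <- !(tab$pair == "C12-C20" & tab$t_mix_ms == 400)
  expect_error(normalize_to_control(tab[drop, ], "C12-C20"), "400")
  expect_error(normalize_to_control(tab, "nope"), "not present")
})

test_that("calibration recovers the generating parameters from clean curves", {
  p <- buildup_params(k_ref = 0.035, T_damp = 1200, amp = 1)
  tab <- generate_buildup_dataset(calibration_geometry(), p, noise_rms = 0)
  cal <- calibrate_buildup(tab, calibration_geometry())
  expect_equal(cal$k_ref, p$k_ref, tolerance = 1e-6)
  expect_equal(cal$T_damp, p$T_damp, tolerance = 1e-6)
  expect_equal(cal$amp, p$amp, tolerance = 1e-6)
  ## per-pair residuals are numerically zero
  expect_true(all(attr(cal, "calibration")$rms_per_pair < 1e-8))
  expect_length(attr(cal, "calibration")$outliers, 0)
})

test_that("calibration rejects under-determined sets and flags mislabels", {
  tab <- noiseless_calibration_table()
  two <- calibration_geometry()[calibration_geometry()$distance < 3, ]
  expect_error(calibrate_buildup(tab, two), "3 distinct")
  ## mislabel one pair by 2 A: its residual dominates
  wrong <- calibration_geometry()
  wrong$distance[wrong$pair == "Cys187CB-Gly188CA"] <- 2.6
  cal <- calibrate_buildup(tab, wrong)
  expect_true("Cys187CB-Gly188CA" %in% attr(cal, "calibration")$outliers)
})

test_that("noiseless inversion round-trips across the working range", {
  p <- default_params()
  for (r0 in seq(1.5, 6.0, by = 0.25)) {
    est <- infer_distance(simulate_buildup(r0, p), p, noise_rms = 0, n_mc = 0)
    expect_equal(est$r_hat, r0, tolerance = 1e-3, info = sprintf("r = %g", r0))
  }
})

test_that("curve fitting agrees with a brute-force grid search", {
  p <- default_params()
  grid <- default_mixing_grid()
  for (r0 in c(2.1, 3.7, 5.3)) {
    curve <- simulate_buildup(r0, p, grid)
    rs <- seq(1, 8, by = 0.001)
    obj <- vapply(rs, function(r) {
      sum((curve - simulate_buildup(r, p, grid))^2)
    }, numeric(1))
    brute <- rs[which.min(obj)]
    est <- infer_distance(curve, p, noise_rms = 0, n_mc = 0)
    expect_lt(abs(est$r_hat - brute), 0.05)
  }
})

test_that("Monte-Carlo sigma shrinks monotonically with the noise level", {
  p <- default_params()
  curve <- simulate_buildup(4.6, p)
  sigmas <- vapply(c(0.02, 0.01, 0.005), function(nr) {
    infer_distance(curve, p, noise_rms = nr, n_mc = 300, seed = 21,
                   assume_present = TRUE)$sigma
  }, numeric(1))
  expect_true(all(diff(sigmas) < 0))
  expect_true(all(sigmas > 0))
})

test_that("absent calls: zero curves, pure noise, saturated detection limit", {
  p <- default_params()
  est <- infer_distance(rep(0, 6), p, noise_rms = 0, n_mc = 0)
  expect_equal(est$status, "absent")
  expect_true(is.na(est$r_hat))
  expect_gte(est$detection_limit, 6.0)
  expect_lte(est$detection_limit, 6.5)
  set.seed(12)
  noise_curve <- rnorm(6, 0, 0.02)
  expect_equal(infer_distance(noise_curve, p, noise_rms = 0.02,
                              n_mc = 0)$status, "absent")
})

test_that("detection thresholding follows the 3-sigma rule", {
  expect_equal(detect_crosspeak(c(0.01, 0.2), 0.02), "present")
  expect_equal(detect_crosspeak(c(0.01, 0.015), 0.02), "absent")
  expect_equal(detect_crosspeak(rep(0, 6), 0), "absent")
})

test_that("a 7 A pair is undetected in at least 95% of replicates", {
  p <- default_params()
  clean <- simulate_buildup(7, p)
  set.seed(7)
  absent <- vapply(1:200, function(i) {
    detect_crosspeak(clean + rnorm(length(clean), 0, 0.02), 0.02) == "absent"
  }, logical(1))
  expect_gte(mean(absent), 0.95)
})

test_that("flat saturated objectives report the shorter edge with wide sigma", {
  p <- default_params()
  est <- infer_distance(simulate_buildup(1.2, p), p, noise_rms = 0, n_mc = 0)
  expect_lte(est$r_hat, 1.2)
  expect_gt(est$sigma, 0)
})

test_that("table-level inversion averages replicates and labels pairs", {
  p <- default_params()
  tab <- generate_buildup_dataset(
    data.frame(pair = c("a", "b"), distance = c(3.0, 4.5)),
    p, noise_rms = 0.01, replicates = 4, seed = 5)
  est <- infer_distances(tab, p, n_mc = 0)
  expect_equal(est$pair, c("a", "b"))
  expect_equal(est$r_hat, c(3.0, 4.5), tolerance = 0.1)
  expect_true(all(est$status == "estimated"))
})
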