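test_that("pixel-to-velocity conversion is the linear VENC map", {
  meta <- test_meta(n_frames = 4, venc = 10, raw_scale = 100)
  raws <- c(100, 0, -50, 25)            # endpoints, midpoint, linearity
  frames <- array(0, c(4, 8, 8))
  frames[, 4, 4] <- raws
  mask <- roi_mask(cbind(4, 4), shape = c(8, 8), kind = "target")
  field <- to_velocity(phase_series(frames, meta), mask)
  expect_equal(drop(field$velocities), c(10, 0, -5, 2.5))
  expect_identical(field$corrections_applied, "venc_scaling")

  # linearity: scaling the raw data scales the velocities
  field2 <- to_velocity(phase_series(frames * 0.4, meta), mask)
  expect_equal(field2$velocities, field$velocities * 0.4)
})

test_that("bias estimation: constant, sinusoid and noise cases", {
  meta <- test_meta(n_frames = 20)
  # constant reference field -> bias = constant, zero spread
  f <- make_field(matrix(1.7, 20, 5), meta, kind = "reference",
                  corrections = "venc_scaling")
  b <- estimate_bias(f)
  expect_equal(b$value, 1.7)
  expect_equal(b$noise_spread, 0)

  # c + zero-mean sinusoid over the full cycle: global mean is exactly c
  tt <- csfflow:::frame_times(meta)
  sine <- 0.9 * sin(2 * pi * tt / meta$cycle_duration + 0.3)
  f2 <- make_field(matrix(0.25 + sine, 20, 4), meta, kind = "reference",
                   corrections = "venc_scaling")
  b2 <- estimate_bias(f2, mode = "per_frame")
  expect_equal(b2$value, 0.25, tolerance = 1e-12)
  expect_equal(b2$reference_mean_curve, 0.25 + sine)

  # zero-mean Gaussian noise: estimate concentrates as 3*sigma/sqrt(n)
  meta_n <- test_meta(n_frames = 100)
  set.seed(42)
  sigma <- 0.5
  v <- matrix(rnorm(100 * 100, sd = sigma), 100, 100)
  b3 <- estimate_bias(make_field(v, meta_n, kind = "reference",
                                 corrections = "venc_scaling"))
  expect_lt(abs(b3$value), 3 * sigma / sqrt(length(v)))
  expect_equal(b3$noise_spread, sigma, tolerance = 0.05)

  # only reference masks qualify
  ft <- make_field(matrix(0, 20, 2), meta, kind = "target",
                   corrections = "venc_scaling")
  expect_error(estimate_bias(ft), "reference ROI")
})

test_that("bias subtraction inverts an added constant and applies once", {
  meta <- test_meta(n_frames = 10)
  set.seed(3)
  v <- matrix(rnorm(10 * 6), 10, 6)
  f <- make_field(v + 0.31, meta,
                  corrections = c("venc_scaling", "aliasing_correction"))
  ref <- make_field(matrix(0.31, 10, 9), meta, kind = "reference",
                    corrections = "venc_scaling")
  out <- subtract_bias(f, estimate_bias(ref))
  expect_equal(out$velocities, v, tolerance = 1e-14)
  expect_true("bias_subtraction" %in% out$corrections_applied)
  expect_error(subtract_bias(out, estimate_bias(ref)), "already applied")

  # zero bias is the identity
  zref <- make_field(matrix(0, 10, 9), meta, kind = "reference",
                     corrections = "venc_scaling")
  f2 <- make_field(v, meta,
                   corrections = c("venc_scaling", "aliasing_correction"))
  expect_identical(subtract_bias(f2, estimate_bias(zref))$velocities, v)

  # per-frame mode subtracts each frame's reference mean
  curve <- seq(-0.2, 0.2, length.out = 10)
  pref <- make_field(matrix(curve, 10, 9), meta, kind = "reference",
                     corrections = "venc_scaling")
  out2 <- subtract_bias(f2, estimate_bias(pref, mode = "per_frame"))
  expect_equal(out2$velocities, v - curve, tolerance = 1e-14)
})

test_that("aliasing correction unwraps 2*VENC jumps and is idempotent", {
  meta <- test_meta(n_frames = 30, venc = 10)
  tt <- csfflow:::frame_times(meta)
  true_v <- 15 * sin(2 * pi * tt / meta$cycle_duration)  # peak 1.5*VENC
  wrapped <- csfflow:::wrap_velocity(true_v, 10)
  expect_equal(max(true_v), 15)
  expect_lt(max(wrapped), 10)            # the peak got wrapped to -0.5*VENC

  f <- make_field(cbind(wrapped, wrapped), meta,
                  corrections = "venc_scaling")
  out <- correct_aliasing(f)
  expect_equal(out$velocities[, 1], true_v, tolerance = 1e-9)
  # consecutive-jump invariant, including the periodic closure
  jumps <- diff(c(out$velocities[, 1], out$velocities[1, 1]))
  expect_true(all(abs(jumps) <= 10 + 1e-12))

  # idempotence and no-op on unaliased data
  again <- correct_aliasing(out)
  expect_identical(again$velocities, out$velocities)
  small <- make_field(cbind(3 * sin(2 * pi * tt / meta$cycle_duration)),
                      meta, corrections = "venc_scaling")
  expect_equal(correct_aliasing(small)$velocities, small$velocities)

  # order contract: no unwrapping after bias subtraction
  done <- make_field(cbind(wrapped), meta)
  expect_error(correct_aliasing(done), "precede bias subtraction")
})

test_that("mean velocity curve averages pixels and commutes with bias", {
  meta <- test_meta(n_frames = 12)
  set.seed(8)
  v <- matrix(rnorm(12), 12, 1)
  expect_identical(mean_velocity_curve(make_field(v, meta)), drop(v))

  # antisymmetric pair of pixels cancels
  f2 <- make_field(cbind(v, -v), meta)
  expect_equal(mean_velocity_curve(f2), rep(0, 12))

  # commutes with global bias subtraction
  f3 <- make_field(matrix(rnorm(12 * 5), 12, 5), meta,
                   corrections = c("venc_scaling", "aliasing_correction"))
  ref <- make_field(matrix(0.4, 12, 4), meta, kind = "reference",
                    corrections = "venc_scaling")
  b <- estimate_bias(ref)
  expect_equal(mean_velocity_curve(subtract_bias(f3, b)),
               mean_velocity_curve(f3) - b$value, tolerance = 1e-14)
})

test_that("parabolic profile ROI mean approaches half the centre velocity", {
  # Poiseuille profile v(r) = v_c (1 - r^2/R^2) has continuum spatial mean
  # v_c/2; a 200x200 pixelation of a radius-90 lumen should be within 1%.
  v_c <- 4
  truth <- flow_ground_truth(mean_velocity_offset = v_c,
                             pulsatile_amplitude = 0, noise_sd = 0,
                             profile = "parabolic",
                             center = c(100.5, 100.5), radius_px = 90)
  sim <- simulate_acquisition(truth, default_sim_meta(),
                              image_shape = c(200, 200), seed = 1,
                              reference_offset = c(-97, -97),
                              reference_halfwidth = 2L)
  field <- to_velocity(sim$series, sim$target)
  expect_equal(mean(mean_velocity_curve(field)), v_c / 2,
               tolerance = 0.01)
})

test_that("low-SNR flagging compares cycle amplitude to noise", {
  meta <- test_meta(n_frames = 20)
  tt <- csfflow:::frame_times(meta)
  strong <- make_field(matrix(5 * sin(2 * pi * tt / meta$cycle_duration),
                              20, 4), meta)
  flat <- make_field(matrix(0.001 * sin(2 * pi * tt / meta$cycle_duration),
                            20, 4), meta)
  set.seed(1)
  ref <- make_field(matrix(rnorm(20 * 9, sd = 0.5), 20, 9), meta,
                    kind = "reference", corrections = "venc_scaling")
  b <- estimate_bias(ref)
  expect_false(flag_low_snr(strong, b))
  expect_true(flag_low_snr(flat, b))
})
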