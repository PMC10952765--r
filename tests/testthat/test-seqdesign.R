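test_that("hard pulses satisfy flip = gamma * B1 * duration", {
  sc <- scanner()
  b <- hard_pulse(pi / 2, 5e-4, gamma = sc$gamma)
  expect_equal(Mod(b$rf$amplitude), (pi / 2) / (267.538e6 * 5e-4),
               tolerance = 1e-4)
  expect_equal(Mod(hard_pulse(0, 5e-4)$rf$amplitude), 0)
  a1 <- Mod(hard_pulse(pi / 3, 2e-4)$rf$amplitude)
  a2 <- Mod(hard_pulse(pi / 3, 4e-4)$rf$amplitude)
  expect_equal(a1, 2 * a2)
  expect_error(hard_pulse(pi / 2, 1e-5, b1_max = 1e-6), "exceeds")
})

test_that("EPI geometry and timing match the Cartesian relations", {
  sc <- scanner()
  sq <- epi_sequence(0.23, 100, te = 100e-3, scanner = sc)
  adcs <- Filter(Negate(is.null), lapply(sq$blocks, function(b) b$adc))
  expect_equal(sum(vapply(adcs, `[[`, 0L, "num_samples")), 10000L)
  k <- k_trajectory(sq, sc$gamma)
  dk <- 1 / 0.23
  expect_equal(dk, 4.3478, tolerance = 1e-4)
  # every line visited exactly once, serpentine order, on the ideal raster
  ky_line <- vapply(k, function(m) mean(m[, 2]), 0)
  expect_equal(ky_line, ((0:99) - 50) * dk, tolerance = 1e-6)
  kx_first <- vapply(k, function(m) m[1, 1], 0)
  expect_equal(kx_first[1], -50 * dk, tolerance = 1e-6)
  expect_equal(kx_first[2], 49 * dk, tolerance = 1e-6)   # reversed line
  for (m in k) {
    expect_equal(sort(m[, 1]), ((0:99) - 50) * dk, tolerance = 1e-6)
    expect_equal(max(abs(m[, 1])), 100 / (2 * 0.23), tolerance = 1e-6)
  }
  # TE: RF center to the center sample of the center line
  st <- block_starts(sq)
  rfb <- which(vapply(sq$blocks, function(b) !is.null(b$rf), TRUE))[1]
  t_rf <- st[rfb] + sq$blocks[[rfb]]$duration / 2
  adcb <- which(vapply(sq$blocks, function(b) !is.null(b$adc), TRUE))[51]
  t_c <- st[adcb] + adc_sample_times(sq$blocks[[adcb]]$adc)[51]
  expect_equal(t_c - t_rf, 100e-3, tolerance = 1e-6)
  expect_error(epi_sequence(0.23, 100, te = 5e-3, scanner = sc), "te too short")
})

test_that("spin-echo EPI places the refocusing pulse at te/2", {
  sc <- scanner()
  sq <- epi_sequence(0.23, 8, te = 20e-3, variant = "se", scanner = sc)
  rfs <- which(vapply(sq$blocks, function(b) !is.null(b$rf), TRUE))
  expect_length(rfs, 2)
  expect_true(sq$blocks[[rfs[2]]]$refocus)
  st <- block_starts(sq)
  c90 <- st[rfs[1]] + sq$blocks[[rfs[1]]]$duration / 2
  c180 <- st[rfs[2]] + sq$blocks[[rfs[2]]]$duration / 2
  expect_equal(c180 - c90, 10e-3, tolerance = 1e-9)
  validate_sequence(sq, sc)
})

test_that("spiral reaches k_max within limits and rotates interleaves", {
  sc <- scanner()
  sq <- spiral_sequence(0.23, 100, te = 1e-4, interleaves = 1, scanner = sc)
  expect_silent(validate_sequence(sq, sc))
  k <- k_trajectory(sq, sc$gamma)
  kend <- k[[1]][nrow(k[[1]]), 1:2]
  expect_lt(abs(sqrt(sum(kend^2)) - 217.4) / 217.4, 0.02)
  # ADC starts te after the RF center
  st <- block_starts(sq)
  rfb <- which(vapply(sq$blocks, function(b) !is.null(b$rf), TRUE))[1]
  adcb <- which(vapply(sq$blocks, function(b) !is.null(b$adc), TRUE))[1]
  t0 <- st[adcb] + sq$blocks[[adcb]]$adc$delay
  expect_equal(t0 - (st[rfb] + sq$blocks[[rfb]]$duration / 2), 1e-4,
               tolerance = 1e-9)
  # 8 interleaves: trajectories are rotations of one another
  sq8 <- spiral_sequence(0.23, 64, te = 1e-4, interleaves = 8, scanner = sc)
  k8 <- k_trajectory(sq8, sc$gamma)
  expect_length(k8, 8)
  th <- 2 * pi / 8
  rot <- k8[[1]][, 1:2] %*% matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2)
  expect_equal(unname(rot), unname(k8[[2]][, 1:2]), tolerance = 1e-6)
})

test_that("fingerprinting schedules stay in the stated ranges", {
  sch <- mrf_schedule(158, spoke_mode = "tiny_golden", seed = 9)
  expect_length(sch$flip_angles, 158)
  expect_true(all(sch$flip_angles >= 0 & sch$flip_angles <= 80 * pi / 180 + 1e-12))
  expect_true(all(sch$TRs >= 14.5e-3 & sch$TRs <= 18e-3))
  expect_equal(sch$TE, 5e-3)
  expect_equal(sch$TI, 50e-3)
  expect_equal(sch$spoke_angles[2] - sch$spoke_angles[1],
               pi / ((1 + sqrt(5)) / 2 + 6), tolerance = 1e-12)
  expect_equal(sch$spoke_angles[2], 0.41238, tolerance = 1e-4)
  schu <- mrf_schedule(158, spoke_mode = "uniform", seed = 9)
  expect_equal(schu$spoke_angles[2], pi / 158, tolerance = 1e-12)
  expect_true(all(schu$spoke_angles >= 0 & schu$spoke_angles < pi))
  # deterministic given seed
  expect_identical(mrf_schedule(50, seed = 3)$flip_angles,
                   mrf_schedule(50, seed = 3)$flip_angles)
  # mixed pattern switches to the noisy sinusoid after TR 500
  schm <- mrf_schedule(600, seed = 1)
  expect_true(all(schm$flip_angles <= 80 * pi / 180 + 1e-12))
})

test_that("radial bSSFP TRs are balanced with alternating phase", {
  sc <- scanner()
  sch <- mrf_schedule(10, seed = 2)
  sq <- mrf_bssfp_sequence(sch, scanner = sc)
  expect_silent(validate_sequence(sq, sc))
  # net gradient area over the whole train is zero on both axes
  for (ax in c("gx", "gy")) {
    tot <- sum(vapply(sq$blocks, function(b)
      if (is.null(b[[ax]])) 0 else grad_area(b[[ax]]), 0))
    expect_lt(abs(tot), 1e-15)
  }
  # per-TR balance: k returns to zero at every spoke center sample +- kmax
  # (each spoke passes through k = 0 at its center sample)
  k <- k_trajectory(sq, sc$gamma)
  for (s in seq_along(k))
    expect_lt(sqrt(sum(k[[s]][51, 1:2]^2)), 1e-6)
  # consecutive excitation phases differ by pi
  phs <- vapply(Filter(function(b) !is.null(b$rf), sq$blocks)[-1],
                function(b) b$rf$phase_offset, 0)
  expect_true(all(abs(diff(phs)) == pi))
  # flip angles follow the schedule
  amps <- vapply(Filter(function(b) !is.null(b$rf), sq$blocks)[-1],
                 function(b) Mod(b$rf$amplitude[1]), 0)
  expect_equal(amps * sc$gamma * 5e-4, sch$flip_angles, tolerance = 1e-12)
})
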