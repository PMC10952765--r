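test_that("Cartesian EPI recon inverts delta and point inputs", {
  n <- 8
  # delta at k-space center -> constant-magnitude image
  K <- matrix(0 + 0i, n, n); K[n / 2 + 1, n / 2 + 1] <- 1
  rd <- raw_data(lapply(seq_len(n), function(m) {
    d <- K[m, ]
    if (m %% 2 == 0) d <- rev(d)   # store as acquired (serpentine)
    list(t = seq_len(n) * 1e-5, data = d, traj = NULL)
  }), header = list(matrix_size = c(n, n)))
  im <- recon_cartesian_epi(rd)
  expect_lt(diff(range(Mod(im))), 1e-12)
  # simulated single spin at the origin peaks at the center pixel
  sc <- scanner()
  ph <- phantom(x = 0, y = 0, M0 = 1, T1 = Inf, T2 = Inf)
  im2 <- Mod(recon_cartesian_epi(simulate_mri(ph, small_epi(sc = sc), sc)))
  pk <- which(im2 == max(im2), arr.ind = TRUE)
  expect_equal(unname(pk), matrix(c(5, 5), 1))   # n/2 + 1 with n = 8
})

test_that("column-phantom EPI concentrates energy at x = 0", {
  sc <- scanner()
  ph <- column_phantom(2e-2)
  im <- Mod(recon_cartesian_epi(simulate_mri(ph, small_epi(sc = sc), sc)))
  col_energy <- colSums(im^2)
  expect_equal(which.max(col_energy), 5L)     # x = 0 column
  expect_gt(col_energy[5] / sum(col_energy), 0.9)
})

test_that("adjoint recon matches the inverse FFT on a full raster", {
  sc <- scanner()
  ph <- phantom(x = c(0, 0.03), y = c(0.02, -0.04), M0 = c(1, 0.7),
                T1 = Inf, T2 = Inf)
  rd <- simulate_mri(ph, small_epi(sc = sc), sc)
  i1 <- recon_cartesian_epi(rd)
  i2 <- recon_adjoint(rd, 8, 0.23, dcf = "uniform")
  expect_lt(max(Mod(i1 - i2)), 1e-8)
  # single k = 0 sample -> constant image
  rd0 <- raw_data(list(list(t = 0, data = 1 + 0i,
                            traj = matrix(0, 1, 3))), header = list())
  im0 <- recon_adjoint(rd0, 8, 0.23)
  expect_lt(diff(range(Mod(im0))), 1e-12)
  expect_error(recon_adjoint(raw_data(list(list(t = 0, data = 1 + 0i,
                                                traj = NULL)),
                                      header = list()), 8, 0.23),
               "trajectory")
})

test_that("radial spokes of a centered disc reconstruct symmetrically", {
  # analytic radial samples of a centered disc (Airy pattern profile): the
  # adjoint image magnitude must be symmetric under point reflection
  n <- 32; fov <- 0.23; a <- 0.05
  kmax <- n / (2 * fov)
  nsp <- 24
  disc_ft <- function(kr) ifelse(kr == 0, pi * a^2,
                                 a * besselJ(2 * pi * a * kr, 1) / kr)
  readouts <- lapply(seq_len(nsp), function(j) {
    th <- (j - 1) * pi / nsp
    kr <- ((0:(n - 1)) - n / 2 + 0.5) / (n / 2) * kmax
    traj <- cbind(kr * cos(th), kr * sin(th), 0)
    list(t = (0:(n - 1)) * 1e-5, data = complex(real = disc_ft(abs(kr))),
         traj = traj)
  })
  im <- Mod(recon_adjoint(raw_data(readouts, list()), n, fov, dcf = "ramp"))
  core <- im[2:n, 2:n]   # pixels with a mirror partner on the even grid
  expect_lt(max(abs(core - core[(n - 1):1, (n - 1):1])) / max(im), 1e-10)
  # roughly disc-shaped: center bright, corners dark
  expect_gt(im[n / 2 + 1, n / 2 + 1], 3 * im[2, 2])
})

test_that("dictionary construction covers the printed grids with unit atoms", {
  sch <- mrf_schedule(40, seed = 8)
  dict <- build_dictionary(schedule = sch)
  expect_equal(length(unique(dict$entries$T1)), 221)
  expect_equal(length(unique(dict$entries$T2)), 78)
  expect_equal(nrow(dict$entries), 221 * 78)
  expect_equal(sqrt(rowSums(Mod(dict$fingerprints)^2)),
               rep(1, nrow(dict$entries)), tolerance = 1e-12)
  # optional physical filter
  d2 <- build_dictionary(schedule = sch, exclude_t2_gt_t1 = TRUE)
  expect_true(all(d2$entries$T2 <= d2$entries$T1))
  expect_lt(nrow(d2$entries), nrow(dict$entries))
  # relaxation-free isochromat under constant flips and no inversion: the
  # alternating-phase pulse pair composes to the identity, so the
  # fingerprint has no transient - it is exactly 2-periodic from the start
  sch2 <- mrf_schedule(20, seed = 8)
  sch2$flip_angles <- rep(pi / 2, 20)
  fp <- fingerprint_signals(Inf, Inf, sch2, inversion = FALSE)
  expect_lt(diff(range(Mod(fp[1, seq(1, 20, by = 2)]))), 1e-9)
  expect_lt(diff(range(Mod(fp[1, seq(2, 20, by = 2)]))), 1e-9)
})

test_that("matching recovers atoms up to phase and scale", {
  sch <- mrf_schedule(60, seed = 12)
  dict <- build_dictionary(t1_grid = seq(0.3, 2.5, by = 0.1),
                           t2_grid = seq(0.04, 0.35, by = 0.02),
                           schedule = sch)
  i <- c(4, 40, 100)
  sig <- dict$fingerprints[i, , drop = FALSE]
  m <- match_fingerprints(sig, dict, mask_threshold = 0)
  expect_equal(m$index, i)
  # complex scale invariance
  m2 <- match_fingerprints(sig * (0.3 - 1.7i), dict, mask_threshold = 0)
  expect_equal(m2$index, i)
  expect_equal(m2$T1, dict$entries$T1[i])
  # simulated off-dictionary-pipeline pixels with on-grid (T1, T2)
  t1 <- c(0.8, 1.5); t2 <- c(0.1, 0.26)
  sig3 <- fingerprint_signals(t1, t2, sch, M0 = c(2, 0.5))
  m3 <- match_fingerprints(sig3, dict, mask_threshold = 0)
  expect_equal(m3$T1, t1)
  expect_equal(m3$T2, t2)
  # masking drops low-signal pixels
  sig4 <- rbind(sig3, 1e-6 * sig3[1, , drop = FALSE])
  m4 <- match_fingerprints(sig4, dict, mask_threshold = 0.05)
  expect_true(is.na(m4$T1[3]))
  expect_equal(m4$T1[1:2], t1)
})

test_that("the normalized mean absolute difference behaves as a metric", {
  expect_equal(signal_mad(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(signal_mad(c(0, 1), c(1, 1)), 50)
  x <- complex(real = rnorm(10), imaginary = rnorm(10))
  y <- complex(real = rnorm(10), imaginary = rnorm(10))
  expect_equal(signal_mad(3.7 * x, 3.7 * y), signal_mad(x, y),
               tolerance = 1e-12)
  expect_error(signal_mad(1:3, 1:2), "lengths")
  expect_error(signal_mad(c(1, 2), c(0, 0)), "zero")
})
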