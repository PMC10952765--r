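test_that("field spinors reproduce the canonical rotations", {
  # zero field -> identity
  s0 <- spinor_from_field(0 + 0i, 0, 1e-3)
  expect_equal(s0$alpha, complex(real = 1))
  expect_equal(s0$beta, complex(real = 0))
  # on-resonance 90-degree pulse about x
  sc <- scanner()
  dt <- 1e-4
  b1 <- (pi / 2) / (sc$gamma * dt)
  s <- spinor_from_field(complex(real = b1), 0, dt, sc$gamma)
  expect_equal(s$alpha, complex(real = cos(pi / 4)), tolerance = 1e-12)
  expect_equal(s$beta, complex(imaginary = sin(pi / 4)), tolerance = 1e-12)
  # pure Bz rotation: z-axis spinor equals the complex-exponential phase
  bz <- 2e-6
  sz <- spinor_from_field(0 + 0i, bz, dt, sc$gamma)
  expect_equal(sz$beta, complex(real = 0))
  expect_equal(sz$alpha, exp(1i * sc$gamma * bz * dt / 2), tolerance = 1e-12)
  m <- mag(complex(real = 1), 0)
  mr <- apply_spinor(sz, m)
  expect_equal(mr$xy, exp(-1i * sc$gamma * bz * dt), tolerance = 1e-12)
})

test_that("spinor application agrees with the rotation-matrix oracle", {
  set.seed(101)
  worst <- 0
  for (i in 1:200) {
    B1 <- complex(real = rnorm(1, 0, 2e-5), imaginary = rnorm(1, 0, 2e-5))
    Bz <- rnorm(1, 0, 2e-5)
    dt <- runif(1, 0, 2e-4)
    xy <- complex(real = rnorm(1), imaginary = rnorm(1))
    z <- rnorm(1)
    s <- spinor_from_field(B1, Bz, dt)
    got <- apply_spinor(s, mag(xy, z))
    want <- rotate_by_matrix(xy, z, B1, Bz, dt)
    worst <- max(worst, Mod(got$xy - want$xy), abs(got$z - want$z))
  }
  expect_lt(worst, 1e-12)
})

test_that("spinor rotations preserve the magnetization norm", {
  set.seed(7)
  xy <- complex(real = rnorm(20), imaginary = rnorm(20))
  z <- rnorm(20)
  m <- mag(xy, z)
  s <- spinor_from_field(complex(real = rnorm(20, 0, 1e-5),
                                 imaginary = rnorm(20, 0, 1e-5)),
                         rnorm(20, 0, 1e-5), 1e-4)
  m2 <- apply_spinor(s, m)
  expect_equal(Mod(m2$xy)^2 + m2$z^2, Mod(xy)^2 + z^2, tolerance = 1e-12)
})

test_that("relaxation follows the closed-form exponentials", {
  m <- mag(complex(real = 1), 0)
  expect_equal(relax(m, 0, 0.1, 0.05, 1), m)                    # dt = 0
  r <- relax(m, 0.1, 0.1, 0.05, 1)                              # dt = T1
  expect_equal(r$z, 1 - exp(-1), tolerance = 1e-12)
  r2 <- relax(m, 0.05 * log(2), 0.1, 0.05, 1)                   # dt = T2 ln2
  expect_equal(Mod(r2$xy), 0.5, tolerance = 1e-12)
  expect_error(relax(m, -1, 0.1, 0.05, 1), ">= 0")
})

test_that("excitation steps compose like a single constant-field rotation", {
  sc <- scanner()
  ph <- phantom(x = 0, M0 = 1, T1 = Inf, T2 = Inf)
  dur <- 5e-4
  b1 <- (pi / 2) / (sc$gamma * dur)
  m1 <- equilibrium_mag(ph)
  for (i in 1:5)
    m1 <- excitation_step(m1, ph, complex(real = b1), c(0, 0, 0), dur / 5,
                          gamma = sc$gamma)
  m2 <- excitation_step(equilibrium_mag(ph), ph, complex(real = b1),
                        c(0, 0, 0), dur, gamma = sc$gamma)
  expect_equal(m1$xy, m2$xy, tolerance = 1e-12)
  expect_equal(m1$z, m2$z, tolerance = 1e-12)
  expect_equal(Mod(m2$xy), 1, tolerance = 1e-12)   # full excitation
  expect_equal(m2$z, 0, tolerance = 1e-12)
})

test_that("gradients and off-resonance tilt the rotation axis during RF", {
  sc <- scanner()
  ph <- phantom(x = 5e-3, M0 = 1, T1 = Inf, T2 = Inf, dw = 300)
  b1 <- complex(real = 1e-5)
  G <- c(8e-3, 0, 0)
  dt <- 1e-4
  got <- excitation_step(equilibrium_mag(ph), ph, b1, G, dt, gamma = sc$gamma)
  bz <- G[1] * 5e-3 + 300 / sc$gamma
  want <- rotate_by_matrix(0 + 0i, 1, b1, bz, dt, sc$gamma)
  expect_equal(got$xy, want$xy, tolerance = 1e-12)
  expect_equal(got$z, want$z, tolerance = 1e-12)
})

test_that("free precession accumulates the exact trapezoidal phase", {
  sc <- scanner()
  mk_nodes <- function(tt, gx = 0) list(t = tt, Gx = rep(gx, length(tt)),
                                        Gy = numeric(length(tt)),
                                        Gz = numeric(length(tt)),
                                        B1 = complex(real = numeric(length(tt))))
  m0 <- mag(complex(real = 1), 0)
  # constant gradient, off-center spin
  ph <- phantom(x = 1e-3, M0 = 1, T1 = Inf, T2 = Inf)
  r <- precession_block(m0, ph, mk_nodes(c(0, 1e-3), gx = 0.01),
                        gamma = sc$gamma)
  expect_equal(Arg(r$m$xy), -sc$gamma * 0.01 * 1e-3 * 1e-3, tolerance = 1e-10)
  expect_equal(Arg(r$m$xy), -2.67538, tolerance = 1e-5)
  # pure off-resonance: 200 rad/s for 10 ms -> -2 rad
  ph2 <- phantom(x = 0, M0 = 1, T1 = Inf, T2 = Inf, dw = 200)
  r2 <- precession_block(m0, ph2, mk_nodes(c(0, 10e-3)), gamma = sc$gamma)
  expect_equal(Arg(r2$m$xy), -2, tolerance = 1e-10)
  # zero field: pure T2 decay, no phase
  ph3 <- phantom(x = 0, M0 = 1, T1 = Inf, T2 = 0.02)
  r3 <- precession_block(m0, ph3, mk_nodes(c(0, 5e-3, 10e-3)),
                         gamma = sc$gamma)
  expect_equal(Mod(r3$m$xy), exp(-10e-3 / 0.02), tolerance = 1e-12)
  expect_equal(Arg(r3$m$xy), 0)
  # nonzero B1 in a precession span is a regime violation
  bad <- mk_nodes(c(0, 1e-3))
  bad$B1[1] <- 1e-6 + 0i
  expect_error(precession_block(m0, ph3, bad), "nonzero B1")
})

test_that("excitation stepping with zero B1 matches the precession kernel", {
  sc <- scanner()
  ph <- phantom(x = c(2e-3, -4e-3), M0 = c(1, 0.8), T1 = 0.5, T2 = 0.05,
                dw = c(100, -50))
  m0 <- mag(complex(real = c(0.6, 0.3), imaginary = c(0.1, -0.2)),
            c(0.5, 0.9))
  tt <- seq(0, 2e-3, by = 1e-4)
  gx <- 0.005 * sin(seq(0, pi, length.out = length(tt)))  # smooth waveform
  nodes <- list(t = tt, Gx = gx, Gy = numeric(length(tt)),
                Gz = numeric(length(tt)),
                B1 = complex(real = numeric(length(tt))))
  mp <- precession_block(m0, ph, nodes, gamma = sc$gamma)$m
  me <- m0
  for (k in seq_len(length(tt) - 1))
    me <- excitation_step(me, ph, 0 + 0i,
                          c((gx[k] + gx[k + 1]) / 2, 0, 0),
                          tt[k + 1] - tt[k], gamma = sc$gamma)
  expect_equal(me$xy, mp$xy, tolerance = 1e-10)
  expect_equal(me$z, mp$z, tolerance = 1e-10)
})
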