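test_that("critical times sample vertices, RF raster and ADC exactly", {
  # trapezoid alone: 4 vertex times + block end, no interior nodes
  g <- grad_event(c(0, 1e-3, 3e-3, 4e-3), c(0, 0.01, 0.01, 0), "x")
  sq <- mr_sequence(list(seq_block(gx = g, duration = 5e-3)))
  ct <- critical_times(sq, sim_config())
  expect_equal(ct, c(0, 1e-3, 3e-3, 4e-3, 5e-3))

  # hard pulse of 0.5 ms at dt_rf = 0.1 ms -> 6 equally spaced nodes
  sq2 <- mr_sequence(list(hard_pulse(pi / 2, 5e-4)))
  ct2 <- critical_times(sq2, sim_config(dt_rf = 1e-4))
  expect_equal(ct2, seq(0, 5e-4, by = 1e-4))

  # every ADC sample time appears exactly once
  sq3 <- mr_sequence(list(seq_block(adc = adc_event(100, 1e-5))))
  ct3 <- critical_times(sq3, sim_config())
  st <- 1e-5 * ((1:100) - 0.5)
  expect_true(all(st %in% ct3))
  d3 <- discretize(sq3, sim_config())
  expect_equal(sum(d3$adc), 100)

  # event beyond block duration is a validation error
  bad <- mr_sequence(list(seq_block(adc = adc_event(10, 1e-3))))
  bad$blocks[[1]]$duration <- 1e-3
  expect_error(critical_times(bad, sim_config()), "beyond")
})

test_that("node set is monotone under added ADC events", {
  g <- grad_event(c(0, 1e-3, 3e-3, 4e-3), c(0, 0.01, 0.01, 0), "x")
  sq_a <- mr_sequence(list(seq_block(gx = g, duration = 5e-3)))
  sq_b <- mr_sequence(list(seq_block(gx = g, adc = adc_event(7, 3e-4),
                                     duration = 5e-3)))
  ct_a <- critical_times(sq_a, sim_config())
  ct_b <- critical_times(sq_b, sim_config())
  expect_true(all(ct_a %in% ct_b))
  expect_gt(length(ct_b), length(ct_a))
})

test_that("discretize samples fields by interpolation rules", {
  sc <- scanner()
  # constant gradient -> same value at every node
  g <- grad_event(c(0, 2e-3), c(0.01, 0.01), "x")
  sq <- mr_sequence(list(seq_block(gx = g, adc = adc_event(5, 4e-4))))
  d <- discretize(sq, sim_config(), sc)
  expect_true(all(abs(d$Gx - 0.01) < 1e-15))
  # linear ramp: node at 0.5 ms reads 5 mT/m
  g2 <- grad_event(c(0, 1e-3), c(0, 0.01), "x")
  sq2 <- mr_sequence(list(seq_block(gx = g2, adc = adc_event(1, 1e-3))))
  d2 <- discretize(sq2, sim_config(), sc)
  expect_equal(d2$Gx[d2$adc], 0.005)
  # RF carries the amplitude inside the pulse, zero outside
  sq3 <- mr_sequence(list(hard_pulse(pi / 2, 5e-4, gamma = sc$gamma),
                          delay_block(5e-4)))
  d3 <- discretize(sq3, sim_config(dt_rf = 1e-4), sc)
  b1 <- (pi / 2) / (sc$gamma * 5e-4)
  inside <- d3$t < 5e-4 - 1e-12
  expect_true(all(abs(d3$B1[inside] - b1) < 1e-18))
  expect_true(all(d3$B1[!inside] == 0))
  # gradient over Gmax is rejected
  gbig <- grad_event(c(0, 1e-3), c(0.2, 0.2), "x")
  sqb <- mr_sequence(list(seq_block(gx = gbig)))
  expect_error(discretize(sqb, sim_config(), sc), "Gmax")
})

test_that("partition covers all steps once and tags regimes", {
  # RF-free sequence: n_blocks precession blocks
  sq <- mr_sequence(list(seq_block(gx = grad_event(seq(0, 1e-2, by = 1e-3),
                                                   rep(c(0.01, 0), 6)[1:11],
                                                   "x"))))
  d <- discretize(sq, sim_config())
  bl <- partition_blocks(d, sim_config(n_blocks = 4))
  expect_length(bl, 4)
  expect_true(all(vapply(bl, `[[`, "", "regime") == "precession"))
  steps <- unlist(lapply(bl, function(b) b$from:b$to))
  expect_identical(sort(steps), seq_along(d$dt))

  # block containing the RF is tagged excitation and the pulse is not split
  sq2 <- mr_sequence(list(delay_block(2e-3), hard_pulse(pi / 2, 5e-4),
                          delay_block(2e-3)))
  d2 <- discretize(sq2, sim_config(dt_rf = 1e-4))
  for (nb in c(1, 2, 3)) {
    bl2 <- partition_blocks(d2, sim_config(n_blocks = nb))
    rf_steps <- which(Mod(d2$B1[-length(d2$B1)]) > 0)
    holder <- vapply(bl2, function(b) any(rf_steps %in% b$from:b$to), TRUE)
    expect_true(all(vapply(bl2[holder], `[[`, "", "regime") == "excitation"))
    expect_equal(sum(vapply(bl2, function(b)
      length(intersect(rf_steps, b$from:b$to)), 0L)), length(rf_steps))
    # the whole RF run sits inside a single block
    expect_equal(sum(holder), 1L)
    steps2 <- unlist(lapply(bl2, function(b) b$from:b$to))
    expect_identical(sort(steps2), seq_along(d2$dt))
  }
  # n_blocks = 1: single block, excitation because the sequence has RF
  bl1 <- partition_blocks(d2, sim_config(n_blocks = 1))
  expect_length(bl1, 1)
  expect_equal(bl1[[1]]$regime, "excitation")
  # clamp with warning
  expect_warning(partition_blocks(d2, sim_config(n_blocks = 10 * length(d2$t))),
                 "clamp")
})

test_that("vertex-only trapezoidal phase equals any node refinement", {
  # free precession under a trapezoid; compare the sequence-aware node set
  # against a 10x refined node set through the actual kernel
  sc <- scanner()
  ph <- phantom(x = c(0.01, -0.02, 0.035), M0 = 1, T1 = Inf, T2 = Inf,
                dw = c(0, 50, -120))
  m0 <- mag(complex(real = rep(1, 3)), rep(0, 3))
  g <- grad_event(c(0, 1e-3, 3e-3, 4e-3), c(0, 0.02, 0.02, 0), "x")
  tt <- c(0, 1e-3, 3e-3, 4e-3, 5e-3)
  nodes <- list(t = tt, Gx = c(0, 0.02, 0.02, 0, 0), Gy = numeric(5),
                Gz = numeric(5), B1 = complex(real = numeric(5)))
  fine_t <- sort(unique(c(tt, seq(0, 5e-3, length.out = 401))))
  nodes_f <- list(t = fine_t,
                  Gx = grad_field_at(g, fine_t), Gy = numeric(length(fine_t)),
                  Gz = numeric(length(fine_t)),
                  B1 = complex(real = numeric(length(fine_t))))
  r1 <- precession_block(m0, ph, nodes, gamma = sc$gamma)
  r2 <- precession_block(m0, ph, nodes_f, gamma = sc$gamma)
  expect_equal(r1$m$xy, r2$m$xy, tolerance = 1e-12)
})
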