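#' Hard RF pulse block
#'
#' A rectangular pulse whose constant amplitude satisfies
#' `flip = gamma * B1 * duration`.
#'
#' @param flip Flip angle (rad).
#' @param duration Pulse duration (s, > 0).
#' @param phase Carrier phase (rad).
#' @param gamma Gyromagnetic ratio (rad/s/T).
#' @param b1_max Optional peak-B1 limit (T); exceeded -> error.
#' @param refocus Mark as a refocusing pulse (k-trajectory metadata).
#' @return A [seq_block()] containing only the RF event.
#' @export
hard_pulse <- function(flip, duration = 5e-4, phase = 0,
                       gamma = 2 * pi * 42.58e6, b1_max = NULL,
                       refocus = FALSE) {
  if (duration <= 0) stop("duration must be > 0")
  amp <- flip / (gamma * duration)
  if (!is.null(b1_max) && abs(amp) > b1_max)
    stop(sprintf("hard pulse B1 = %.3g T exceeds limit %.3g T", amp, b1_max))
  seq_block(rf = rf_event(complex(real = amp), raster = duration,
                          phase_offset = phase),
            duration = duration, refocus = refocus)
}

# trapezoid (or triangle) gradient achieving an exact area within limits;
# rise/flat times are raster-aligned, the amplitude absorbs the rounding
design_trap <- function(area, scanner, axis, safety = 0.9) {
  if (area == 0) return(NULL)
  A <- abs(area); s <- sign(area)
  gm <- safety * scanner$Gmax; sm <- safety * scanner$Smax
  rt <- scanner$raster_time
  amp0 <- min(gm, sqrt(A * sm))
  rise <- ceiling(amp0 / sm / rt) * rt
  flat <- max(0, A / amp0 - rise)
  flat <- ceiling(flat / rt) * rt
  amp <- A / (rise + flat)
  if (flat == 0) {
    grad_event(c(0, rise, 2 * rise), s * c(0, amp, 0), axis)
  } else {
    grad_event(c(0, rise, rise + flat, 2 * rise + flat),
               s * c(0, amp, amp, 0), axis)
  }
}

grad_dur <- function(g) if (is.null(g)) 0 else max(g$times)

#' Single-shot EPI sequence
#'
#' Hard 90-degree excitation, pre-phasers to the k-space corner, then `n`
#' serpentine readout lines of `n` samples each with alternating readout
#' polarity and phase-encode blips (played on the falling ramp of each
#' line).  Sampling is on flat-tops only; sample `j` of a line lands on
#' `kx = (j - n/2) / fov` and line `m` on `ky = (m - n/2) / fov`, so the
#' k-space extent is `n / (2 fov)` per axis.  Timing places the center
#' sample of the center line (`m = n/2`) exactly `te` after the excitation
#' center.  The spin-echo variant inserts a hard 180 at `te/2` (simulated
#' as a real pulse; flagged for k-trajectory negation) and plays the
#' pre-phasers after it.
#'
#' @param fov Field of view (m).
#' @param n Matrix size (even).
#' @param te Echo time (s).
#' @param variant `"gre"` or `"se"`.
#' @param scanner A [scanner()].
#' @param dwell ADC dwell time (s).
#' @param ramp Readout ramp time (s).
#' @param rf_duration Hard-pulse duration (s).
#' @return An [mr_sequence()].
#' @export
epi_sequence <- function(fov, n, te, variant = c("gre", "se"),
                         scanner = default_scanner(), dwell = 4e-6, ramp = 1e-4,
                         rf_duration = 5e-4) {
  variant <- match.arg(variant)
  if (n %% 2 != 0) stop("n must be even")
  g2p <- scanner$gamma / (2 * pi)
  dk <- 1 / fov
  Ga <- dk / (g2p * dwell)
  if (Ga > scanner$Gmax)
    stop("readout gradient exceeds Gmax; increase dwell or fov")
  if (Ga / ramp > scanner$Smax)
    stop("readout ramp exceeds Smax; increase ramp")
  flat <- n * dwell
  blip_area <- dk / g2p
  Gb <- blip_area / (ramp / 2)
  line_dur <- 2 * ramp + flat
  line_block <- function(m) {
    sgn <- if (m %% 2 == 0) 1 else -1
    gx <- grad_event(c(0, ramp, ramp + flat, line_dur),
                     sgn * c(0, Ga, Ga, 0), "x")
    gy <- if (m < n - 1)
      grad_event(c(ramp + flat, ramp + flat + ramp / 2, line_dur),
                 c(0, Gb, 0), "y") else NULL
    seq_block(gx = gx, gy = gy,
              adc = adc_event(n, dwell, delay = ramp),
              duration = line_dur)
  }
  A_prex <- -((n + 1) / 2) * dk / g2p - Ga * ramp / 2
  A_prey <- -(n / 2) * dk / g2p
  pre_x <- design_trap(A_prex, scanner, "x")
  pre_y <- design_trap(A_prey, scanner, "y")
  pre_dur <- max(grad_dur(pre_x), grad_dur(pre_y))
  pre_block <- seq_block(gx = pre_x, gy = pre_y, duration = pre_dur)
  # time from start of the readout train to the k-space-center sample
  t_train_center <- (n / 2) * line_dur + ramp + (n / 2 + 0.5) * dwell
  blocks <- list(hard_pulse(pi / 2, rf_duration, gamma = scanner$gamma))
  if (variant == "gre") {
    gap <- te - rf_duration / 2 - pre_dur - t_train_center
    if (gap < 0) stop("te too short for the EPI readout train")
    if (gap > 1e-9) blocks <- c(blocks, list(delay_block(gap)))
    blocks <- c(blocks, list(pre_block))
  } else {
    gap_a <- te / 2 - rf_duration  # 90 and 180 half-durations
    if (gap_a < 0) stop("te too short for the refocusing pulse")
    blocks <- c(blocks,
                if (gap_a > 1e-9) list(delay_block(gap_a)),
                list(hard_pulse(pi, rf_duration, gamma = scanner$gamma,
                                refocus = TRUE)))
    gap_b <- te / 2 - rf_duration / 2 - pre_dur - t_train_center
    if (gap_b < 0) stop("te too short for the EPI readout train")
    if (gap_b > 1e-9) blocks <- c(blocks, list(delay_block(gap_b)))
    blocks <- c(blocks, list(pre_block))
  }
  blocks <- c(blocks, lapply(0:(n - 1), line_block))
  sq <- mr_sequence(blocks, name = if (variant == "gre") "epi" else "se-epi",
                    fov = c(fov, fov), matrix_size = c(n, n))
  validate_sequence(sq, scanner)
  sq
}

#' Single-shot (or interleaved) spiral sequence
#'
#' Per interleave: a short hard 90, a delay so sampling starts `te` after
#' the pulse center, then an outward Archimedean-type spiral
#' `k(tau) = kmax * tau^2 * exp(1i * (2 pi N tau + theta0))` reaching
#' `kmax = n / (2 fov)`, with the gradient waveform sampled onto a
#' piecewise-linear raster and the duration chosen to respect `Gmax` and
#' `Smax`.  The ADC is on throughout the spiral.  Interleaves are rotated
#' by `2 pi / interleaves`.
#'
#' @param fov Field of view (m).
#' @param n Matrix size.
#' @param te Echo time (s).
#' @param interleaves Number of rotated shots.
#' @param scanner A [scanner()].
#' @param raster Gradient/ADC raster of the spiral (s).
#' @param rf_duration Hard-pulse duration (s).
#' @return An [mr_sequence()].
#' @export
spiral_sequence <- function(fov, n, te = 1e-4, interleaves = 1,
                            scanner = default_scanner(), raster = 1e-5,
                            rf_duration = 1e-4) {
  g2p <- scanner$gamma / (2 * pi)
  kmax <- n / (2 * fov)
  turns <- n / (2 * interleaves)
  w <- 2 * pi * turns
  # G(tau)/T and dG/dtau/T^2 on a fine grid to pick the duration T
  tau <- seq(0, 1, length.out = 2001)
  dk <- kmax * (2 * tau + 1i * w * tau^2) * exp(1i * w * tau)  # dk/dtau
  gmag <- Mod(dk) / g2p                                        # |G| * T
  d2k <- kmax * (2 + 4i * w * tau - w^2 * tau^2) * exp(1i * w * tau)
  smag <- Mod(d2k) / g2p                                       # |slew| * T^2
  T_g <- max(gmag) / (0.9 * scanner$Gmax)
  T_s <- sqrt(max(smag) / (0.9 * scanner$Smax))
  Tsp <- ceiling(max(T_g, T_s) / raster) * raster
  nv <- round(Tsp / raster)
  shot <- function(theta0) {
    tv <- raster * (0:nv)
    tauv <- tv / Tsp
    kv <- kmax * tauv^2 * exp(1i * (w * tauv + theta0))
    Gv <- kmax * (2 * tauv + 1i * w * tauv^2) *
      exp(1i * (w * tauv + theta0)) / (g2p * Tsp)
    # taper to zero after the readout so the waveform never jumps
    tdown <- max(raster,
                 ceiling(Mod(Gv[nv + 1]) / (0.9 * scanner$Smax) / raster) *
                   raster)
    gx <- grad_event(c(tv, Tsp + tdown), c(Re(Gv), 0), "x")
    gy <- grad_event(c(tv, Tsp + tdown), c(Im(Gv), 0), "y")
    nsamp <- floor(Tsp / raster)
    sp <- seq_block(gx = gx, gy = gy,
                    adc = adc_event(nsamp, raster, delay = 0),
                    duration = Tsp + tdown)
    # rewind k to zero after the shot so interleaves start fresh
    rw_x <- design_trap(-grad_area(gx), scanner, "x")
    rw_y <- design_trap(-grad_area(gy), scanner, "y")
    rw <- seq_block(gx = rw_x, gy = rw_y,
                    duration = max(grad_dur(rw_x), grad_dur(rw_y)))
    gap <- te - rf_duration / 2
    if (gap < 0) stop("te shorter than half the RF pulse")
    c(list(hard_pulse(pi / 2, rf_duration, gamma = scanner$gamma)),
      if (gap > 1e-9) list(delay_block(gap)),
      list(sp, rw))
  }
  blocks <- do.call(c, lapply(0:(interleaves - 1),
                              function(i) shot(2 * pi * i / interleaves)))
  sq <- mr_sequence(blocks, name = "spiral", fov = c(fov, fov),
                    matrix_size = c(n, n))
  validate_sequence(sq, scanner)
  sq
}

#' Magnetic resonance fingerprinting schedule
#'
#' Per-TR flip angles, repetition times, spoke angles and the fixed TE/TI of
#' a radial bSSFP fingerprinting train.  Flip angles lie in `[0, 80]`
#' degrees: a smooth seeded gradient-noise ("perlin") pattern, a noisy
#' sinusoid, or the mixed pattern (gradient noise for the first 500 TRs,
#' noisy sinusoid afterwards).  TRs are uniform in `[14.5, 18.0]` ms,
#' TE = 5 ms, TI = 50 ms.  Spoke angles advance by `pi/n_tr` (uniform mode)
#' or by the tiny golden angle `pi/(phi + 6)`, modulo `pi`.
#'
#' @param n_tr Number of TRs (>= 1).
#' @param pattern `"paper_mix"`, `"perlin"` or `"sinusoid"`.
#' @param spoke_mode `"uniform"` or `"tiny_golden"`.
#' @param seed Integer seed; the schedule is deterministic given it.
#' @return An object of class `mrf_schedule` with fields `flip_angles`
#'   (rad), `TRs` (s), `TE`, `TI` (s), `spoke_angles` (rad).
#' @export
mrf_schedule <- function(n_tr, pattern = c("paper_mix", "perlin", "sinusoid"),
                         spoke_mode = c("uniform", "tiny_golden"), seed = 1) {
  pattern <- match.arg(pattern)
  spoke_mode <- match.arg(spoke_mode)
  if (n_tr < 1) stop("n_tr must be >= 1")
  set.seed(seed)
  flip_max <- 80 * pi / 180
  perlin <- function(n) {
    # 1-D gradient noise, 4 octaves; sample off-lattice (gradient noise
    # vanishes on lattice points)
    out <- numeric(n)
    x <- (seq_len(n) - 0.5) / n
    for (o in 0:3) {
      np <- 4 * 2^o
      gr <- stats::runif(np + 1, -1, 1)
      xi <- x * np
      i0 <- pmin(floor(xi), np - 1)
      f <- xi - i0
      sm <- f^3 * (f * (f * 6 - 15) + 10)
      v0 <- gr[i0 + 1] * f
      v1 <- gr[i0 + 2] * (f - 1)
      out <- out + (v0 + sm * (v1 - v0)) / 2^o
    }
    out
  }
  noisy_sin <- function(n) {
    k <- seq_len(n)
    base <- 0.5 + 0.5 * sin(2 * pi * k / 250)
    pmin(pmax(base + stats::rnorm(n, 0, 0.05), 0), 1)
  }
  norm01 <- function(p)
    if (max(p) - min(p) < 1e-12) rep(0.5, length(p))
    else (p - min(p)) / (max(p) - min(p))
  unit <- switch(pattern,
    perlin = norm01(perlin(n_tr)),
    sinusoid = noisy_sin(n_tr),
    paper_mix = {
      n1 <- min(500L, n_tr)
      p <- norm01(perlin(n1))
      if (n_tr > n1) c(p, noisy_sin(n_tr - n1)) else p
    })
  flips <- unit * flip_max
  TRs <- stats::runif(n_tr, 14.5e-3, 18.0e-3)
  dtheta <- switch(spoke_mode,
                   uniform = pi / n_tr,
                   tiny_golden = pi / ((1 + sqrt(5)) / 2 + 6))
  structure(list(flip_angles = flips, TRs = TRs, TE = 5e-3, TI = 50e-3,
                 spoke_angles = ((0:(n_tr - 1)) * dtheta) %% pi,
                 spoke_mode = spoke_mode, pattern = pattern, seed = seed),
            class = "mrf_schedule")
}

#' @export
print.mrf_schedule <- function(x, ...) {
  cat(sprintf(
    "<mrf_schedule> %d TRs (%s flips, %s spokes), TE = %g ms, TI = %g ms\n",
    length(x$TRs), x$pattern, x$spoke_mode, x$TE * 1e3, x$TI * 1e3))
  invisible(x)
}

#' Radial balanced-SSFP fingerprinting sequence
#'
#' A hard 180 inversion, a TI delay, then one balanced radial TR per
#' schedule entry: a hard pulse with the scheduled flip and alternating
#' 0/pi RF phase, a pre-phaser, a readout spoke at the scheduled angle whose
#' center sample crosses k = 0 exactly TE after the RF center, and a
#' rewinder that refunds all gradient area, so the net gradient moment of
#' every TR is zero on both axes.  The ADC phase follows the RF phase.
#'
#' @param schedule An [mrf_schedule()].
#' @param fov Field of view (m).
#' @param n Samples per spoke (matrix size).
#' @param scanner A [scanner()].
#' @param dwell ADC dwell time (s).
#' @param ramp Readout ramp time (s).
#' @param rf_duration Hard-pulse duration (s).
#' @return An [mr_sequence()].
#' @export
mrf_bssfp_sequence <- function(schedule, fov = 0.23, n = 100,
                               scanner = default_scanner(), dwell = 1e-5,
                               ramp = 1e-4, rf_duration = 5e-4) {
  g2p <- scanner$gamma / (2 * pi)
  dk <- 1 / fov
  Ga <- dk / (g2p * dwell)
  if (Ga > scanner$Gmax) stop("readout gradient exceeds Gmax")
  flat <- n * dwell
  read_dur <- 2 * ramp + flat
  A_pre <- -((n + 1) / 2) * dk / g2p - Ga * ramp / 2
  A_read <- Ga * (flat + ramp)
  A_rew <- -(A_pre + A_read)
  pre_shape <- design_trap(A_pre, scanner, "x")
  rew_shape <- design_trap(A_rew, scanner, "x")
  pre_dur <- grad_dur(pre_shape); rew_dur <- grad_dur(rew_shape)
  proj <- function(shape, fac, axis) {
    if (is.null(shape) || fac == 0) return(NULL)
    grad_event(shape$times, shape$amplitudes * fac, axis)
  }
  blocks <- list(hard_pulse(pi, rf_duration, gamma = scanner$gamma))
  ti_gap <- schedule$TI - rf_duration
  if (ti_gap < 0) stop("TI shorter than the RF pulses")
  if (ti_gap > 1e-9) blocks <- c(blocks, list(delay_block(ti_gap)))
  te_gap <- schedule$TE - rf_duration / 2 - pre_dur - ramp -
    (n / 2 + 0.5) * dwell
  if (te_gap < 0) stop("TE incompatible with the readout duration")
  for (k in seq_along(schedule$TRs)) {
    phase_k <- pi * ((k - 1) %% 2)
    th <- schedule$spoke_angles[k]
    cx <- cos(th); sy <- sin(th)
    rfb <- hard_pulse(schedule$flip_angles[k], rf_duration, phase = phase_k,
                      gamma = scanner$gamma)
    pre <- seq_block(gx = proj(pre_shape, cx, "x"),
                     gy = proj(pre_shape, sy, "y"), duration = pre_dur)
    read <- seq_block(
      gx = proj(grad_event(c(0, ramp, ramp + flat, read_dur),
                           c(0, Ga, Ga, 0), "x"), cx, "x"),
      gy = proj(grad_event(c(0, ramp, ramp + flat, read_dur),
                           c(0, Ga, Ga, 0), "y"), sy, "y"),
      adc = adc_event(n, dwell, delay = ramp, phase = phase_k),
      duration = read_dur)
    rew <- seq_block(gx = proj(rew_shape, cx, "x"),
                     gy = proj(rew_shape, sy, "y"), duration = rew_dur)
    tr_fill <- schedule$TRs[k] - rf_duration - te_gap - pre_dur - read_dur -
      rew_dur
    if (tr_fill < 0) stop("TR too short for the balanced readout")
    blocks <- c(blocks, list(rfb),
                if (te_gap > 1e-9) list(delay_block(te_gap)),
                list(pre, read, rew),
                if (tr_fill > 1e-9) list(delay_block(tr_fill)))
  }
  sq <- mr_sequence(blocks, name = "mrf-bssfp", fov = c(fov, fov),
                    matrix_size = c(n, n))
  validate_sequence(sq, scanner)
  sq
}
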