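# shared fixtures and small independent oracles used across test files

GAMMA_DEF <- 2 * pi * 42.58e6

# Rodrigues rotation matrix about unit axis (nx, ny, nz) by angle phi;
# independent oracle for the spinor algebra
rotation_matrix <- function(nx, ny, nz, phi) {
  cp <- cos(phi); sp <- sin(phi); om <- 1 - cp
  matrix(c(cp + nx * nx * om, nx * ny * om - nz * sp, nx * nz * om + ny * sp,
           ny * nx * om + nz * sp, cp + ny * ny * om, ny * nz * om - nx * sp,
           nz * nx * om - ny * sp, nz * ny * om + nx * sp, cp + nz * nz * om),
         3, 3, byrow = TRUE)
}

# rotate magnetization (Mxy complex, Mz) by the field (B1, Bz) over dt using
# the matrix oracle
rotate_by_matrix <- function(xy, z, B1, Bz, dt, gamma = GAMMA_DEF) {
  B <- sqrt(Mod(B1)^2 + Bz^2)
  if (B == 0) return(list(xy = xy, z = z))
  phi <- -gamma * B * dt
  R <- rotation_matrix(Re(B1) / B, Im(B1) / B, Bz / B, phi)
  v <- R %*% c(Re(xy), Im(xy), z)
  list(xy = complex(real = v[1], imaginary = v[2]), z = v[3])
}

sim_signal <- function(rd) unlist(lapply(rd$readouts, `[[`, "data"))

# small single-shot EPI shared by several files (cheap to build)
small_epi <- function(n = 8, te = 8e-3, variant = "gre", sc = scanner()) {
  epi_sequence(0.23, n, te = te, variant = variant, scanner = sc)
}

# fixture for convergence studies: linear-ramp RF envelope on a 1 us raster
ramped_rf_seq <- function(dur = 1e-3, sc = scanner()) {
  raster <- 1e-6
  nsamp <- round(dur / raster)
  amp <- (seq_len(nsamp) - 0.5) / nsamp * (pi / (sc$gamma * dur))
  mr_sequence(list(seq_block(rf = rf_event(complex(real = amp), raster),
                             duration = dur)))
}

# analytic pixel-coverage rendering of the concentric-circles M0 map
circles_coverage_map <- function(n = 100, fov = 0.23, R = 0.05, ss = 8) {
  off <- ((1:ss) - 0.5) / ss - 0.5
  dx <- fov / n
  ref <- matrix(0, n, n)
  for (q in 1:n) for (p in 1:n) {
    xc <- (q - 1 - n / 2) * dx; yc <- (p - 1 - n / 2) * dx
    gx <- xc + off * dx; gy <- yc + off * dx
    ref[p, q] <- mean(outer(gy^2, gx^2, `+`) < R^2)
  }
  ref
}
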