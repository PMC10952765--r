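#' Spinor of a constant effective field
#'
#' Builds the SU(2) rotation generated by a constant effective field
#' `(Re B1, Im B1, Bz)` acting for `dt`.  With `B = sqrt(|B1|^2 + Bz^2)` the
#' rotation angle is `phi = -gamma * B * dt` about the unit axis
#' `(B1/B, Bz/B)`, giving `alpha = cos(phi/2) - 1i*nz*sin(phi/2)` and
#' `beta = -1i*nxy*sin(phi/2)`.  A zero field returns the identity spinor.
#' All arguments may be per-spin vectors.
#'
#' @param B1 Complex transverse field (T).
#' @param Bz Longitudinal field (T).
#' @param dt Step duration (s, >= 0).
#' @param gamma Gyromagnetic ratio (rad/s/T).
#' @return A [spinor()] (vector-valued).
#' @export
spinor_from_field <- function(B1, Bz, dt, gamma = 2 * pi * 42.58e6) {
  if (any(dt < 0)) stop("dt must be >= 0")
  n <- max(length(B1), length(Bz))
  B1 <- rep_len(as.complex(B1), n)
  Bz <- rep_len(as.numeric(Bz), n)
  B <- sqrt(Mod(B1)^2 + Bz^2)
  phi <- -gamma * B * dt
  alpha <- complex(real = rep(1, n))
  beta <- complex(real = rep(0, n))
  nz <- B > 0
  if (any(nz)) {
    c2 <- cos(phi[nz] / 2); s2 <- sin(phi[nz] / 2)
    alpha[nz] <- complex(real = c2) - 1i * (Bz[nz] / B[nz]) * s2
    beta[nz] <- -1i * (B1[nz] / B[nz]) * s2
  }
  spinor(alpha, beta)
}

#' Apply a spinor rotation to magnetization
#'
#' Elementwise SU(2) action on `(Mxy, Mz)`:
#' `Mxy+ = 2*Conj(a)*b*Mz + Conj(a)^2*Mxy - b^2*Conj(Mxy)` and
#' `Mz+ = (|a|^2 - |b|^2)*Mz - 2*Re(a*b*Conj(Mxy))`.
#'
#' @param s A [spinor()] (scalar or one rotation per spin).
#' @param m A [mag()].
#' @return The rotated [mag()].
#' @export
apply_spinor <- function(s, m) {
  a <- s$alpha; b <- s$beta
  xy <- m$xy; z <- m$z
  xy2 <- 2 * Conj(a) * b * z + Conj(a)^2 * xy - b^2 * Conj(xy)
  z2 <- (Mod(a)^2 - Mod(b)^2) * z - 2 * Re(a * b * Conj(xy))
  mag(xy2, z2)
}

#' Relaxation over a time step
#'
#' Exact solution of the relaxation sub-equation:
#' `Mxy <- Mxy * exp(-dt/T2)`;
#' `Mz <- Mz * exp(-dt/T1) + M0 * (1 - exp(-dt/T1))`.
#'
#' @param m A [mag()].
#' @param dt Step duration (s, >= 0).
#' @param T1,T2 Relaxation times (s); `Inf` disables relaxation.
#' @param M0 Equilibrium longitudinal magnetization (a.u.).
#' @return The relaxed [mag()].
#' @export
relax <- function(m, dt, T1, T2, M0) {
  if (any(dt < 0)) stop("dt must be >= 0")
  e2 <- exp(-dt / T2)
  e1 <- exp(-dt / T1)
  mag(m$xy * e2, m$z * e1 + M0 * (1 - e1))
}

#' One excitation step: rotate, then relax
#'
#' Per spin the longitudinal field is `Bz = G . x(t) + dw/gamma` (gradients
#' and off-resonance both tilt the rotation axis during RF), the constant
#' field `(B1, Bz)` is applied as a spinor rotation over `dt`, then
#' relaxation over the same `dt`.
#'
#' @param m A [mag()].
#' @param phantom An [phantom()].
#' @param B1 Complex RF field over the step (T).
#' @param G Length-3 gradient vector over the step (T/m).
#' @param dt Step duration (s).
#' @param t Time at which spin positions are evaluated (s); pass the step
#'   midpoint for moving phantoms.
#' @param gamma Gyromagnetic ratio (rad/s/T).
#' @return The updated [mag()].
#' @export
excitation_step <- function(m, phantom, B1, G, dt, t = 0,
                            gamma = 2 * pi * 42.58e6) {
  pos <- spin_position(phantom, t)
  Bz <- pos %*% G + phantom$dw / gamma
  s <- spinor_from_field(B1, as.numeric(Bz), dt, gamma)
  relax(apply_spinor(s, m), dt, phantom$T1, phantom$T2, phantom$M0)
}

#' Free-precession over a span of discrete-sequence nodes
#'
#' Exact precession solver for RF-free spans.  The per-spin phase at node k
#' is the trapezoidal cumulative integral
#' `phi_k = -gamma * sum_i (Bz_i + Bz_{i+1})/2 * dt_i` with
#' `Bz = G . x + dw/gamma`, exact for piecewise-linear gradients and static
#' spins.  Transverse magnetization at node k is
#' `xy_in * exp(-(t_k - t_1)/T2) * exp(1i * phi_k)`; the complex signal at
#' requested sample columns is the sum over spins.  Longitudinal relaxation
#' does not couple to precession and is applied once over the span.
#'
#' @param m A [mag()].
#' @param phantom An [phantom()].
#' @param nodes A list with fields `t`, `Gx`, `Gy`, `Gz`, `B1` (all length
#'   nn) - e.g. a sliced [discretize()] result.
#' @param sample_cols Integer indices (into `nodes$t`) at which to record
#'   the summed signal.
#' @param gamma Gyromagnetic ratio (rad/s/T).
#' @param chunk_max Maximum spins x nodes matrix cells held at once.
#' @return `list(m = updated mag, signal = complex vector of
#'   length(sample_cols))`.
#' @export
precession_block <- function(m, phantom, nodes, sample_cols = integer(0),
                             gamma = 2 * pi * 42.58e6, chunk_max = 4e6) {
  if (any(Mod(nodes$B1) > 0))
    stop("internal error: nonzero B1 inside a precession block")
  nn <- length(nodes$t)
  ns <- length(m$xy)
  if (nn == 1) {
    sig <- if (length(sample_cols)) rep(sum(m$xy), length(sample_cols)) else complex(0)
    return(list(m = m, signal = sig))
  }
  tt <- nodes$t
  el <- tt - tt[1]
  dts <- diff(tt)
  moving <- !is.null(phantom$motion)
  csize <- max(1L, min(ns, floor(chunk_max / nn)))
  sig <- complex(real = numeric(length(sample_cols)))
  xy_out <- m$xy
  for (c0 in seq(1, ns, by = csize)) {
    c1 <- min(ns, c0 + csize - 1)
    idx <- c0:c1
    nc <- length(idx)
    if (moving) {
      Bz <- matrix(0, nc, nn)
      for (k in seq_len(nn)) {
        pos <- spin_position(phantom, tt[k])[idx, , drop = FALSE]
        Bz[, k] <- pos[, 1] * nodes$Gx[k] + pos[, 2] * nodes$Gy[k] +
          pos[, 3] * nodes$Gz[k]
      }
      Bz <- Bz + phantom$dw[idx] / gamma
    } else {
      Bz <- outer(phantom$x[idx], nodes$Gx) + outer(phantom$y[idx], nodes$Gy) +
        outer(phantom$z[idx], nodes$Gz) + phantom$dw[idx] / gamma
    }
    # cumulative trapezoid along nodes
    incr <- (Bz[, -1, drop = FALSE] + Bz[, -nn, drop = FALSE]) / 2
    incr <- incr * rep(dts, each = nc)
    phi <- if (nc == 1) -gamma * matrix(cumsum(incr[1, ]), 1)
           else if (nn == 2) -gamma * incr
           else -gamma * t(apply(incr, 1, cumsum))
    phi <- cbind(0, phi)
    decay <- exp(outer(-1 / phantom$T2[idx], el))
    xyk <- (m$xy[idx] * decay) * exp(1i * phi)
    if (length(sample_cols))
      sig <- sig + colSums(xyk[, sample_cols, drop = FALSE])
    xy_out[idx] <- xyk[, nn]
  }
  elapsed <- el[nn]
  e1 <- exp(-elapsed / phantom$T1)
  z_out <- m$z * e1 + phantom$M0 * (1 - e1)
  list(m = mag(xy_out, z_out), signal = sig)
}
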