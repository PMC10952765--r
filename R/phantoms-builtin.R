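#' Four-segment column phantom
#'
#' A one-dimensional column of spins along the y axis (the EPI phase-encode
#' axis), spanning four contiguous 50 mm segments centered on the origin
#' (`y` in `[-100, 100)` mm, `x = z = 0`).  Segment properties, in order of
#' increasing y: `M0 = c(1, 0.5, 1, 0.5)` and `T1 = T2 = c(100, 50, 100,
#' 50)` ms.  Segment membership uses half-open intervals so every spin
#' belongs to exactly one segment.
#'
#' @param spacing Spin spacing (m); the default 1 mm gives 200 spins.
#' @return An [phantom()].
#' @export
column_phantom <- function(spacing = 1e-3) {
  if (spacing <= 0) stop("spacing must be > 0")
  l <- 50e-3
  y <- seq(-2 * l, 2 * l - spacing / 2, by = spacing)
  segment <- pmin(floor((y + 2 * l) / l + 1e-9), 3)  # half-open, float-safe
  M0 <- c(1, 0.5, 1, 0.5)[segment + 1]
  tau <- c(0.1, 0.05, 0.1, 0.05)[segment + 1]
  phantom(x = 0, y = y, z = 0, M0 = M0, T1 = tau, T2 = tau, dw = 0,
          name = "column")
}

#' Concentric-circles phantom
#'
#' Spins on a square grid inside a disc of radius R = 50 mm.  The inner
#' disc (r = 25 mm) carries a constant off-resonance of 200 rad/s and
#' `T1 = T2 = 50` ms; the outer annulus is on-resonance with `T1 = T2 =
#' 100` ms.  `M0 = 1` everywhere.  Region tests are strict-interior
#' (`radius < R`) so boundary spins belong to exactly one region.
#'
#' @param spacing Grid spacing (m).
#' @param dw_inner Off-resonance of the inner disc (rad/s); set 0 for the
#'   on-resonance control.
#' @param relaxation_free If `TRUE`, set `T1 = T2 = Inf` everywhere (useful
#'   for density-map recovery checks).
#' @return An [phantom()].
#' @export
circles_phantom <- function(spacing = 1e-3, dw_inner = 200,
                            relaxation_free = FALSE) {
  if (spacing <= 0) stop("spacing must be > 0")
  R <- 50e-3; r <- 25e-3
  g <- seq(-R, R, by = spacing)
  pts <- expand.grid(x = g, y = g)
  rad <- sqrt(pts$x^2 + pts$y^2)
  keep <- rad < R
  pts <- pts[keep, ]; rad <- rad[keep]
  inner <- rad < r
  tau <- ifelse(inner, 0.05, 0.1)
  if (relaxation_free) tau <- rep(Inf, length(tau))
  phantom(x = pts$x, y = pts$y, z = 0, M0 = 1, T1 = tau, T2 = tau,
          dw = ifelse(inner, dw_inner, 0), name = "circles")
}

#' Pseudo-brain phantom (synthetic stand-in)
#'
#' A two-dimensional multi-ellipse head phantom with three tissue classes
#' (white-matter-, gray-matter- and CSF-like), entirely synthetic: it mimics
#' the geometry of an axial brain slice but is not derived from any imaging
#' database.  Ellipse axes are jittered deterministically from `seed`.
#' Tissue values (M0, T1 ms, T2 ms): WM (0.77, 830, 70), GM (0.86, 1300,
#' 90), CSF (1.0, 4000, 2000).
#'
#' @param spacing Grid spacing (m).
#' @param seed Integer seed; the phantom is deterministic given it.
#' @param dw_range Length-2 range (rad/s) of an optional smooth off-resonance
#'   field (a tilted quadratic across the head); `NULL` for on-resonance.
#' @return An [phantom()].
#' @export
pseudo_brain_phantom <- function(spacing = 2e-3, seed = 1, dw_range = NULL) {
  if (spacing <= 0) stop("spacing must be > 0")
  rng <- local({ set.seed(seed); stats::runif(6, -0.05, 0.05) })
  a <- 90e-3 * (1 + rng[1]); b <- 110e-3 * (1 + rng[2])  # outer skull
  g <- seq(-b, b, by = spacing)
  pts <- expand.grid(x = g, y = g)
  inside <- (pts$x / a)^2 + (pts$y / b)^2 < 1
  pts <- pts[inside, ]
  tissue <- rep(1L, nrow(pts))  # 1 = WM background
  # GM ribbon: between outer ellipse and an inner one
  in2 <- (pts$x / (0.82 * a))^2 + (pts$y / (0.82 * b))^2 < 1
  tissue[!in2] <- 2L
  # CSF: two ventricle-like ellipses, jittered
  for (s in c(-1, 1)) {
    vx <- s * 22e-3 * (1 + rng[3]); vy <- 15e-3 * (1 + rng[4])
    va <- 12e-3 * (1 + rng[5]); vb <- 30e-3 * (1 + rng[6])
    inv <- ((pts$x - vx) / va)^2 + ((pts$y - vy) / vb)^2 < 1
    tissue[inv] <- 3L
  }
  M0 <- c(0.77, 0.86, 1.0)[tissue]
  T1 <- c(0.83, 1.3, 4.0)[tissue]
  T2 <- c(0.07, 0.09, 2.0)[tissue]
  dw <- rep(0, nrow(pts))
  if (!is.null(dw_range)) {
    stopifnot(length(dw_range) == 2, dw_range[2] > dw_range[1])
    f <- pts$x / a + (pts$y / b)^2          # smooth, in [-1, 1+]
    f <- (f - min(f)) / (max(f) - min(f))
    dw <- dw_range[1] + f * (dw_range[2] - dw_range[1])
  }
  phantom(x = pts$x, y = pts$y, z = 0, M0 = M0, T1 = T1, T2 = T2, dw = dw,
          name = "pseudo_brain")
}

#' Attach rigid linear motion along y
#'
#' Adds the Lagrangian displacement field `u(x0, t) = (0, vy * t, 0)`.
#'
#' @param phantom An [phantom()].
#' @param vy Velocity along y (m/s).
#' @return The phantom with the motion field attached (or static if
#'   `vy = 0`).
#' @export
with_linear_motion <- function(phantom, vy) {
  if (vy == 0) { phantom$motion <- NULL; return(phantom) }
  phantom$motion <- function(pos0, t) {
    u <- matrix(0, nrow(pos0), 3)
    u[, 2] <- vy * t
    u
  }
  phantom
}
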