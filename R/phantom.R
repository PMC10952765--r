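#' Spin phantom
#'
#' A phantom is a set of N isochromats ("spins"), each with a position,
#' proton density, relaxation times and off-resonance frequency.  Positions
#' are continuous coordinates in meters; no grid is implied.  An optional
#' Lagrangian motion field gives the displacement of each spin as a function
#' of its initial position and time.
#'
#' @param x,y,z Spin positions (m).  Scalars are recycled to the common
#'   length.
#' @param M0 Proton density per spin (arbitrary units, >= 0).
#' @param T1 Longitudinal relaxation time per spin (s, > 0; `Inf` allowed).
#' @param T2 Transverse relaxation time per spin (s, > 0; `Inf` allowed).
#' @param dw Off-resonance angular frequency per spin (rad/s).
#' @param motion Either `NULL` (static phantom) or a function
#'   `function(pos0, t)` mapping the N x 3 matrix of initial positions and a
#'   time (s) to an N x 3 displacement matrix (m).
#' @param name Optional phantom name (used in file headers).
#'
#' @return An object of class `mr_phantom`.
#' @seealso [spin_position()], [equilibrium_mag()], [column_phantom()]
#' @export
phantom <- function(x, y = 0, z = 0, M0 = 1, T1 = Inf, T2 = Inf, dw = 0,
                    motion = NULL, name = "phantom") {
  n <- max(length(x), length(y), length(z), length(M0),
           length(T1), length(T2), length(dw))
  if (n < 1) stop("phantom must contain at least one spin")
  rec <- function(v, what) {
    if (length(v) == 1) v <- rep(v, n)
    if (length(v) != n)
      stop(sprintf("phantom field '%s' has length %d, expected %d",
                   what, length(v), n))
    if (!all(is.finite(v) | v == Inf))
      stop(sprintf("phantom field '%s' contains non-finite values", what))
    as.numeric(v)
  }
  x <- rec(x, "x"); y <- rec(y, "y"); z <- rec(z, "z")
  M0 <- rec(M0, "M0"); T1 <- rec(T1, "T1"); T2 <- rec(T2, "T2")
  dw <- rec(dw, "dw")
  if (any(M0 < 0)) stop("M0 must be >= 0")
  if (any(T1 <= 0)) stop("T1 must be > 0")
  if (any(T2 <= 0)) stop("T2 must be > 0")
  if (!is.null(motion) && !is.function(motion))
    stop("motion must be NULL or a function(pos0, t)")
  structure(list(x = x, y = y, z = z, M0 = M0, T1 = T1, T2 = T2, dw = dw,
                 motion = motion, name = name),
            class = "mr_phantom")
}

#' Number of spins in a phantom
#' @param phantom An `mr_phantom`.
#' @return Integer spin count.
#' @export
n_spins <- function(phantom) length(phantom$x)

#' @export
print.mr_phantom <- function(x, ...) {
  cat(sprintf("<mr_phantom> '%s': %d spins%s\n", x$name, n_spins(x),
              if (is.null(x$motion)) "" else " (moving)"))
  cat(sprintf("  T1 [%g, %g] ms, T2 [%g, %g] ms, |dw| max %g rad/s\n",
              min(x$T1) * 1e3, max(x$T1) * 1e3,
              min(x$T2) * 1e3, max(x$T2) * 1e3, max(abs(x$dw))))
  invisible(x)
}

#' Spin positions at a given time
#'
#' Returns initial positions plus the motion-field displacement at time `t`;
#' for a static phantom the positions are time-invariant.
#'
#' @param phantom An `mr_phantom`.
#' @param t Time (s, >= 0).
#' @return An N x 3 matrix of positions (m), columns x, y, z.
#' @export
spin_position <- function(phantom, t) {
  if (t < 0) stop("t must be >= 0")
  pos <- cbind(x = phantom$x, y = phantom$y, z = phantom$z)
  if (!is.null(phantom$motion)) {
    u <- phantom$motion(pos, t)
    if (!is.matrix(u) || !all(dim(u) == dim(pos)))
      stop("motion function must return an N x 3 displacement matrix")
    pos <- pos + u
  }
  pos
}

#' Magnetization state
#'
#' Per-spin magnetization: complex transverse component `xy = Mx + i*My` and
#' real longitudinal component `z`.
#'
#' @param xy Complex vector of transverse magnetization (a.u.).
#' @param z Numeric vector of longitudinal magnetization (a.u.).
#' @return An object of class `mag`.
#' @export
mag <- function(xy, z) {
  if (length(xy) != length(z)) stop("xy and z must have equal length")
  xy <- as.complex(xy)
  z <- as.numeric(z)
  if (!all(is.finite(Re(xy)) & is.finite(Im(xy))) || !all(is.finite(z)))
    stop("magnetization must be finite")
  structure(list(xy = xy, z = z), class = "mag")
}

#' Thermal-equilibrium magnetization of a phantom
#'
#' @param phantom An `mr_phantom`.
#' @return A [mag()] with `xy = 0` and `z = M0` per spin.
#' @export
equilibrium_mag <- function(phantom) {
  n <- n_spins(phantom)
  mag(complex(real = rep(0, n)), phantom$M0)
}

#' SU(2) rotation (Cayley-Klein parameters)
#'
#' A spinor `(alpha, beta)` with `|alpha|^2 + |beta|^2 = 1` encodes a 3-D
#' rotation of the magnetization.  Vector-valued fields encode one rotation
#' per spin.
#'
#' @param alpha,beta Complex Cayley-Klein parameters.
#' @return An object of class `spinor`.
#' @export
spinor <- function(alpha, beta) {
  if (length(alpha) != length(beta))
    stop("alpha and beta must have equal length")
  alpha <- as.complex(alpha); beta <- as.complex(beta)
  nrm <- Mod(alpha)^2 + Mod(beta)^2
  if (any(abs(nrm - 1) > 1e-9))
    stop("spinor is not normalized: |alpha|^2 + |beta|^2 must be 1")
  structure(list(alpha = alpha, beta = beta), class = "spinor")
}

#' Write / read a phantom to the HDF5 layout
#'
#' The file carries datasets `/position` (N x 3, m), `/M0`, `/T1`, `/T2`,
#' `/dw` (each length N).  Motion fields are code-level objects and are not
#' serialized.
#'
#' @param phantom An `mr_phantom`.
#' @param path File path.
#' @return `read_phantom_h5` returns an `mr_phantom`; `write_phantom_h5`
#'   returns `path` invisibly.
#' @export
write_phantom_h5 <- function(phantom, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5write(cbind(phantom$x, phantom$y, phantom$z), path, "position")
  rhdf5::h5write(phantom$M0, path, "M0")
  rhdf5::h5write(phantom$T1, path, "T1")
  rhdf5::h5write(phantom$T2, path, "T2")
  rhdf5::h5write(phantom$dw, path, "dw")
  invisible(path)
}

#' @rdname write_phantom_h5
#' @export
read_phantom_h5 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  pos <- rhdf5::h5read(path, "position")
  phantom(x = pos[, 1], y = pos[, 2], z = pos[, 3],
          M0 = as.numeric(rhdf5::h5read(path, "M0")),
          T1 = as.numeric(rhdf5::h5read(path, "T1")),
          T2 = as.numeric(rhdf5::h5read(path, "T2")),
          dw = as.numeric(rhdf5::h5read(path, "dw")),
          name = sub("\\.h5$", "", basename(path)))
}
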