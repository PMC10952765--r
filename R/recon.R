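fftshift_mat <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  m[c((floor(n1 / 2) + 1):n1, 1:floor(n1 / 2)),
    c((floor(n2 / 2) + 1):n2, 1:floor(n2 / 2))]
}

ifftshift_mat <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  m[c((n1 - floor(n1 / 2) + 1):n1, 1:(n1 - floor(n1 / 2))),
    c((n2 - floor(n2 / 2) + 1):n2, 1:(n2 - floor(n2 / 2)))]
}

#' Cartesian EPI reconstruction
#'
#' Undoes the serpentine readout (every second line acquired under negative
#' readout polarity is reversed), arranges the samples into an n x n
#' k-space matrix (rows = phase-encode lines, ky ascending; columns = kx
#' ascending) and applies a centered inverse 2-D discrete Fourier
#' transform.  Pixel `[p, q]` sits at `y = (p - 1 - n/2) * fov/n`,
#' `x = (q - 1 - n/2) * fov/n`.
#'
#' @param raw A [raw_data()] from an EPI acquisition (n readouts of n).
#' @param n Matrix size; defaults to the header's matrix size.
#' @return Complex n x n image matrix.
#' @export
recon_cartesian_epi <- function(raw, n = NULL) {
  if (is.null(n)) n <- raw$header$matrix_size[1]
  if (length(raw$readouts) != n)
    stop(sprintf("expected %d readouts, got %d", n, length(raw$readouts)))
  K <- matrix(0 + 0i, n, n)
  for (m in seq_len(n)) {
    d <- raw$readouts[[m]]$data
    if (length(d) != n)
      stop(sprintf("readout %d has %d samples, expected %d", m, length(d), n))
    if (m %% 2 == 0) d <- rev(d)  # odd (0-based) lines: negative polarity
    K[m, ] <- d
  }
  fftshift_mat(stats::fft(ifftshift_mat(K), inverse = TRUE)) / n^2
}

#' Direct adjoint (conjugate-phase) reconstruction
#'
#' `image(p) = sum_samples d * w * exp(+2i pi k . p)` over an n x n grid of
#' pixel centers, with density-compensation weights `w`: uniform for
#' Cartesian rasters, ramp `|k|` for radial spokes.  Exact but O(samples x
#' pixels); intended for desk-scale non-Cartesian data.
#'
#' @param raw A [raw_data()] whose readouts carry trajectories.
#' @param n Image matrix size.
#' @param fov Field of view (m); defaults to the header fov.
#' @param dcf `"uniform"` or `"ramp"`.
#' @return Complex n x n image matrix (rows = y, columns = x).
#' @export
recon_adjoint <- function(raw, n, fov = NULL, dcf = c("uniform", "ramp")) {
  dcf <- match.arg(dcf)
  if (is.null(fov)) fov <- raw$header$fov[1]
  if (is.null(fov)) stop("fov not given and absent from header")
  kx <- ky <- d <- numeric(0)
  for (r in raw$readouts) {
    if (is.null(r$traj)) stop("readout lacks a k-space trajectory")
    kx <- c(kx, r$traj[, 1]); ky <- c(ky, r$traj[, 2])
    d <- c(d, r$data)
  }
  w <- if (dcf == "ramp") {
    wk <- sqrt(kx^2 + ky^2)
    wk[wk == 0] <- min(wk[wk > 0], na.rm = TRUE) / 4
    wk / mean(wk)
  } else rep(1, length(d))
  px <- ((seq_len(n) - 1) - n / 2) * fov / n
  img <- matrix(0 + 0i, n, n)
  dw <- d * w
  chunk <- max(1L, floor(2e6 / n))
  for (c0 in seq(1, length(dw), by = chunk)) {
    c1 <- min(length(dw), c0 + chunk - 1)
    sel <- c0:c1
    ex <- exp(2i * pi * outer(px, kx[sel]))      # n x ns (x phase)
    ey <- exp(2i * pi * outer(py <- px, ky[sel]))
    img <- img + ey %*% (t(ex) * dw[sel])        # rows y, cols x
  }
  img / length(dw)
}

#' Mean absolute difference of two normalized signals, in percent
#'
#' Both series are divided by `max(Mod(xref))`, then the mean elementwise
#' absolute (complex) difference is returned as a percentage.
#'
#' @param x,xref Complex (or numeric) series of equal length; `xref` is the
#'   reference whose maximum magnitude normalizes both.
#' @return Scalar percentage.
#' @examples
#' signal_mad(c(0, 1), c(1, 1))  # 50
#' @export
signal_mad <- function(x, xref) {
  if (length(x) != length(xref)) stop("series lengths differ")
  m <- max(Mod(xref))
  if (m == 0) stop("reference signal maximum is zero")
  100 * mean(Mod(x / m - xref / m))
}
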