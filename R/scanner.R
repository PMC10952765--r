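#' Scanner system description
#'
#' Holds the hardware limits and physical constants of the simulated system.
#' All fields are strict SI: Tesla, T/m, T/m/s, seconds, rad/s/T.
#'
#' @param B0 Main field strength (T).
#' @param Gmax Maximum gradient amplitude (T/m).
#' @param Smax Maximum slew rate (T/m/s).
#' @param raster_time Minimum event time raster (s).
#' @param gamma Gyromagnetic ratio (rad/s/T).  The default, `2*pi*42.58e6`,
#'   is the proton value rounded as commonly printed on clinical systems; a
#'   CODATA-precision value can be passed instead.
#'
#' @return An object of class `mr_scanner`.
#' @examples
#' sc <- scanner()
#' sc$gamma / (2 * pi)  # Larmor frequency per Tesla, Hz/T
#' @export
scanner <- function(B0 = 1.5, Gmax = 60e-3, Smax = 500,
                    raster_time = 1e-6, gamma = 2 * pi * 42.58e6) {
  stopifnot(is.numeric(B0), length(B0) == 1)
  if (Gmax <= 0) stop("Gmax must be positive")
  if (Smax <= 0) stop("Smax must be positive")
  if (raster_time <= 0) stop("raster_time must be positive")
  if (gamma <= 0) stop("gamma must be positive")
  structure(list(B0 = B0, Gmax = Gmax, Smax = Smax,
                 raster_time = raster_time, gamma = gamma),
            class = "mr_scanner")
}

# alias so other functions can use scanner() as a default for an argument
# that is itself named `scanner` without tripping lazy-evaluation recursion
default_scanner <- function() scanner()

#' @export
print.mr_scanner <- function(x, ...) {
  cat(sprintf("<mr_scanner> B0 = %g T, Gmax = %g mT/m, Smax = %g T/m/s\n",
              x$B0, x$Gmax * 1e3, x$Smax))
  cat(sprintf("  raster = %g us, gamma/2pi = %.6g MHz/T\n",
              x$raster_time * 1e6, x$gamma / (2 * pi) / 1e6))
  invisible(x)
}

#' Gyromagnetic ratio in scanner-interface units
#'
#' Converts a gyromagnetic ratio from rad/s/T to rad/us/mT, the scaling in
#' which some simulator front ends express gradient strengths (a gradient of
#' G mT/m is entered as `gamma_scaled(gamma) * G`).
#'
#' @param gamma Gyromagnetic ratio (rad/s/T), positive.
#' @return The same ratio expressed in rad/us/mT, i.e. `gamma * 1e-9`.
#' @examples
#' gamma_scaled(2 * pi * 42.58e6)  # ~0.267538
#' @export
gamma_scaled <- function(gamma) {
  if (!is.numeric(gamma) || any(gamma <= 0)) stop("gamma must be positive")
  gamma * 1e-9
}
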