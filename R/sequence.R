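#' RF pulse event
#'
#' A complex B1 envelope sampled piecewise-constant on a raster.  The
#' physical field during raster bin j (zero-based) is
#' `amplitude[j+1] * exp(1i * (phase_offset + freq_offset * t_loc))` where
#' `t_loc` is time from the pulse start.
#'
#' @param amplitude Complex envelope samples B1 (T); one value per raster bin.
#' @param raster Sample spacing (s, > 0).
#' @param delay Offset of the pulse start from the block start (s, >= 0).
#' @param freq_offset Carrier frequency offset (rad/s).
#' @param phase_offset Carrier phase offset (rad).
#' @return An object of class `rf_event`.
#' @export
rf_event <- function(amplitude, raster, delay = 0, freq_offset = 0,
                     phase_offset = 0) {
  amplitude <- as.complex(amplitude)
  if (length(amplitude) < 1) stop("rf_event needs at least one sample")
  if (!all(is.finite(Re(amplitude)) & is.finite(Im(amplitude))))
    stop("rf amplitude must be finite")
  if (raster <= 0) stop("raster must be > 0")
  if (delay < 0) stop("delay must be >= 0")
  structure(list(amplitude = amplitude, raster = raster, delay = delay,
                 freq_offset = freq_offset, phase_offset = phase_offset),
            class = "rf_event")
}

event_end <- function(ev) {
  if (is.null(ev)) return(0)
  switch(class(ev)[1],
         rf_event = ev$delay + length(ev$amplitude) * ev$raster,
         grad_event = max(ev$times),
         adc_event = ev$delay + ev$num_samples * ev$dwell,
         stop("unknown event"))
}

#' Evaluate an RF envelope at local times
#'
#' Piecewise-constant lookup of the complex B1 field (carrier included) at
#' times relative to the block start.  Zero outside the pulse.
#'
#' @param rf An `rf_event` or `NULL`.
#' @param t Times relative to block start (s).
#' @return Complex vector of B1 values (T).
#' @keywords internal
rf_field_at <- function(rf, t) {
  out <- complex(real = numeric(length(t)))
  if (is.null(rf)) return(out)
  tl <- t - rf$delay
  n <- length(rf$amplitude)
  # right-continuous bins: bin j covers [j*raster, (j+1)*raster)
  j <- floor(tl / rf$raster + 1e-9)
  ok <- j >= 0 & j < n
  if (any(ok)) {
    amp <- rf$amplitude[j[ok] + 1]
    out[ok] <- amp * exp(1i * (rf$phase_offset + rf$freq_offset * tl[ok]))
  }
  out
}

#' Mean RF field over time intervals
#'
#' Exact average of the piecewise-constant complex B1 field over
#' `[t0, t1]` intervals (local times).  Used by the dense reference
#' integrator; the sequence-aware path never needs it because its steps
#' never straddle raster bins.
#' @keywords internal
rf_field_mean <- function(rf, t0, t1) {
  if (is.null(rf)) return(complex(real = numeric(length(t0))))
  # integrate the envelope via a fine subdivision of each raster bin overlap
  n <- length(rf$amplitude)
  edges <- rf$delay + rf$raster * (0:n)
  vapply(seq_along(t0), function(i) {
    a <- t0[i]; b <- t1[i]
    if (b <= a) return(rf_field_at(rf, a))
    cuts <- sort(unique(c(a, b, edges[edges > a & edges < b])))
    mids <- (cuts[-1] + cuts[-length(cuts)]) / 2
    w <- diff(cuts)
    sum(rf_field_at(rf, mids) * w) / (b - a)
  }, complex(1))
}

#' Gradient waveform event
#'
#' A piecewise-linear waveform on one gradient axis, defined by vertex times
#' (relative to block start) and amplitudes.  The waveform is zero outside
#' `[times[1], times[n]]`; builders normally start and end at amplitude 0.
#'
#' @param times Vertex times (s), strictly increasing.
#' @param amplitudes Gradient amplitude at each vertex (T/m).
#' @param axis One of `"x"`, `"y"`, `"z"`.
#' @return An object of class `grad_event`.
#' @export
grad_event <- function(times, amplitudes, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  if (length(times) != length(amplitudes) || length(times) < 2)
    stop("times and amplitudes must have equal length >= 2")
  if (any(diff(times) <= 0)) stop("vertex times must be strictly increasing")
  if (times[1] < 0) stop("vertex times must be >= 0")
  if (!all(is.finite(amplitudes))) stop("amplitudes must be finite")
  structure(list(times = as.numeric(times),
                 amplitudes = as.numeric(amplitudes), axis = axis),
            class = "grad_event")
}

grad_field_at <- function(g, t) {
  if (is.null(g)) return(numeric(length(t)))
  out <- numeric(length(t))
  inside <- t >= g$times[1] - 1e-12 & t <= g$times[length(g$times)] + 1e-12
  if (any(inside))
    out[inside] <- stats::approx(g$times, g$amplitudes, xout = t[inside],
                                 rule = 2)$y
  out
}

#' Net area of a gradient event (T s / m)
#' @keywords internal
grad_area <- function(g) {
  if (is.null(g)) return(0)
  sum(diff(g$times) * (g$amplitudes[-1] + g$amplitudes[-length(g$amplitudes)]) / 2)
}

#' ADC sampling event
#'
#' `num_samples` signal samples at the centers of contiguous dwell windows:
#' sample j (zero-based) is taken at `delay + (j + 1/2) * dwell` from the
#' block start.
#'
#' @param num_samples Number of samples (>= 1).
#' @param dwell Sample spacing (s, > 0).
#' @param delay Offset of the sampling window from block start (s).
#' @param phase Receiver demodulation phase (rad); samples are multiplied by
#'   `exp(-1i * phase)` when grouped into readouts.
#' @return An object of class `adc_event`.
#' @export
adc_event <- function(num_samples, dwell, delay = 0, phase = 0) {
  if (num_samples < 1) stop("num_samples must be >= 1")
  if (dwell <= 0) stop("dwell must be > 0")
  if (delay < 0) stop("delay must be >= 0")
  structure(list(num_samples = as.integer(num_samples), dwell = dwell,
                 delay = delay, phase = phase),
            class = "adc_event")
}

adc_sample_times <- function(adc) {
  adc$delay + (seq_len(adc$num_samples) - 0.5) * adc$dwell
}

#' Sequence block
#'
#' One block of simultaneous events: at most one RF pulse, one gradient
#' waveform per axis, and one ADC window.  The block duration must cover
#' every contained event.
#'
#' @param rf Optional [rf_event()].
#' @param gx,gy,gz Optional [grad_event()] per axis.
#' @param adc Optional [adc_event()].
#' @param duration Block length (s); defaults to the latest event end.
#' @param refocus Logical flag marking the block's RF pulse as a 180-degree
#'   refocusing pulse; [k_trajectory()] negates the accumulated k-vector at
#'   the pulse center (display metadata only - the RF itself is simulated).
#' @return An object of class `seq_block`.
#' @export
seq_block <- function(rf = NULL, gx = NULL, gy = NULL, gz = NULL, adc = NULL,
                      duration = NULL, refocus = FALSE) {
  for (nm in c("gx", "gy", "gz")) {
    g <- get(nm)
    if (!is.null(g) && !inherits(g, "grad_event"))
      stop(nm, " must be a grad_event")
  }
  ends <- c(event_end(rf), event_end(gx), event_end(gy), event_end(gz),
            event_end(adc))
  if (is.null(duration)) duration <- max(ends)
  if (duration < max(ends) - 1e-12)
    stop("block duration is shorter than a contained event")
  if (duration <= 0) stop("block duration must be positive")
  structure(list(rf = rf, gx = gx, gy = gy, gz = gz, adc = adc,
                 duration = duration, refocus = isTRUE(refocus)),
            class = "seq_block")
}

#' Pure delay block
#' @param duration Delay (s, > 0).
#' @return A [seq_block()] with no events.
#' @export
delay_block <- function(duration) seq_block(duration = duration)

#' Pulse sequence
#'
#' An ordered list of [seq_block()]s plus free-form definitions (name,
#' field of view, matrix size) carried into file headers.
#'
#' @param blocks List of `seq_block` objects (at least one).
#' @param name Sequence name.
#' @param fov Field of view, length-2 numeric (m), or `NULL`.
#' @param matrix_size Reconstruction matrix, length-2 integer, or `NULL`.
#' @return An object of class `mr_sequence`.
#' @export
mr_sequence <- function(blocks, name = "seq", fov = NULL, matrix_size = NULL) {
  if (length(blocks) < 1) stop("sequence needs at least one block")
  if (!all(vapply(blocks, inherits, TRUE, "seq_block")))
    stop("all elements must be seq_block objects")
  structure(list(blocks = blocks, name = name, fov = fov,
                 matrix_size = matrix_size),
            class = "mr_sequence")
}

#' Total sequence duration (s)
#' @param seq An `mr_sequence`.
#' @export
seq_duration <- function(seq) sum(vapply(seq$blocks, `[[`, 0, "duration"))

block_starts <- function(seq) {
  durs <- vapply(seq$blocks, `[[`, 0, "duration")
  c(0, cumsum(durs))[seq_along(durs)]
}

#' @export
print.mr_sequence <- function(x, ...) {
  nb <- length(x$blocks)
  nadc <- sum(vapply(x$blocks, function(b) !is.null(b$adc), TRUE))
  nrf <- sum(vapply(x$blocks, function(b) !is.null(b$rf), TRUE))
  cat(sprintf("<mr_sequence> '%s': %d blocks, %d RF, %d ADC, %.3f ms\n",
              x$name, nb, nrf, nadc, seq_duration(x) * 1e3))
  invisible(x)
}

#' Validate a sequence against scanner limits
#'
#' Checks every gradient vertex against `Gmax` and every vertex-to-vertex
#' slope against `Smax`.
#'
#' @param seq An `mr_sequence`.
#' @param scanner An [scanner()].
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_sequence <- function(seq, scanner) {
  for (i in seq_along(seq$blocks)) {
    b <- seq$blocks[[i]]
    for (g in list(b$gx, b$gy, b$gz)) {
      if (is.null(g)) next
      if (max(abs(g$amplitudes)) > scanner$Gmax * (1 + 1e-9))
        stop(sprintf("block %d: gradient amplitude %.4g T/m exceeds Gmax",
                     i, max(abs(g$amplitudes))))
      slew <- abs(diff(g$amplitudes) / diff(g$times))
      if (any(slew > scanner$Smax * (1 + 1e-9)))
        stop(sprintf("block %d: slew rate %.4g T/m/s exceeds Smax",
                     i, max(slew)))
    }
  }
  invisible(TRUE)
}
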