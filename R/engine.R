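#' Simulation-method registry
#'
#' The engine dispatches three hooks through a `simulation_method` object:
#' `initialize_state(phantom)`, an excitation handler, and a precession
#' handler, so alternative spin-state representations (e.g. extended phase
#' graphs) can reuse the discretization, chunking and signal plumbing.  The
#' default `"bloch"` method wires the magnetization kernels
#' ([spinor_from_field()]/[apply_spinor()]/[relax()]/[precession_block()]).
#'
#' @param tag Method name.
#' @param initialize_state `function(phantom) -> state`.
#' @param run_excitation `function(state, phantom, dseq, from, to,
#'   sample_cols, gamma) -> list(state, signal)` where `from:to` are step
#'   indices.
#' @param run_precession Same signature as `run_excitation`.
#' @return An object of class `simulation_method`.
#' @export
simulation_method <- function(tag, initialize_state, run_excitation,
                              run_precession) {
  structure(list(tag = tag, initialize_state = initialize_state,
                 run_excitation = run_excitation,
                 run_precession = run_precession),
            class = "simulation_method")
}

bloch_run_excitation <- function(state, phantom, dseq, from, to, sample_cols,
                                 gamma) {
  sig <- complex(real = numeric(length(sample_cols)))
  node_of_sample <- sample_cols  # node index == column in the global dseq
  for (k in from:to) {
    G <- c((dseq$Gx[k] + dseq$Gx[k + 1]) / 2,
           (dseq$Gy[k] + dseq$Gy[k + 1]) / 2,
           (dseq$Gz[k] + dseq$Gz[k + 1]) / 2)
    tmid <- (dseq$t[k] + dseq$t[k + 1]) / 2
    state <- excitation_step(state, phantom, dseq$B1[k], G, dseq$dt[k],
                             t = tmid, gamma = gamma)
    hit <- which(node_of_sample == k + 1)
    if (length(hit)) sig[hit] <- sum(state$xy)
  }
  list(state = state, signal = sig)
}

bloch_run_precession <- function(state, phantom, dseq, from, to, sample_cols,
                                 gamma) {
  span <- from:(to + 1)
  nodes <- list(t = dseq$t[span], Gx = dseq$Gx[span], Gy = dseq$Gy[span],
                Gz = dseq$Gz[span], B1 = dseq$B1[span])
  res <- precession_block(state, phantom, nodes,
                          sample_cols = match(sample_cols, span),
                          gamma = gamma)
  list(state = res$m, signal = res$signal)
}

bloch_method <- function() {
  simulation_method("bloch", initialize_state = equilibrium_mag,
                    run_excitation = bloch_run_excitation,
                    run_precession = bloch_run_precession)
}

#' Simulate an MRI acquisition
#'
#' Full pipeline: discretize the sequence with sequence-aware time stepping,
#' partition the steps into excitation/precession simulation blocks, split
#' the phantom into `n_threads` disjoint spin chunks, run each block with the
#' regime's solver, accumulate per-chunk partial signals, and package the
#' sampled signal into readouts.  The signal is the unweighted sum of the
#' transverse magnetization over spins (single uniform receive coil, no
#' noise); it is invariant to `n_threads` and `n_blocks`.
#'
#' @param phantom An [phantom()].
#' @param seq An [mr_sequence()].
#' @param scanner A [scanner()].
#' @param config A [sim_config()].
#' @param method A [simulation_method()]; default is the Bloch
#'   magnetization solver.
#' @return A [raw_data()] object.
#' @examples
#' ph <- phantom(x = 0, M0 = 1, T1 = 0.1, T2 = 0.05)
#' sq <- mr_sequence(list(hard_pulse(pi / 2, 5e-4),
#'                        seq_block(adc = adc_event(8, 1e-3))))
#' rd <- simulate_mri(ph, sq, scanner(), sim_config())
#' Mod(rd$readouts[[1]]$data)  # FID decaying with T2
#' @export
simulate_mri <- function(phantom, seq, scanner = default_scanner(),
                         config = sim_config(), method = NULL) {
  if (is.null(method)) {
    method <- switch(config$method,
                     bloch = bloch_method(),
                     stop("unknown simulation method tag: ", config$method))
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  dseq <- discretize(seq, config, scanner, has_motion = !is.null(phantom$motion))
  blocks <- partition_blocks(dseq, config)
  adc_nodes <- which(dseq$adc)
  if (length(adc_nodes) == 0)
    warning("sequence has no ADC events; raw data will be empty")
  n <- n_spins(phantom)
  nth <- min(config$n_threads, n)
  bnds <- round(seq(0, n, length.out = nth + 1))
  samples <- complex(real = numeric(length(adc_nodes)))
  for (ci in seq_len(nth)) {
    if (bnds[ci + 1] <= bnds[ci]) next
    sel <- (bnds[ci] + 1):bnds[ci + 1]
    sub <- phantom_subset(phantom, sel)
    state <- method$initialize_state(sub)
    partial <- complex(real = numeric(length(adc_nodes)))
    # a sample at the very first node is the initial state
    first <- which(adc_nodes == 1L)
    if (length(first)) partial[first] <- sum(state$xy)
    for (b in blocks) {
      cols <- adc_nodes[adc_nodes > b$from & adc_nodes <= b$to + 1L]
      hit <- match(cols, adc_nodes)
      run <- if (b$regime == "excitation") method$run_excitation
             else method$run_precession
      res <- run(state, sub, dseq, b$from, b$to, cols, scanner$gamma)
      state <- res$state
      if (length(hit)) partial[hit] <- res$signal
    }
    samples <- samples + partial
  }
  signal_to_readouts(dseq, seq, samples, scanner = scanner,
                     sim_params = config)
}

phantom_subset <- function(ph, sel) {
  structure(list(x = ph$x[sel], y = ph$y[sel], z = ph$z[sel],
                 M0 = ph$M0[sel], T1 = ph$T1[sel], T2 = ph$T2[sel],
                 dw = ph$dw[sel],
                 motion = ph$motion, name = ph$name),
            class = "mr_phantom")
}

#' Raw acquisition data
#'
#' @param readouts List of readouts, each `list(t, data, traj)`: absolute
#'   sample times (s), complex samples, and an optional N x 3 k-space
#'   trajectory (1/m).
#' @param header List with `fov` (m), `matrix_size`, `name`, `sim_params`.
#' @return An object of class `raw_data`.
#' @export
raw_data <- function(readouts, header = list()) {
  for (r in readouts) {
    if (length(r$t) != length(r$data))
      stop("readout sample times and data lengths differ")
  }
  structure(list(readouts = readouts, header = header), class = "raw_data")
}

#' @export
print.raw_data <- function(x, ...) {
  ns <- vapply(x$readouts, function(r) length(r$data), 0L)
  cat(sprintf("<raw_data> '%s': %d readouts, %d samples\n",
              if (is.null(x$header$name)) "?" else x$header$name,
              length(ns), sum(ns)))
  invisible(x)
}

#' Group sampled signal into readouts
#'
#' One readout per ADC event in sequence order.  The receiver phase of each
#' ADC event is applied as `exp(-1i * phase)`; the k-space trajectory from
#' [k_trajectory()] is attached per readout.
#'
#' @param dseq The [discretize()] result used for the simulation.
#' @param seq The source [mr_sequence()].
#' @param samples Complex samples, one per ADC node of `dseq`, in node order.
#' @param scanner A [scanner()] (for the trajectory's gamma).
#' @param sim_params Optional [sim_config()] snapshot for the header.
#' @return A [raw_data()].
#' @export
signal_to_readouts <- function(dseq, seq, samples, scanner = default_scanner(),
                               sim_params = NULL) {
  adc_nodes <- which(dseq$adc)
  if (length(samples) != length(adc_nodes))
    stop("internal error: sample count does not match ADC node count")
  ids <- dseq$adc_id[adc_nodes]
  traj <- k_trajectory(seq, scanner$gamma)
  adc_events <- Filter(Negate(is.null),
                       lapply(seq$blocks, function(b) b$adc))
  readouts <- lapply(seq_along(adc_events), function(e) {
    sel <- ids == e
    ph <- adc_events[[e]]$phase
    list(t = dseq$t[adc_nodes[sel]],
         data = samples[sel] * exp(-1i * ph),
         traj = traj[[e]])
  })
  hdr <- list(fov = seq$fov, matrix_size = seq$matrix_size, name = seq$name,
              sim_params = if (is.null(sim_params)) list() else
                unclass(sim_params))
  raw_data(readouts, hdr)
}

#' k-space trajectory of a sequence
#'
#' `k(t) = gamma/(2*pi) * integral of G` computed exactly on the
#' piecewise-linear gradient waveforms, evaluated at every ADC sample time.
#' Excitation pulses do not reset k, but a block flagged `refocus`
#' (180-degree pulse) negates the k accumulated up to its RF center.
#'
#' @param seq An [mr_sequence()].
#' @param gamma Gyromagnetic ratio (rad/s/T).
#' @return A list with one N x 3 matrix (1/m) per ADC event, in order.
#' @export
k_trajectory <- function(seq, gamma = 2 * pi * 42.58e6) {
  starts <- block_starts(seq)
  # gather: per axis absolute-time knots, refocus times, adc times
  refocus_t <- numeric(0)
  adc_t <- list()
  knots <- list(x = numeric(0), y = numeric(0), z = numeric(0))
  segs <- list(x = NULL, y = NULL, z = NULL)  # matrices: t0,t1,a0,a1
  for (i in seq_along(seq$blocks)) {
    b <- seq$blocks[[i]]
    t0 <- starts[i]
    for (ax in c("x", "y", "z")) {
      g <- b[[paste0("g", ax)]]
      if (is.null(g)) next
      nt <- length(g$times)
      segs[[ax]] <- rbind(segs[[ax]],
                          cbind(t0 + g$times[-nt], t0 + g$times[-1],
                                g$amplitudes[-nt], g$amplitudes[-1]))
    }
    if (b$refocus && !is.null(b$rf))
      refocus_t <- c(refocus_t,
                     t0 + b$rf$delay +
                       length(b$rf$amplitude) * b$rf$raster / 2)
    if (!is.null(b$adc))
      adc_t <- c(adc_t, list(t0 + adc_sample_times(b$adc)))
  }
  area_at <- function(ax, tq) {
    s <- segs[[ax]]
    out <- numeric(length(tq))
    if (is.null(s)) return(out)
    ord <- order(s[, 1])
    s <- s[ord, , drop = FALSE]
    a_cum <- c(0, cumsum((s[, 2] - s[, 1]) * (s[, 3] + s[, 4]) / 2))
    for (q in seq_along(tq)) {
      t <- tq[q]
      done <- which(s[, 2] <= t + 1e-15)
      acc <- if (length(done)) a_cum[max(done) + 1] else 0
      j <- which(s[, 1] < t & s[, 2] > t + 1e-15)
      if (length(j)) {
        j <- j[1]
        h <- t - s[j, 1]
        aa <- s[j, 3] + (s[j, 4] - s[j, 3]) * h / (s[j, 2] - s[j, 1])
        acc <- acc + h * (s[j, 3] + aa) / 2
      }
      out[q] <- acc
    }
    out
  }
  refocus_t <- sort(refocus_t)
  k_at <- function(tq) {
    # apply sign flips from refocusing pulses: k(t) picks up a factor (-1)
    # on everything accumulated before each refocus time
    A <- cbind(area_at("x", tq), area_at("y", tq), area_at("z", tq))
    if (length(refocus_t)) {
      Ar <- cbind(area_at("x", refocus_t), area_at("y", refocus_t),
                  area_at("z", refocus_t))
      for (q in seq_along(tq)) {
        nref <- sum(refocus_t <= tq[q])
        if (nref > 0) {
          kk <- c(0, 0, 0); prev <- c(0, 0, 0)
          Aseq <- rbind(Ar[seq_len(nref), , drop = FALSE],
                        A[q, , drop = FALSE])
          for (r in seq_len(nref + 1)) {
            kk <- kk + (Aseq[r, ] - prev)
            prev <- Aseq[r, ]
            if (r <= nref) kk <- -kk
          }
          A[q, ] <- kk
        }
      }
    }
    gamma / (2 * pi) * A
  }
  lapply(adc_t, k_at)
}
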