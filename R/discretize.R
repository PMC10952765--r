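#' Simulation configuration
#'
#' @param dt Maximum time step inside precession intervals when the phantom
#'   moves (s).  For static phantoms the trapezoidal phase integral is exact
#'   on gradient vertices alone and no interior nodes are added.
#' @param dt_rf Maximum time step across nonzero RF (s).
#' @param n_blocks Target number of simulation blocks the node set is
#'   partitioned into (memory/locality knob; the result is invariant to it).
#' @param n_threads Number of disjoint spin chunks whose partial signals are
#'   accumulated separately and summed (the result is invariant to it).
#' @param method Simulation-method tag; `"bloch"` is the built-in
#'   magnetization solver (see [simulation_method()]).
#' @param seed Optional RNG seed recorded with the run.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 1e-3, dt_rf = 1e-5, n_blocks = 20, n_threads = 1,
                       method = "bloch", seed = NULL) {
  if (dt <= 0) stop("dt must be > 0")
  if (dt_rf <= 0) stop("dt_rf must be > 0")
  if (n_blocks < 1) stop("n_blocks must be >= 1")
  if (n_threads < 1) stop("n_threads must be >= 1")
  structure(list(dt = dt, dt_rf = dt_rf, n_blocks = as.integer(n_blocks),
                 n_threads = as.integer(n_threads), method = method,
                 seed = seed),
            class = "sim_config")
}

TIME_MERGE_TOL <- 1e-12

merge_times <- function(t, tol = TIME_MERGE_TOL) {
  t <- sort(t)
  if (length(t) <= 1) return(t)
  keep <- c(TRUE, diff(t) > tol)
  t[keep]
}

# snap values in `t` onto values in `ref` that are within tol, so that ADC
# sample times survive the duplicate merge verbatim
snap_to <- function(t, ref, tol = TIME_MERGE_TOL) {
  if (length(ref) == 0 || length(t) == 0) return(t)
  idx <- findInterval(t, ref)
  for (k in seq_along(t)) {
    for (j in c(idx[k], idx[k] + 1)) {
      if (j >= 1 && j <= length(ref) && abs(t[k] - ref[j]) <= tol) {
        t[k] <- ref[j]
        break
      }
    }
  }
  t
}

refine_gaps <- function(t, dt_max) {
  if (length(t) < 2) return(t)
  out <- lapply(seq_len(length(t) - 1), function(i) {
    gap <- t[i + 1] - t[i]
    if (gap <= dt_max + TIME_MERGE_TOL) return(t[i])
    k <- ceiling(gap / dt_max * (1 - 1e-12))
    t[i] + gap * (0:(k - 1)) / k
  })
  c(unlist(out), t[length(t)])
}

#' Sequence-aware critical time nodes
#'
#' Computes the node times the solver must visit: block boundaries, every
#' gradient vertex, RF raster boundaries (refined to spacing `<= dt_rf`
#' wherever B1 is nonzero), every ADC sample time, and - only when the
#' phantom moves - interior nodes at spacing `<= dt`.  Trapezoidal phase
#' integration over piecewise-linear gradients is exact on this node set for
#' static spins, which is what makes vertex-only stepping sufficient outside
#' RF and ADC windows.
#'
#' @param seq An [mr_sequence()].
#' @param config A [sim_config()].
#' @param has_motion Whether the phantom carries a motion field.
#' @return Sorted numeric vector of node times (s), duplicates merged at
#'   1e-12 s.
#' @export
critical_times <- function(seq, config = sim_config(), has_motion = FALSE) {
  starts <- block_starts(seq)
  adc_times <- numeric(0)
  nodes <- numeric(0)
  for (i in seq_along(seq$blocks)) {
    b <- seq$blocks[[i]]
    t0 <- starts[i]
    for (ev in list(b$rf, b$gx, b$gy, b$gz, b$adc)) {
      if (!is.null(ev) && event_end(ev) > b$duration + 1e-12)
        stop(sprintf("block %d: event extends beyond block duration", i))
    }
    bn <- c(0, b$duration)
    for (g in list(b$gx, b$gy, b$gz)) if (!is.null(g)) bn <- c(bn, g$times)
    if (!is.null(b$rf)) {
      nrf <- length(b$rf$amplitude)
      edges <- b$rf$delay + b$rf$raster * (0:nrf)
      bn <- c(bn, edges)
      # refine bins with nonzero amplitude to spacing <= dt_rf
      for (j in seq_len(nrf)) {
        if (Mod(b$rf$amplitude[j]) == 0) next
        a <- edges[j]; z <- edges[j + 1]
        if (z - a > config$dt_rf + TIME_MERGE_TOL) {
          k <- ceiling((z - a) / config$dt_rf * (1 - 1e-12))
          bn <- c(bn, a + (z - a) * (1:(k - 1)) / k)
        }
      }
    }
    if (!is.null(b$adc)) {
      st <- adc_sample_times(b$adc)
      bn <- c(bn, st)
      adc_times <- c(adc_times, t0 + st)
    }
    nodes <- c(nodes, t0 + bn)
  }
  nodes <- merge_times(snap_to(nodes, sort(adc_times)))
  if (has_motion) nodes <- merge_times(refine_gaps(nodes, config$dt))
  nodes
}

#' Discretize a sequence onto its critical time nodes
#'
#' Samples the complex RF field (piecewise-constant on its raster, carrier
#' applied) and the piecewise-linear gradients at every node, and flags the
#' nodes that are ADC sample times.  `adc_id[k]` numbers the ADC event
#' (in block order) owning node k, 0 elsewhere.
#'
#' @inheritParams critical_times
#' @param scanner A [scanner()]; used for gradient amplitude validation.
#' @return An object of class `discrete_seq` with fields `t`, `dt`, `B1`,
#'   `Gx`, `Gy`, `Gz`, `adc` (logical), `adc_id` (integer).
#' @export
discretize <- function(seq, config = sim_config(), scanner = NULL,
                       has_motion = FALSE) {
  t <- critical_times(seq, config, has_motion)
  n <- length(t)
  starts <- block_starts(seq)
  ends <- starts + vapply(seq$blocks, `[[`, 0, "duration")
  B1 <- complex(real = numeric(n))
  Gx <- numeric(n); Gy <- numeric(n); Gz <- numeric(n)
  adc_id <- integer(n)
  eid <- 0L
  for (i in seq_along(seq$blocks)) {
    b <- seq$blocks[[i]]
    # nodes inside this block; boundary nodes belong to both, events are
    # local so sampling either way is identical (fields are 0 at block ends)
    in_blk <- which(t >= starts[i] - TIME_MERGE_TOL &
                    t <= ends[i] + TIME_MERGE_TOL)
    tl <- t[in_blk] - starts[i]
    if (!is.null(b$rf)) B1[in_blk] <- B1[in_blk] + rf_field_at(b$rf, tl)
    if (!is.null(b$gx)) Gx[in_blk] <- Gx[in_blk] + grad_field_at(b$gx, tl)
    if (!is.null(b$gy)) Gy[in_blk] <- Gy[in_blk] + grad_field_at(b$gy, tl)
    if (!is.null(b$gz)) Gz[in_blk] <- Gz[in_blk] + grad_field_at(b$gz, tl)
    if (!is.null(b$adc)) {
      eid <- eid + 1L
      st <- starts[i] + adc_sample_times(b$adc)
      idx <- match_times(st, t)
      if (anyNA(idx)) stop("internal error: ADC sample time missing from nodes")
      adc_id[idx] <- eid
    }
  }
  if (!is.null(scanner)) {
    gm <- max(abs(c(Gx, Gy, Gz)))
    if (gm > scanner$Gmax * (1 + 1e-9))
      stop(sprintf("gradient amplitude %.4g T/m exceeds Gmax = %.4g T/m",
                   gm, scanner$Gmax))
  }
  structure(list(t = t, dt = diff(t), B1 = B1, Gx = Gx, Gy = Gy, Gz = Gz,
                 adc = adc_id > 0L, adc_id = adc_id),
            class = "discrete_seq")
}

match_times <- function(x, table, tol = 10 * TIME_MERGE_TOL) {
  idx <- findInterval(x, table)
  out <- rep(NA_integer_, length(x))
  for (k in seq_along(x)) {
    best <- NA_integer_; bestd <- tol
    for (j in c(idx[k], idx[k] + 1)) {
      if (j >= 1 && j <= length(table)) {
        d <- abs(x[k] - table[j])
        if (d <= bestd) { best <- j; bestd <- d }
      }
    }
    out[k] <- best
  }
  out
}

#' Partition discrete-sequence steps into simulation blocks
#'
#' Splits the `n-1` steps between nodes into `n_blocks` contiguous spans of
#' approximately equal size.  A span is tagged `"excitation"` if any of its
#' steps has nonzero B1 at its left node, else `"precession"`.  Boundaries
#' are shifted forward so that a contiguous nonzero-B1 run (an RF pulse) or
#' the sample run of a single ADC event is never split across blocks.
#'
#' @param dseq A [discretize()] result.
#' @param config A [sim_config()].
#' @return List of blocks, each `list(from, to, regime)` where `from:to`
#'   index steps (step k spans nodes k to k+1).
#' @export
partition_blocks <- function(dseq, config = sim_config()) {
  nstep <- length(dseq$dt)
  if (nstep == 0) return(list())
  nb <- min(config$n_blocks, nstep)
  if (config$n_blocks > nstep)
    warning("n_blocks exceeds step count; clamped to ", nstep)
  # a step may not be separated from its predecessor when both belong to the
  # same RF run or the same ADC event's sample run
  b1 <- Mod(dseq$B1[seq_len(nstep)]) > 0
  glue <- rep(FALSE, nstep)   # glue[k]: no boundary between steps k-1 and k
  if (nstep > 1) {
    for (k in 2:nstep) {
      if (b1[k] && b1[k - 1]) glue[k] <- TRUE
      # nodes k and k-1 are interior samples of the same ADC event
      if (dseq$adc_id[k] > 0 && dseq$adc_id[k] == dseq$adc_id[k - 1])
        glue[k] <- TRUE
    }
  }
  targets <- round(seq(0, nstep, length.out = nb + 1))
  bounds <- 0
  for (i in 2:(nb + 1)) {
    cut <- targets[i]
    while (cut < nstep && cut >= 1 && glue[cut + 1]) cut <- cut + 1
    if (cut > bounds[length(bounds)]) bounds <- c(bounds, cut)
  }
  if (bounds[length(bounds)] < nstep) bounds <- c(bounds, nstep)
  blocks <- vector("list", length(bounds) - 1)
  for (i in seq_along(blocks)) {
    from <- bounds[i] + 1; to <- bounds[i + 1]
    regime <- if (any(b1[from:to])) "excitation" else "precession"
    blocks[[i]] <- list(from = from, to = to, regime = regime)
  }
  blocks
}
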