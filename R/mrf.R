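#' Simulate a fingerprinting dictionary
#'
#' For every (T1, T2) pair on the grid a single on-resonance isochromat is
#' driven through the fingerprinting train's RF/TR/TE/TI schedule:
#' instantaneous rotations with the scheduled flip and alternating 0/pi
#' phase (bSSFP phase cycling), relaxation to TE where the demodulated
#' transverse magnetization is recorded, then relaxation over the TR
#' remainder.  Gradients are ignored (they are balanced within every TR),
#' standard single-isochromat dictionary practice.  Fingerprints are
#' L2-normalized.
#'
#' @param t1_grid,t2_grid T1/T2 grids (s); the defaults are 300-2500 ms
#'   every 10 ms and 40-350 ms every 4 ms.
#' @param schedule An [mrf_schedule()].
#' @param exclude_t2_gt_t1 Drop atoms with T2 > T1 (default keeps all).
#' @return An object of class `mrf_dictionary`: `entries` (data.frame T1,
#'   T2 in s) and `fingerprints` (atoms x TRs complex matrix, unit rows).
#' @export
build_dictionary <- function(t1_grid = seq(0.3, 2.5, by = 0.01),
                             t2_grid = seq(0.04, 0.35, by = 0.004),
                             schedule, exclude_t2_gt_t1 = FALSE) {
  if (!length(t1_grid) || !length(t2_grid)) stop("grids must be nonempty")
  entries <- expand.grid(T1 = t1_grid, T2 = t2_grid)
  if (exclude_t2_gt_t1) entries <- entries[entries$T2 <= entries$T1, ]
  F <- fingerprint_signals(entries$T1, entries$T2, schedule)
  nrm <- sqrt(rowSums(Mod(F)^2))
  nrm[nrm == 0] <- 1
  structure(list(entries = entries, fingerprints = F / nrm,
                 schedule = schedule),
            class = "mrf_dictionary")
}

#' @export
print.mrf_dictionary <- function(x, ...) {
  cat(sprintf("<mrf_dictionary> %d atoms x %d TRs (T1 %g-%g ms, T2 %g-%g ms)\n",
              nrow(x$entries), ncol(x$fingerprints),
              min(x$entries$T1) * 1e3, max(x$entries$T1) * 1e3,
              min(x$entries$T2) * 1e3, max(x$entries$T2) * 1e3))
  invisible(x)
}

#' Per-isochromat fingerprint signals (unnormalized)
#'
#' The raw complex signal at each TE for isochromats with the given
#' relaxation times under an [mrf_schedule()]; used both to build the
#' dictionary and to synthesize noiseless per-pixel series.
#'
#' @param T1,T2 Vectors of relaxation times (s), equal length.
#' @param schedule An [mrf_schedule()].
#' @param M0 Proton density (scalar or per-isochromat).
#' @param inversion Apply the initial 180 and TI recovery (default TRUE).
#' @param phase_cycle Alternate the RF phase 0/pi per TR (default TRUE).
#' @return Complex matrix, isochromats x TRs.
#' @export
fingerprint_signals <- function(T1, T2, schedule, M0 = 1, inversion = TRUE,
                                phase_cycle = TRUE) {
  n <- length(T1)
  stopifnot(length(T2) == n)
  M0 <- rep_len(M0, n)
  ntr <- length(schedule$TRs)
  m <- mag(complex(real = rep(0, n)), M0)
  if (inversion) {
    m <- apply_spinor(spinor(0 + 0i, -1i), m)   # pi about x
    m <- relax(m, schedule$TI, T1, T2, M0)
  }
  F <- matrix(0 + 0i, n, ntr)
  for (k in seq_len(ntr)) {
    f <- schedule$flip_angles[k]
    phk <- if (phase_cycle) pi * ((k - 1) %% 2) else 0
    s <- spinor(complex(real = cos(f / 2)),
                1i * exp(1i * phk) * sin(f / 2))
    m <- apply_spinor(s, m)
    m <- relax(m, schedule$TE, T1, T2, M0)
    F[, k] <- m$xy * exp(-1i * phk)
    m <- relax(m, schedule$TRs[k] - schedule$TE, T1, T2, M0)
  }
  F
}

#' Dictionary matching by maximum dot product
#'
#' Per pixel, picks the atom maximizing the magnitude of the complex inner
#' product `|<signal, atom>|` (phase- and scale-invariant); ties break to
#' the lowest atom index.  Pixels whose first-frame magnitude falls below
#' `mask_threshold` times the maximum are masked (NA maps).
#'
#' @param signals Complex matrix, pixels x TRs (a single series may be a
#'   vector).
#' @param dict An [build_dictionary()] result.
#' @param mask_threshold Relative first-frame magnitude cutoff (0 disables).
#' @return `list(T1, T2, index, score)`, each of length npixels (s units).
#' @export
match_fingerprints <- function(signals, dict, mask_threshold = 0.05) {
  if (is.null(dim(signals))) signals <- matrix(signals, nrow = 1)
  if (ncol(signals) != ncol(dict$fingerprints))
    stop("series length does not match fingerprint length")
  keep <- rep(TRUE, nrow(signals))
  if (mask_threshold > 0) {
    a1 <- Mod(signals[, 1])
    keep <- a1 >= mask_threshold * max(a1)
  }
  T1 <- T2 <- score <- rep(NA_real_, nrow(signals))
  index <- rep(NA_integer_, nrow(signals))
  if (any(keep)) {
    sc <- Mod(signals[keep, , drop = FALSE] %*% Conj(t(dict$fingerprints)))
    idx <- max.col(sc, ties.method = "first")
    index[keep] <- idx
    T1[keep] <- dict$entries$T1[idx]
    T2[keep] <- dict$entries$T2[idx]
    score[keep] <- sc[cbind(seq_len(nrow(sc)), idx)]
  }
  list(T1 = T1, T2 = T2, index = index, score = score)
}
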