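#' Decompress a Pulseq shape stream
#'
#' Pulseq stores waveform shapes as a run-length-encoded derivative: a value
#' occurring twice in a row is followed by the count of additional repeats
#' (so `v v c` expands to `c + 2` copies of `v`), and the expanded stream is
#' the sample-to-sample derivative, reconstructed by a cumulative sum.
#'
#' @param stream Numeric vector as stored in the `[SHAPES]` section.
#' @param num_samples Expected sample count; a mismatch after expansion is a
#'   corrupt-shape error.
#' @return Numeric vector of `num_samples` decompressed samples.
#' @examples
#' decompress_shape(c(0.01, 0.01, 98), 100)  # linear ramp 0.01..1
#' @export
decompress_shape <- function(stream, num_samples) {
  out <- numeric(0)
  i <- 1; n <- length(stream)
  while (i <= n) {
    if (i + 1 <= n && stream[i + 1] == stream[i]) {
      if (i + 2 > n) stop("corrupt shape: run without repeat count")
      cnt <- stream[i + 2]
      if (cnt < 0 || cnt != round(cnt))
        stop("corrupt shape: invalid repeat count")
      out <- c(out, rep(stream[i], 2 + cnt))
      i <- i + 3
    } else {
      out <- c(out, stream[i])
      i <- i + 1
    }
  }
  if (length(out) != num_samples)
    stop(sprintf("corrupt shape: expanded to %d samples, expected %d",
                 length(out), num_samples))
  cumsum(out)
}

# inverse of decompress_shape: derivative, then run-length encoding
compress_shape <- function(samples) {
  d <- c(samples[1], diff(samples))
  out <- numeric(0)
  i <- 1; n <- length(d)
  while (i <= n) {
    j <- i
    while (j < n && d[j + 1] == d[i]) j <- j + 1
    len <- j - i + 1
    if (len == 1) out <- c(out, d[i])
    else out <- c(out, d[i], d[i], len - 2)
    i <- j + 1
  }
  out
}

PULSEQ_RF_RASTER <- 1e-6
PULSEQ_GRAD_RASTER <- 1e-5
PULSEQ_BLOCK_RASTER <- 1e-7

fmt_num <- function(x) formatC(x, digits = 10, format = "g", width = -1)

#' Write a sequence to a Pulseq v1.4 file
#'
#' Emits the v1.4 subset used by this package: `[VERSION]`,
#' `[DEFINITIONS]` (rasters, FOV, Name), `[BLOCKS]`, `[RF]` (envelopes
#' resampled to the 1 us RF raster, magnitude/phase shape pair), `[TRAP]`
#' for trapezoid/triangle gradients, `[GRADIENTS]` for arbitrary waveforms
#' (sampled at gradient-raster centers), `[ADC]` and `[SHAPES]`.  RF and
#' gradient amplitudes are stored in Hz and Hz/m (`gamma/2pi` times the
#' Tesla value), per the format convention.
#'
#' @param seq An [mr_sequence()].
#' @param path Output path.
#' @param scanner A [scanner()]; its `gamma` fixes the Hz conversions.
#' @return `path`, invisibly.
#' @export
write_pulseq <- function(seq, path, scanner = default_scanner()) {
  g2p <- scanner$gamma / (2 * pi)
  shapes <- list(); shape_keys <- character(0)
  add_shape <- function(samples) {
    key <- paste(formatC(samples, digits = 12, format = "g"), collapse = ",")
    hit <- match(key, shape_keys)
    if (!is.na(hit)) return(hit)
    shapes[[length(shapes) + 1]] <<- samples
    shape_keys <<- c(shape_keys, key)
    length(shapes)
  }
  rf_rows <- list(); rf_keys <- character(0)
  trap_rows <- list(); trap_keys <- character(0)
  grad_rows <- list(); grad_keys <- character(0)
  adc_rows <- list(); adc_keys <- character(0)
  rf_id <- function(rf) {
    nbin <- as.integer(round((length(rf$amplitude) * rf$raster) /
                               PULSEQ_RF_RASTER))
    tt <- (seq_len(nbin) - 0.5) * PULSEQ_RF_RASTER
    env_c <- rf_field_at(rf_event(rf$amplitude, rf$raster), tt)
    peak <- max(Mod(env_c))
    mag <- if (peak > 0) Mod(env_c) / peak else Mod(env_c)
    ph <- (Arg(env_c) / (2 * pi)) %% 1
    ph[mag == 0] <- 0
    key <- paste(formatC(c(peak, mag, ph, rf$delay, rf$freq_offset,
                           rf$phase_offset), digits = 12,
                         format = "g"), collapse = ",")
    hit <- match(key, rf_keys)
    if (!is.na(hit)) return(hit)
    mid <- add_shape(mag); pid <- add_shape(ph)
    rf_rows[[length(rf_rows) + 1]] <<- c(
      amp = peak * g2p, mag_id = mid, phase_id = pid, time_id = 0,
      delay = round(rf$delay * 1e6, 6), freq = rf$freq_offset / (2 * pi),
      phase = rf$phase_offset)
    rf_keys <<- c(rf_keys, key)
    length(rf_rows)
  }
  is_trap <- function(g) {
    n <- length(g$times)
    if (n == 4 && g$amplitudes[1] == 0 && g$amplitudes[4] == 0 &&
        g$amplitudes[2] == g$amplitudes[3]) return("trap")
    if (n == 3 && g$amplitudes[1] == 0 && g$amplitudes[3] == 0) return("tri")
    NA_character_
  }
  grad_id <- function(g) {
    kind <- is_trap(g)
    key <- paste(formatC(c(g$times, g$amplitudes), digits = 12, format = "g"),
                 collapse = ",")
    if (!is.na(kind)) {
      hit <- match(key, trap_keys)
      if (!is.na(hit)) return(c(hit, 1))
      if (kind == "trap") {
        row <- c(amp = g$amplitudes[2] * g2p,
                 rise = (g$times[2] - g$times[1]) * 1e6,
                 flat = (g$times[3] - g$times[2]) * 1e6,
                 fall = (g$times[4] - g$times[3]) * 1e6,
                 delay = g$times[1] * 1e6)
      } else {
        row <- c(amp = g$amplitudes[2] * g2p,
                 rise = (g$times[2] - g$times[1]) * 1e6, flat = 0,
                 fall = (g$times[3] - g$times[2]) * 1e6,
                 delay = g$times[1] * 1e6)
      }
      trap_rows[[length(trap_rows) + 1]] <<- row
      trap_keys <<- c(trap_keys, key)
      return(c(length(trap_rows), 1))
    }
    hit <- match(key, grad_keys)
    if (!is.na(hit)) return(c(hit, 2))
    t0 <- g$times[1]; t1 <- g$times[length(g$times)]
    nb <- max(1L, as.integer(ceiling(round((t1 - t0) / PULSEQ_GRAD_RASTER, 9))))
    tc <- t0 + (seq_len(nb) - 0.5) * PULSEQ_GRAD_RASTER
    vals <- grad_field_at(g, pmin(tc, t1))
    peak <- max(abs(vals))
    sh <- if (peak > 0) vals / peak else vals
    sid <- add_shape(sh)
    grad_rows[[length(grad_rows) + 1]] <<- c(
      amp = peak * g2p, shape_id = sid, time_id = 0, delay = t0 * 1e6)
    grad_keys <<- c(grad_keys, key)
    c(length(grad_rows), 2)
  }
  adc_id_of <- function(a) {
    key <- paste(a$num_samples, formatC(c(a$dwell, a$delay, a$phase),
                                        digits = 12, format = "g"),
                 collapse = ",")
    hit <- match(key, adc_keys)
    if (!is.na(hit)) return(hit)
    adc_rows[[length(adc_rows) + 1]] <<- c(
      num = a$num_samples, dwell = a$dwell * 1e9,
      delay = a$delay * 1e6, freq = 0, phase = a$phase)
    adc_keys <<- c(adc_keys, key)
    length(adc_rows)
  }
  blocks_tab <- matrix(0, length(seq$blocks), 8)
  grad_kind <- matrix(0L, length(seq$blocks), 3)  # 1 trap, 2 arbitrary
  for (i in seq_along(seq$blocks)) {
    b <- seq$blocks[[i]]
    blocks_tab[i, 1] <- i
    blocks_tab[i, 2] <- round(b$duration / PULSEQ_BLOCK_RASTER)
    if (!is.null(b$rf)) blocks_tab[i, 3] <- rf_id(b$rf)
    for (ax in 1:3) {
      g <- b[[c("gx", "gy", "gz")[ax]]]
      if (!is.null(g)) {
        gi <- grad_id(g)
        blocks_tab[i, 3 + ax] <- gi[1]
        grad_kind[i, ax] <- gi[2]
      }
    }
    if (!is.null(b$adc)) blocks_tab[i, 7] <- adc_id_of(b$adc)
  }
  # ids must be unique across [TRAP] and [GRADIENTS]; offset arbitrary ones
  ntrap <- length(trap_rows)
  for (i in seq_len(nrow(blocks_tab)))
    for (ax in 1:3)
      if (grad_kind[i, ax] == 2L)
        blocks_tab[i, 3 + ax] <- blocks_tab[i, 3 + ax] + ntrap
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# Pulseq sequence file")
  w("[VERSION]"); w("major 1"); w("minor 4"); w("revision 0"); w("")
  w("[DEFINITIONS]")
  w("AdcRasterTime 1e-07")
  w("BlockDurationRaster %s", fmt_num(PULSEQ_BLOCK_RASTER))
  w("GradientRasterTime %s", fmt_num(PULSEQ_GRAD_RASTER))
  w("RadiofrequencyRasterTime %s", fmt_num(PULSEQ_RF_RASTER))
  if (!is.null(seq$fov)) w("FOV %s %s 0.003", fmt_num(seq$fov[1]),
                           fmt_num(seq$fov[2]))
  w("Name %s", seq$name); w("")
  w("[BLOCKS]")
  for (i in seq_len(nrow(blocks_tab)))
    w("%d %d %d %d %d %d %d %d", blocks_tab[i, 1], blocks_tab[i, 2],
      blocks_tab[i, 3], blocks_tab[i, 4], blocks_tab[i, 5], blocks_tab[i, 6],
      blocks_tab[i, 7], blocks_tab[i, 8])
  w("")
  if (length(rf_rows)) {
    w("[RF]")
    for (i in seq_along(rf_rows)) {
      r <- rf_rows[[i]]
      w("%d %s %d %d %d %s %s %s", i, fmt_num(r[["amp"]]), r[["mag_id"]],
        r[["phase_id"]], r[["time_id"]], fmt_num(r[["delay"]]),
        fmt_num(r[["freq"]]), fmt_num(r[["phase"]]))
    }
    w("")
  }
  if (length(grad_rows)) {
    w("[GRADIENTS]")
    for (i in seq_along(grad_rows)) {
      r <- grad_rows[[i]]
      w("%d %s %d %d %s", i + ntrap, fmt_num(r[["amp"]]), r[["shape_id"]],
        r[["time_id"]], fmt_num(r[["delay"]]))
    }
    w("")
  }
  if (length(trap_rows)) {
    w("[TRAP]")
    for (i in seq_along(trap_rows)) {
      r <- trap_rows[[i]]
      w("%d %s %s %s %s %s", i, fmt_num(r[["amp"]]), fmt_num(r[["rise"]]),
        fmt_num(r[["flat"]]), fmt_num(r[["fall"]]), fmt_num(r[["delay"]]))
    }
    w("")
  }
  if (length(adc_rows)) {
    w("[ADC]")
    for (i in seq_along(adc_rows)) {
      r <- adc_rows[[i]]
      w("%d %d %s %s %s %s", i, as.integer(r[["num"]]), fmt_num(r[["dwell"]]),
        fmt_num(r[["delay"]]), fmt_num(r[["freq"]]), fmt_num(r[["phase"]]))
    }
    w("")
  }
  if (length(shapes)) {
    w("[SHAPES]")
    for (i in seq_along(shapes)) {
      w("shape_id %d", i)
      w("num_samples %d", length(shapes[[i]]))
      # full precision: the codec's run detection relies on printed values
      # being equal exactly when the doubles are
      comp <- compress_shape(shapes[[i]])
      writeLines(sprintf("%.17g", comp), con)
      w("")
    }
  }
  invisible(path)
}

#' Read a Pulseq file into a sequence
#'
#' Parses the v1.4 subset written by [write_pulseq()] and is tolerant of
#' v1.2/1.3 files (legacy delay column in `[BLOCKS]` plus a `[DELAYS]`
#' section).  Hz-based RF and gradient amplitudes are converted to Tesla
#' units through the scanner's `gamma`; trapezoids become 4-vertex (or
#' 3-vertex, when the flat top is empty) gradient events; arbitrary
#' gradient shapes become piecewise-linear vertices at gradient-raster
#' centers.  `[EXTENSIONS]` sections are skipped with a warning.
#'
#' @param path Path to a `.seq` file.
#' @param scanner A [scanner()].
#' @return An [mr_sequence()].
#' @export
read_pulseq <- function(path, scanner = default_scanner()) {
  if (!file.exists(path)) stop("no such file: ", path)
  g2p <- scanner$gamma / (2 * pi)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines)
  sec_at <- grep("^\\[.*\\]$", lines)
  if (!length(sec_at)) stop("not a Pulseq file: no sections found")
  sections <- list()
  for (i in seq_along(sec_at)) {
    nm <- gsub("\\[|\\]", "", lines[sec_at[i]])
    to <- if (i < length(sec_at)) sec_at[i + 1] - 1 else length(lines)
    body <- lines[(sec_at[i] + 1):to]
    sections[[toupper(nm)]] <- body[nzchar(body)]
  }
  need <- function(nm) {
    if (is.null(sections[[nm]]))
      stop("missing required Pulseq section: [", nm, "]")
    sections[[nm]]
  }
  ver <- need("VERSION")
  getv <- function(key) {
    ln <- grep(paste0("^", key, "\\b"), ver, value = TRUE)
    as.numeric(strsplit(ln[1], "\\s+")[[1]][2])
  }
  major <- getv("major"); minor <- getv("minor")
  if (is.na(major) || is.na(minor)) stop("unreadable [VERSION] section")
  if (major > 1 || (major == 1 && minor > 4))
    stop(sprintf("unsupported Pulseq version %d.%d (supported: <= 1.4)",
                 major, minor))
  legacy <- minor < 4
  defs <- sections[["DEFINITIONS"]]
  def_val <- function(key, default) {
    if (is.null(defs)) return(default)
    ln <- grep(paste0("^", key, "\\b"), defs, value = TRUE)
    if (!length(ln)) return(default)
    as.numeric(strsplit(ln[1], "\\s+")[[1]][2])
  }
  def_str <- function(key, default) {
    if (is.null(defs)) return(default)
    ln <- grep(paste0("^", key, "\\b"), defs, value = TRUE)
    if (!length(ln)) return(default)
    strsplit(ln[1], "\\s+")[[1]][2]
  }
  bdr <- def_val("BlockDurationRaster", 1e-5)
  rf_raster <- def_val("RadiofrequencyRasterTime", 1e-6)
  grad_raster <- def_val("GradientRasterTime", 1e-5)
  fov1 <- def_val("FOV", NA)
  name <- def_str("Name", sub("\\.seq$", "", basename(path)))
  if (!is.null(sections[["EXTENSIONS"]]))
    warning("Pulseq [EXTENSIONS] section is not supported; skipping")
  parse_rows <- function(body) {
    if (is.null(body) || !length(body)) return(NULL)
    do.call(rbind, lapply(body, function(l)
      as.numeric(strsplit(l, "\\s+")[[1]])))
  }
  shapes <- list()
  sh <- sections[["SHAPES"]]
  if (!is.null(sh)) {
    ids <- grep("^shape_id", sh)
    for (i in seq_along(ids)) {
      sid <- as.integer(strsplit(sh[ids[i]], "\\s+")[[1]][2])
      to <- if (i < length(ids)) ids[i + 1] - 1 else length(sh)
      body <- sh[(ids[i] + 1):to]
      ns_ln <- grep("^num_samples", body, value = TRUE)
      ns <- as.integer(strsplit(ns_ln[1], "\\s+")[[1]][2])
      dat <- as.numeric(body[!grepl("^num_samples", body)])
      shapes[[sid]] <- decompress_shape(dat, ns)
    }
  }
  rf_tab <- parse_rows(sections[["RF"]])
  trap_tab <- parse_rows(sections[["TRAP"]])
  grad_tab <- parse_rows(sections[["GRADIENTS"]])
  adc_tab <- parse_rows(sections[["ADC"]])
  delay_tab <- if (legacy) parse_rows(sections[["DELAYS"]]) else NULL
  row_of <- function(tab, id) {
    r <- which(tab[, 1] == id)
    if (!length(r)) stop("Pulseq file references undefined event id ", id)
    tab[r[1], ]
  }
  make_rf <- function(id) {
    r <- row_of(rf_tab, id)
    mag <- shapes[[r[3]]]; ph <- shapes[[r[4]]]
    amp_t <- r[2] / g2p
    rf_event(amp_t * mag * exp(2i * pi * ph), raster = rf_raster,
             delay = r[6] * 1e-6, freq_offset = 2 * pi * r[7],
             phase_offset = r[8])
  }
  make_grad <- function(id, axis) {
    if (!is.null(trap_tab) && any(trap_tab[, 1] == id)) {
      r <- row_of(trap_tab, id)
      amp <- r[2] / g2p
      rise <- r[3] * 1e-6; flat <- r[4] * 1e-6; fall <- r[5] * 1e-6
      d <- r[6] * 1e-6
      if (flat > 0)
        grad_event(d + c(0, rise, rise + flat, rise + flat + fall),
                   c(0, amp, amp, 0), axis)
      else
        grad_event(d + c(0, rise, rise + fall), c(0, amp, 0), axis)
    } else {
      r <- row_of(grad_tab, id)
      sh <- shapes[[r[3]]]
      amp <- r[2] / g2p
      d <- r[5] * 1e-6
      nb <- length(sh)
      # samples at raster centers, linearly connected, held to the bin edges
      tc <- d + c(0, (seq_len(nb) - 0.5) * grad_raster, nb * grad_raster)
      vals <- amp * c(sh[1], sh, sh[nb])
      grad_event(tc, vals, axis)
    }
  }
  make_adc <- function(id) {
    r <- row_of(adc_tab, id)
    adc_event(r[2], r[3] * 1e-9, r[4] * 1e-6, r[6])
  }
  blk_tab <- parse_rows(need("BLOCKS"))
  blocks <- vector("list", nrow(blk_tab))
  for (i in seq_len(nrow(blk_tab))) {
    r <- blk_tab[i, ]
    if (legacy) {
      # columns: id delay rf gx gy gz adc [ext]
      dly <- if (r[2] > 0 && !is.null(delay_tab))
        row_of(delay_tab, r[2])[2] * 1e-6 else 0
      ids <- r[3:7]; dur <- NA
    } else {
      dur <- r[2] * bdr
      ids <- r[3:7]
      dly <- 0
    }
    rf <- if (ids[1] > 0) make_rf(ids[1]) else NULL
    gx <- if (ids[2] > 0) make_grad(ids[2], "x") else NULL
    gy <- if (ids[3] > 0) make_grad(ids[3], "y") else NULL
    gz <- if (ids[4] > 0) make_grad(ids[4], "z") else NULL
    adc <- if (ids[5] > 0) make_adc(ids[5]) else NULL
    ends <- max(event_end(rf), event_end(gx), event_end(gy), event_end(gz),
                event_end(adc))
    if (is.na(dur)) dur <- max(ends, dly)
    blocks[[i]] <- seq_block(rf = rf, gx = gx, gy = gy, gz = gz, adc = adc,
                             duration = max(dur, ends))
  }
  mr_sequence(blocks, name = name,
              fov = if (is.na(fov1)) NULL else {
                parts <- as.numeric(strsplit(
                  grep("^FOV\\b", defs, value = TRUE)[1], "\\s+")[[1]][-1])
                parts[1:2]
              })
}
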