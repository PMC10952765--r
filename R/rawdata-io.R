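#' Write raw data to an ISMRMRD-flavored HDF5 profile
#'
#' A simplified self-describing layout rather than the full standard
#' header schema (the field names map 1:1, so converting to strict ISMRMRD
#' is a thin adapter): group `/header` with attributes `fov` (m),
#' `matrix_size`, `name` and the simulation-parameter snapshot
#' (`sim_*` attributes); one group `/acq{i}` (0-based, readout order) per
#' readout holding `data` (N x 2 real/imaginary pairs), `t` (s) and
#' optionally `traj` (N x 3, 1/m).
#'
#' @param raw A [raw_data()].
#' @param path Output path (overwritten).
#' @return `path`, invisibly.
#' @export
write_rawdata <- function(raw, path) {
  if (file.exists(path)) unlink(path)
  if (!rhdf5::h5createFile(path)) stop("cannot create file: ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createGroup(path, "header")
  fid <- rhdf5::H5Fopen(path)
  gid <- rhdf5::H5Gopen(fid, "header")
  h <- raw$header
  if (!is.null(h$fov)) rhdf5::h5writeAttribute(h$fov, gid, "fov")
  if (!is.null(h$matrix_size))
    rhdf5::h5writeAttribute(as.integer(h$matrix_size), gid, "matrix_size")
  rhdf5::h5writeAttribute(if (is.null(h$name)) "sim" else h$name, gid, "name")
  rhdf5::h5writeAttribute(length(raw$readouts), gid, "n_readouts")
  for (nm in names(h$sim_params)) {
    v <- h$sim_params[[nm]]
    if (is.numeric(v) || is.character(v) || is.logical(v))
      rhdf5::h5writeAttribute(v, gid, paste0("sim_", nm))
  }
  rhdf5::H5Gclose(gid)
  rhdf5::H5Fclose(fid)
  for (i in seq_along(raw$readouts)) {
    r <- raw$readouts[[i]]
    grp <- sprintf("acq%d", i - 1)
    rhdf5::h5createGroup(path, grp)
    rhdf5::h5write(cbind(Re(r$data), Im(r$data)), path,
                   paste0(grp, "/data"))
    rhdf5::h5write(r$t, path, paste0(grp, "/t"))
    if (!is.null(r$traj)) rhdf5::h5write(r$traj, path, paste0(grp, "/traj"))
  }
  invisible(path)
}

#' Read raw data from the HDF5 profile
#'
#' @param path Path written by [write_rawdata()] (or any file following the
#'   documented layout).
#' @return A [raw_data()].
#' @export
read_rawdata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls <- rhdf5::h5ls(path)
  if (!any(ls$name == "header" & ls$group == "/"))
    stop("malformed raw-data file: missing /header")
  atts <- rhdf5::h5readAttributes(path, "header")
  att <- function(nm) if (is.null(atts[[nm]])) NULL else as.vector(atts[[nm]])
  hdr <- list(fov = as.numeric(att("fov")),
              matrix_size = as.integer(att("matrix_size")),
              name = as.character(att("name")))
  nr <- as.integer(att("n_readouts"))
  hdr$sim_params <- lapply(atts[grep("^sim_", names(atts))], as.vector)
  names(hdr$sim_params) <- sub("^sim_", "", names(hdr$sim_params))
  if (length(hdr$fov) == 0) hdr["fov"] <- list(NULL)
  if (length(hdr$matrix_size) == 0) hdr["matrix_size"] <- list(NULL)
  readouts <- lapply(seq_len(nr), function(i) {
    grp <- sprintf("/acq%d", i - 1)
    if (!any(ls$group == grp & ls$name == "data"))
      stop("malformed raw-data file: missing ", grp, "/data")
    dm <- rhdf5::h5read(path, paste0(grp, "/data"))
    tt <- as.numeric(rhdf5::h5read(path, paste0(grp, "/t")))
    traj <- if (any(ls$group == grp & ls$name == "traj"))
      rhdf5::h5read(path, paste0(grp, "/traj")) else NULL
    list(t = tt, data = complex(real = dm[, 1], imaginary = dm[, 2]),
         traj = traj)
  })
  raw_data(readouts, hdr)
}
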