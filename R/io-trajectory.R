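#' Read a coordinate trajectory against a known topology
#'
#' Supported dialects: `"dcd"` (binary, read through `bio3d::read.dcd`) and
#' `"gro"` (concatenated GRO frames, plain text). XTC is not supported;
#' convert to DCD or GRO upstream. Times are taken from the file where the
#' dialect stores them (GRO `t=` tags, DCD header timestep) and may be
#' overridden with `dt_ns`. With `apply_time_scale` the stored times are
#' multiplied by 4, the conventional mapping from coarse-grained simulation
#' time to effective (real) time.
#'
#' @param topology A [droplet_topology()] describing the beads.
#' @param path Path to the trajectory file.
#' @param dialect `"dcd"` or `"gro"`.
#' @param apply_time_scale Multiply times by 4 on ingest (default `FALSE`).
#' @param dt_ns Optional frame interval override (ns, before scaling).
#' @return A [droplet_trajectory()].
#' @export
read_trajectory <- function(topology, path, dialect = c("dcd", "gro", "xtc"),
                            apply_time_scale = FALSE, dt_ns = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "xtc") {
    abort("XTC is not supported (no reader available); convert to DCD or GRO")
  }
  assert_that(file.exists(path), paste("file not found:", path))
  raw <- switch(dialect,
    gro = read_gro_frames(path),
    dcd = read_dcd_frames(path)
  )
  nb <- dim(raw$coords)[2]
  if (nb != nrow(topology)) {
    abort(sprintf("bead-count mismatch: topology has %d beads, trajectory frames have %d",
                  nrow(topology), nb))
  }
  times <- raw$times_ns
  if (!is.null(dt_ns)) times <- (seq_len(dim(raw$coords)[1]) - 1) * dt_ns
  if (is.null(times)) times <- seq_len(dim(raw$coords)[1]) - 1
  if (apply_time_scale) times <- times * 4
  droplet_trajectory(topology, raw$coords, times_ns = times,
                     time_scale_applied = apply_time_scale)
}

read_gro_frames <- function(path) {
  lines <- readLines(path)
  frames <- list()
  times <- numeric()
  offset <- 0L
  while (offset < length(lines)) {
    if (all(trimws(lines[(offset + 1L):length(lines)]) == "")) break
    blk <- parse_gro_block(lines, offset)
    frames[[length(frames) + 1L]] <- blk$coords
    times <- c(times, blk$time_ns %||% NA_real_)
    offset <- offset + blk$n_lines
  }
  nb <- nrow(frames[[1]])
  coords <- array(NA_real_, dim = c(length(frames), nb, 3L))
  for (f in seq_along(frames)) {
    assert_that(nrow(frames[[f]]) == nb, "inconsistent bead count across GRO frames")
    coords[f, , ] <- frames[[f]]
  }
  if (anyNA(times)) times <- NULL
  list(coords = coords, times_ns = times)
}

read_dcd_frames <- function(path) {
  xyz <- bio3d::read.dcd(path, verbose = FALSE)  # frames x 3N, Angstrom
  nf <- nrow(xyz)
  nb <- ncol(xyz) / 3L
  coords <- array(NA_real_, dim = c(nf, nb, 3L))
  for (f in seq_len(nf)) {
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE) / 10
  }
  hdr <- read_dcd_header(path)
  times <- if (!is.null(hdr)) (seq_len(nf) - 1) * hdr$dt_ps * hdr$nsavc / 1000 else NULL
  list(coords = coords, times_ns = times)
}

# Minimal DCD header read: frame interval = delta (ps) * nsavc.
read_dcd_header <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  for (endian in c("little", "big")) {
    seek(con, 0)
    m <- readBin(con, "integer", 1, size = 4, endian = endian)
    if (length(m) == 1 && !is.na(m) && m == 84L) {
      readChar(con, 4)
      icntrl <- readBin(con, "integer", 9, size = 4, endian = endian)
      delta <- readBin(con, "numeric", 1, size = 4, endian = endian)
      return(list(nsavc = max(1L, icntrl[3]), dt_ps = delta))
    }
  }
  NULL
}

#' Write a trajectory as a CHARMM-style DCD file
#'
#' Binary writer used to emit fixtures in the same dialect [read_trajectory()]
#' accepts. Coordinates are written in \enc{Å}{Angstrom}; the header timestep
#' field carries the frame interval in ps.
#'
#' @param trajectory A [droplet_trajectory()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dcd <- function(trajectory, path) {
  nf <- n_frames(trajectory)
  nb <- nrow(trajectory$topology)
  dt_ps <- if (nf > 1) frame_interval(trajectory) * 1000 else 1
  con <- file(path, open = "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  # header record: "CORD" + 20 control ints (delta stored as float in slot 10)
  wi(84); writeChar("CORD", con, 4, eos = NULL)
  wi(c(nf, 1L, 1L, nf, 0L, 0L, 0L, 0L, 0L))
  wf(dt_ps)
  wi(rep(0L, 9)); wi(24L)
  wi(84)
  title <- formatC("dropletmetrics trajectory", width = -80)
  wi(4L + 80L); wi(1L); writeChar(title, con, 80, eos = NULL); wi(4L + 80L)
  wi(4L); wi(nb); wi(4L)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(trajectory, f) * 10
    for (k in 1:3) {
      wi(4L * nb); wf(xyz[, k]); wi(4L * nb)
    }
  }
  invisible(path)
}
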