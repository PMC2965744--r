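#' Construct a droplet trajectory
#'
#' Bundles a topology with an ordered set of frames. Coordinates are stored as
#' an `n_frames x n_beads x 3` array in nm; times are in ns of *effective*
#' time (coarse-grained simulation time is conventionally multiplied by 4 on
#' ingest when `time_scale_applied`).
#'
#' @param topology A [droplet_topology()].
#' @param coords Numeric array `n_frames x n_beads x 3` (nm), or an
#'   `n_beads x 3` matrix for a single frame.
#' @param times_ns Strictly increasing frame times (ns).
#' @param box Optional per-frame box matrices (ignored by the analyses; the
#'   particle is compact and treated as unwrapped).
#' @param time_scale_applied Whether `times_ns` already include the x4
#'   effective-time scaling.
#' @return An object of class `droplet_trajectory`.
#' @export
droplet_trajectory <- function(topology, coords, times_ns = NULL, box = NULL,
                               time_scale_applied = FALSE) {
  assert_that(inherits(topology, "droplet_topology"), "topology must be a droplet_topology")
  if (length(dim(coords)) == 2L) {
    coords <- array(coords, dim = c(1L, dim(coords)))
  }
  assert_that(length(dim(coords)) == 3L && dim(coords)[3] == 3L,
              "coords must be an n_frames x n_beads x 3 array")
  if (dim(coords)[2] != nrow(topology)) {
    abort(sprintf("bead-count mismatch: topology has %d beads, frames have %d",
                  nrow(topology), dim(coords)[2]))
  }
  nf <- dim(coords)[1]
  if (is.null(times_ns)) times_ns <- seq_len(nf) - 1
  assert_that(length(times_ns) == nf, "times_ns must have one entry per frame")
  if (nf > 1) assert_that(all(diff(times_ns) > 0), "frame times must be strictly increasing")
  structure(
    list(topology = topology, coords = coords, times_ns = as.numeric(times_ns),
         box = box, time_scale_applied = isTRUE(time_scale_applied)),
    class = "droplet_trajectory"
  )
}

#' @export
print.droplet_trajectory <- function(x, ...) {
  cat(sprintf(
    "<droplet_trajectory> %d frames x %d beads, t = %.4g..%.4g ns%s\n",
    n_frames(x), nrow(x$topology), x$times_ns[1], x$times_ns[n_frames(x)],
    if (x$time_scale_applied) " (effective time, x4 applied)" else ""))
  invisible(x)
}

#' @rdname droplet_trajectory
#' @param x A trajectory.
#' @export
n_frames <- function(x) dim(x$coords)[1]

# n_beads x 3 coordinate matrix of one frame
frame_coords <- function(trajectory, frame) {
  matrix(trajectory$coords[frame, , ], ncol = 3L,
         dimnames = list(NULL, c("x", "y", "z")))
}

# Frame interval (ns); requires an (approximately) uniform time grid.
frame_interval <- function(trajectory) {
  dt <- diff(trajectory$times_ns)
  if (length(dt) == 0) abort("trajectory has a single frame; no frame interval")
  assert_that(max(dt) - min(dt) < 1e-6 * max(dt, 1e-12),
              "frame times are not uniformly spaced")
  dt[1]
}

#' Center of mass of one molecule in one frame
#'
#' @param trajectory A [droplet_trajectory()].
#' @param molecule_id Molecule id (as in the topology).
#' @param frame Frame index (1-based).
#' @param weights `"uniform"` (default; the COM weighting used throughout
#'   unless stated) or `"mass"` to use the topology's per-bead mass column.
#' @return A length-3 numeric vector (nm).
#' @export
molecule_com <- function(trajectory, molecule_id, frame = 1L,
                         weights = c("uniform", "mass")) {
  weights <- match.arg(weights)
  idx <- which(trajectory$topology$molecule_id == molecule_id)
  if (length(idx) == 0) abort(sprintf("unknown molecule_id: %s", molecule_id))
  xyz <- frame_coords(trajectory, frame)[idx, , drop = FALSE]
  w <- if (weights == "mass") trajectory$topology$mass[idx] else rep(1, length(idx))
  unname(colSums(xyz * w) / sum(w))
}

# COMs of all molecules of a bead-index subset, all frames:
# returns list(ids = molecule ids, coms = n_frames x n_mol x 3 array)
molecule_coms <- function(trajectory, bead_idx = NULL, weights = "uniform") {
  top <- trajectory$topology
  if (is.null(bead_idx)) bead_idx <- seq_len(nrow(top))
  mol <- top$molecule_id[bead_idx]
  ids <- unique(mol)
  g <- match(mol, ids)
  w <- if (identical(weights, "mass")) top$mass[bead_idx] else rep(1, length(bead_idx))
  wsum <- as.vector(rowsum(w, g))
  nf <- n_frames(trajectory)
  out <- array(NA_real_, dim = c(nf, length(ids), 3L))
  for (f in seq_len(nf)) {
    xyz <- matrix(trajectory$coords[f, bead_idx, ], ncol = 3L)
    out[f, , ] <- rowsum(xyz * w, g) / wsum
  }
  list(ids = ids, coms = out)
}

# Particle center of mass per frame (n_frames x 3). By default lipid beads
# only (water always excluded; protein excluded unless include_protein).
particle_com <- function(trajectory, frame = NULL, include_protein = FALSE,
                         weights = "uniform") {
  top <- trajectory$topology
  keep <- top$species %in% c("POPC", "PPC", "CHOL", "CE", "TG")
  if (include_protein) keep <- keep | top$species == "PROTEIN"
  if (!any(keep)) keep <- top$species != "WATER"
  w <- if (identical(weights, "mass")) top$mass[keep] else rep(1, sum(keep))
  frames <- if (is.null(frame)) seq_len(n_frames(trajectory)) else frame
  out <- matrix(NA_real_, length(frames), 3L)
  for (i in seq_along(frames)) {
    xyz <- matrix(trajectory$coords[frames[i], keep, ], ncol = 3L)
    out[i, ] <- colSums(xyz * w) / sum(w)
  }
  out
}

#' Guard against wrapped (periodic-image) molecules
#'
#' The analyses assume whole, unwrapped molecules in a compact droplet. This
#' guard flags molecules whose per-axis coordinate extent exceeds a threshold
#' in any frame, the signature of a molecule split across a periodic boundary.
#'
#' @param trajectory A [droplet_trajectory()].
#' @param threshold_nm Maximum allowed intra-molecular extent (default 5 nm).
#' @param include_protein Also check protein molecules (default `FALSE`: an
#'   apolipoprotein belt legitimately spans the whole particle).
#' @param error If `TRUE` (default) raise an error naming offending molecules.
#' @return Invisibly, the ids of offending molecules (empty if none).
#' @export
check_unwrapped <- function(trajectory, threshold_nm = 5,
                            include_protein = FALSE, error = TRUE) {
  top <- trajectory$topology
  lip <- !top$species %in% c("WATER", if (!include_protein) "PROTEIN")
  mol <- top$molecule_id[lip]
  ids <- unique(mol)
  g <- match(mol, ids)
  bad <- logical(length(ids))
  for (f in seq_len(n_frames(trajectory))) {
    xyz <- matrix(trajectory$coords[f, lip, ], ncol = 3L)
    for (k in 1:3) {
      mx <- tapply(xyz[, k], g, max) - tapply(xyz[, k], g, min)
      bad <- bad | (mx > threshold_nm)
    }
    if (all(bad)) break
  }
  offenders <- ids[bad]
  if (error && length(offenders) > 0) {
    abort(paste("molecules appear wrapped (extent >", threshold_nm, "nm):",
                paste(head(offenders, 10), collapse = ", ")))
  }
  invisible(offenders)
}

#' Tidy view of trajectory coordinates
#'
#' @param x A [droplet_trajectory()].
#' @param frames Frame indices to include (default all).
#' @param ... Unused.
#' @return A long tibble with bead annotations and `frame`, `time_ns`,
#'   `x`, `y`, `z` columns.
#' @exportS3Method generics::tidy
tidy.droplet_trajectory <- function(x, frames = NULL, ...) {
  frames <- frames %||% seq_len(n_frames(x))
  purrr::map_dfr(frames, function(f) {
    xyz <- frame_coords(x, f)
    dplyr::bind_cols(as_tibble(x$topology),
                     tibble(frame = f, time_ns = x$times_ns[f],
                            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
  })
}
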