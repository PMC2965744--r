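# Small fixture builders and independent brute-force oracles used across the
# suite. Everything is generated in code at test time; no stored data.

# a minimal hand-built topology of free beads (one molecule per bead)
bead_cloud_topology <- function(n, species = "PROTEIN", residue_name = "GLY") {
  if (species == "PROTEIN") {
    droplet_topology(tibble::tibble(
      molecule_id = 1L, species = species, bead_name = "BB",
      moiety = "backbone", residue_index = seq_len(n),
      residue_name = residue_name,
      hydro_class = ifelse(residue_name %in%
                             c("TRP", "PHE", "VAL", "LEU", "ILE", "MET", "ALA"),
                           "hydrophobic", "hydrophilic"),
      chain = "A"))
  } else {
    droplet_topology(tibble::tibble(
      molecule_id = seq_len(n), species = species, bead_name = "C1",
      moiety = "other"))
  }
}

# a two-molecule, two-bead-per-molecule lipid topology for COM arithmetic
tiny_lipid_traj <- function(coords, species = "CHOL",
                            bead_names = c("R5", "R1")) {
  n_mol <- nrow(coords) / length(bead_names)
  top <- droplet_topology(tibble::tibble(
    molecule_id = rep(seq_len(n_mol), each = length(bead_names)),
    species = species, bead_name = rep(bead_names, n_mol),
    moiety = "sterol_ring"))
  droplet_trajectory(top, coords)
}

small_droplet_spec <- function(n_frames = 1, seed = 11, ...) {
  synthetic_spec(composition = c(POPC = 30, PPC = 4, CE = 16, CHOL = 10,
                                 TG = 6),
                 n_frames = n_frames, dt_ns = 1, seed = seed, ...)
}

# O(N^2) all-pairs contact oracle (independent of neighbor_pairs internals)
oracle_pairs <- function(xa, xb, cutoff) {
  hits <- list()
  for (i in seq_len(nrow(xa))) {
    for (j in seq_len(nrow(xb))) {
      d <- sqrt(sum((xa[i, ] - xb[j, ])^2))
      if (d < cutoff) hits[[length(hits) + 1L]] <- c(i, j, d)
    }
  }
  if (length(hits) == 0) {
    return(tibble::tibble(i = integer(), j = integer(), dist_nm = numeric()))
  }
  m <- do.call(rbind, hits)
  tibble::tibble(i = as.integer(m[, 1]), j = as.integer(m[, 2]),
                 dist_nm = m[, 3]) |>
    dplyr::arrange(i, j)
}

# brute-force gap-merging oracle: scans the series once, bridging interior
# FALSE runs shorter than `tol` frames
oracle_merge <- function(x, tol) {
  out <- x
  n <- length(x)
  i <- 1L
  while (i <= n) {
    if (!out[i]) {
      j <- i
      while (j < n && !out[j + 1L]) j <- j + 1L
      interior <- i > 1L && j < n
      if (interior && (j - i + 1L) < tol) out[i:j] <- TRUE
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# dwell means from a raw boolean series without any merging
oracle_dwell_means <- function(x, dt) {
  r <- rle(x)
  n <- length(r$lengths)
  keep <- seq_len(n) > 1 & seq_len(n) < n
  c(on = mean(r$lengths[keep & r$values]) * dt,
    off = mean(r$lengths[keep & !r$values]) * dt)
}

# sample jump lengths exactly from the free-diffusion propagators
sample_p2d <- function(n, D, tau) sqrt(2 * D * tau * stats::rchisq(n, df = 2))
sample_p3d <- function(n, D, tau) sqrt(2 * D * tau * stats::rchisq(n, df = 3))

random_rotation <- function(seed = 1) {
  set.seed(seed)
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

rotate_trajectory <- function(traj, Rm, shift = c(0, 0, 0)) {
  coords <- traj$coords
  for (f in seq_len(dim(coords)[1])) {
    coords[f, , ] <- sweep(matrix(coords[f, , ], ncol = 3) %*% t(Rm), 2,
                           shift, `+`)
  }
  droplet_trajectory(traj$topology, coords, traj$times_ns)
}

annular_fixture <- function(lipid_x) {
  top <- droplet_topology(dplyr::bind_rows(
    tibble::tibble(molecule_id = 1L, species = "CHOL",
                   bead_name = c("R5", "R1"), moiety = "sterol_ring"),
    tibble::tibble(molecule_id = 2L, species = "PROTEIN", bead_name = "BB",
                   moiety = "backbone", residue_index = 1L,
                   residue_name = "TRP", hydro_class = "hydrophobic",
                   chain = "A")))
  droplet_trajectory(top, rbind(c(lipid_x, 0, 0), c(lipid_x + 0.3, 0, 0),
                                c(0, 0, 0)))
}

sasa_cloud <- function(coords, hydro = rep("hydrophilic", nrow(coords))) {
  top <- droplet_topology(tibble::tibble(
    molecule_id = 1L, species = "PROTEIN", bead_name = "BB",
    moiety = "backbone", residue_index = seq_len(nrow(coords)),
    residue_name = ifelse(hydro == "hydrophobic", "LEU", "SER"),
    hydro_class = hydro, chain = "A"))
  droplet_trajectory(top, coords)
}
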