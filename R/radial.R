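#' Radial number-density profile
#'
#' Histograms distances of selected beads (or molecule centers of mass) from
#' the particle center of mass, frame by frame, and converts time-averaged
#' counts to number densities by dividing by the spherical shell volume
#' `(4/3) pi (r+^3 - r-^3)`. Water is always excluded from the particle COM;
#' protein is excluded by default (the reference COM is the lipid droplet).
#'
#' @param trajectory A [droplet_trajectory()].
#' @param species Character vector of species to profile (default: all
#'   species present except water).
#' @param bin_width_nm Radial bin width (default 0.1 nm, fine enough to
#'   resolve the ~1 nm intermediate region).
#' @param reference `"bead"` (every bead counts) or `"molecule_com"` (one
#'   count per molecule at its COM).
#' @param com_include_protein Include protein beads in the particle COM.
#' @param r_max_nm Outer edge of the histogram (default: covers the data).
#' @param center Optional fixed reference point (length-3, nm) overriding the
#'   per-frame particle COM.
#' @return A tibble of class `radial_profile` with `species`, `r` (bin
#'   center), `count` (time-averaged counts per bin) and `density` (nm^-3).
#' @export
radial_density <- function(trajectory, species = NULL, bin_width_nm = 0.1,
                           reference = c("bead", "molecule_com"),
                           com_include_protein = FALSE, r_max_nm = NULL,
                           center = NULL) {
  reference <- match.arg(reference)
  assert_that(bin_width_nm > 0, "bin_width_nm must be > 0")
  top <- trajectory$topology
  species <- species %||% setdiff(unique(top$species), "WATER")
  sel <- top$species %in% species
  if (!any(sel)) abort(paste("empty selection: no beads of species",
                             paste(species, collapse = ", ")))
  nf <- n_frames(trajectory)
  pcom <- if (is.null(center)) {
    particle_com(trajectory, include_protein = com_include_protein)
  } else {
    matrix(center, nf, 3L, byrow = TRUE)
  }

  # collect per-frame radii and labels
  if (reference == "bead") {
    lab <- top$species[sel]
    radii <- lapply(seq_len(nf), function(f) {
      xyz <- matrix(trajectory$coords[f, sel, ], ncol = 3L)
      row_norms(sweep(xyz, 2, pcom[f, ]))
    })
  } else {
    mc <- molecule_coms(trajectory, which(sel))
    lab <- top$species[sel][match(mc$ids, top$molecule_id[sel])]
    radii <- lapply(seq_len(nf), function(f) {
      row_norms(sweep(matrix(mc$coms[f, , ], ncol = 3L), 2, pcom[f, ]))
    })
  }
  rmax <- r_max_nm %||% (max(vapply(radii, max, numeric(1))) + bin_width_nm)
  edges <- seq(0, rmax + bin_width_nm, by = bin_width_nm)
  nb <- length(edges) - 1L
  shell_vol <- 4 / 3 * pi * (edges[-1]^3 - edges[-length(edges)]^3)

  out <- purrr::map_dfr(species, function(sp) {
    counts <- numeric(nb)
    for (f in seq_len(nf)) {
      r <- radii[[f]][lab == sp]
      idx <- pmin(nb, findInterval(r, edges, left.open = FALSE))
      counts <- counts + tabulate(idx, nbins = nb)
    }
    counts <- counts / nf
    tibble(species = sp, r = (edges[-1] + edges[-length(edges)]) / 2,
           count = counts, density = counts / shell_vol)
  })
  attr(out, "bin_width_nm") <- bin_width_nm
  attr(out, "reference") <- reference
  class(out) <- c("radial_profile", class(out))
  out
}

#' Molecular composition table
#'
#' Counts molecules per species and converts to mol%. By convention the
#' denominator includes the protein chains (that convention reproduces the
#' reference composition table of the studied HDL system); set
#' `include_protein = FALSE` for the lipid-only denominator.
#'
#' @param topology A [droplet_topology()] (or a trajectory, whose topology is
#'   used).
#' @param include_protein Count protein chains in the mol% denominator.
#' @return A tibble with `species`, `n`, `mol_pct`.
#' @export
#' @examples
#' spec <- synthetic_spec(n_frames = 1)
#' composition(build_droplet(spec)$topology)
composition <- function(topology, include_protein = TRUE) {
  if (inherits(topology, "droplet_trajectory")) topology <- topology$topology
  cen <- species_census(topology) |> filter(.data$species != "WATER")
  assert_that(nrow(cen) > 0, "topology is empty")
  denom <- sum(cen$n_molecules[include_protein | cen$species != "PROTEIN"])
  cen |>
    mutate(n = .data$n_molecules,
           mol_pct = 100 * .data$n_molecules / denom) |>
    select("species", "n", "mol_pct") |>
    arrange(factor(.data$species, levels = species_levels()))
}

#' Radius of gyration
#'
#' `Rg = sqrt( sum w_i |x_i - xbar|^2 / sum w_i )` per frame over the
#' selected beads.
#'
#' @param trajectory A [droplet_trajectory()].
#' @param species Species to include (default: all non-water).
#' @param weights `"uniform"` or `"mass"`.
#' @return A tibble with `frame`, `time_ns`, `rg_nm`; mean and sd in
#'   attributes `"mean"` and `"sd"`.
#' @export
radius_of_gyration <- function(trajectory, species = NULL,
                               weights = c("uniform", "mass")) {
  weights <- match.arg(weights)
  top <- trajectory$topology
  species <- species %||% setdiff(unique(top$species), "WATER")
  sel <- top$species %in% species
  if (!any(sel)) abort("empty selection for radius_of_gyration")
  w <- if (weights == "mass") top$mass[sel] else rep(1, sum(sel))
  nf <- n_frames(trajectory)
  rg <- vapply(seq_len(nf), function(f) {
    xyz <- matrix(trajectory$coords[f, sel, ], ncol = 3L)
    ctr <- colSums(xyz * w) / sum(w)
    sqrt(sum(w * rowSums(sweep(xyz, 2, ctr)^2)) / sum(w))
  }, numeric(1))
  out <- tibble(frame = seq_len(nf), time_ns = trajectory$times_ns, rg_nm = rg)
  attr(out, "mean") <- mean(rg)
  attr(out, "sd") <- if (nf > 1) sd(rg) else 0
  out
}

#' Classify molecules into core / intermediate / surface regions
#'
#' Labels each molecule in each frame by its COM distance from the particle
#' COM: `r < r1` core, `r1 <= r < r2` intermediate, `r >= r2` surface
#' (half-open convention at both boundaries).
#'
#' @param trajectory A [droplet_trajectory()].
#' @param molecule_id Molecule ids to classify (default: all lipid molecules).
#' @param boundaries Region boundaries `(r1, r2)` in nm (default `c(3, 4)`).
#' @param com_include_protein Include protein in the particle COM.
#' @return A tibble with `molecule_id`, `species`, `frame`, `r_nm`, `region`,
#'   and the per-molecule modal label in `modal_region`.
#' @export
assign_region <- function(trajectory, molecule_id = NULL,
                          boundaries = c(3, 4), com_include_protein = FALSE) {
  assert_that(boundaries[1] < boundaries[2], "boundaries must satisfy r1 < r2")
  top <- trajectory$topology
  lipid <- top$species %in% c("POPC", "PPC", "CHOL", "CE", "TG")
  ids <- molecule_id %||% unique(top$molecule_id[lipid])
  bead_idx <- which(top$molecule_id %in% ids)
  assert_that(length(bead_idx) > 0, "no beads for the requested molecules")
  mc <- molecule_coms(trajectory, bead_idx)
  pcom <- particle_com(trajectory, include_protein = com_include_protein)
  nf <- n_frames(trajectory)
  sp <- top$species[match(mc$ids, top$molecule_id)]
  res <- purrr::map_dfr(seq_len(nf), function(f) {
    r <- row_norms(sweep(matrix(mc$coms[f, , ], ncol = 3L), 2, pcom[f, ]))
    tibble(molecule_id = mc$ids, species = sp, frame = f, r_nm = r,
           region = region_label(r, boundaries))
  })
  modal <- res |>
    count(.data$molecule_id, .data$region) |>
    group_by(.data$molecule_id) |>
    slice_max(.data$n, n = 1, with_ties = FALSE) |>
    ungroup() |>
    select("molecule_id", modal_region = "region")
  dplyr::left_join(res, modal, by = "molecule_id")
}

region_label <- function(r, boundaries) {
  ifelse(r < boundaries[1], "core",
         ifelse(r < boundaries[2], "intermediate", "surface"))
}
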