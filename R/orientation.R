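#' Define a molecular axis as a named bead pair
#'
#' @param species Species the axis belongs to.
#' @param from,to Bead names; the axis is drawn from `from` to `to`
#'   (tail to head).
#' @return A list of class `axis_segment`.
#' @export
axis_segment <- function(species, from, to) {
  structure(list(species = species, from = from, to = to),
            class = "axis_segment")
}

# Per-frame axis vectors and midpoints for all molecules of a species.
# Returns list(ids, vecs = nf x nmol x 3, mids = nf x nmol x 3).
segment_vectors <- function(trajectory, segment) {
  top <- trajectory$topology
  sel <- top$species == segment$species
  assert_that(any(sel), paste("no molecules of species", segment$species))
  ids <- unique(top$molecule_id[sel])
  locate <- function(bead) {
    cand <- which(sel & top$bead_name == bead)
    if (anyDuplicated(top$molecule_id[cand]) > 0) {
      abort(sprintf("axis bead '%s' occurs more than once per %s molecule",
                    bead, segment$species))
    }
    i <- cand[match(ids, top$molecule_id[cand])]
    if (anyNA(i)) {
      abort(sprintf("axis bead '%s' missing from %d %s molecule(s)",
                    bead, sum(is.na(i)), segment$species))
    }
    i
  }
  i_from <- locate(segment$from)
  i_to <- locate(segment$to)
  nf <- n_frames(trajectory)
  vecs <- array(NA_real_, dim = c(nf, length(ids), 3L))
  mids <- vecs
  for (f in seq_len(nf)) {
    a <- matrix(trajectory$coords[f, i_from, ], ncol = 3L)
    b <- matrix(trajectory$coords[f, i_to, ], ncol = 3L)
    vecs[f, , ] <- b - a
    mids[f, , ] <- (a + b) / 2
  }
  list(ids = ids, vecs = vecs, mids = mids)
}

#' Effective radial normal at a molecular axis midpoint
#'
#' The effective normal is the unit vector from the particle center of mass
#' to the midpoint of the molecular axis; it serves as the local director for
#' order parameters on a spheroidal particle.
#'
#' @param axis_midpoint An `n x 3` matrix (or length-3 vector) of axis
#'   midpoints (nm).
#' @param particle_com The particle COM (default origin).
#' @return An `n x 3` matrix of unit vectors. A midpoint coinciding with the
#'   COM has no defined normal and raises an error.
#' @export
#' @examples
#' effective_normal(c(3, 4, 0))  # (0.6, 0.8, 0)
effective_normal <- function(axis_midpoint, particle_com = c(0, 0, 0)) {
  if (is.null(dim(axis_midpoint))) axis_midpoint <- matrix(axis_midpoint, ncol = 3L)
  v <- sweep(axis_midpoint, 2, particle_com)
  if (any(row_norms(v) < 1e-10)) {
    abort("undefined effective normal: axis midpoint coincides with the particle COM")
  }
  unit_rows(v)
}

#' Orientational order parameter profile against the effective normal
#'
#' For every molecule of the species in every frame, computes the angle
#' between its axis (a named bead pair, e.g. the sterol ring axis) and the
#' effective normal at the axis midpoint, accumulates the second Legendre
#' polynomial `P2 = (3 cos^2 theta - 1)/2` into radial bins by midpoint
#' distance, and reports the bin average `S(r)`. `S = 1` for radial axes,
#' `0` for isotropic, `-0.5` for tangential.
#'
#' @param trajectory A [droplet_trajectory()].
#' @param segment An [axis_segment()]; defaults to the species' ring axis
#'   from [default_axis_definitions()] when `species` is given instead.
#' @param species Convenience: species whose default ring/primary axis to use.
#' @param bin_width_nm Radial bin width (default 0.1 nm).
#' @param min_count Bins with fewer samples are flagged unreliable.
#' @param com_include_protein Include protein in the particle COM.
#' @return A tibble of class `order_profile` with `r`, `S`, `n`, `reliable`.
#' @export
order_parameter_profile <- function(trajectory, segment = NULL, species = NULL,
                                    bin_width_nm = 0.1, min_count = 50,
                                    com_include_protein = FALSE) {
  if (is.null(segment)) {
    assert_that(!is.null(species), "give either a segment or a species")
    ax <- default_axis_definitions()
    ax <- ax[ax$species == species, ][1, ]
    assert_that(!is.na(ax$species), paste("no default axis for species", species))
    segment <- axis_segment(species, ax$from, ax$to)
  }
  sv <- segment_vectors(trajectory, segment)
  pcom <- particle_com(trajectory, include_protein = com_include_protein)
  nf <- n_frames(trajectory)
  r_all <- c(); p2_all <- c()
  for (f in seq_len(nf)) {
    mids <- matrix(sv$mids[f, , ], ncol = 3L)
    vecs <- matrix(sv$vecs[f, , ], ncol = 3L)
    nrm <- effective_normal(mids, pcom[f, ])
    ct <- rowSums(unit_rows(vecs) * nrm)
    r_all <- c(r_all, row_norms(sweep(mids, 2, pcom[f, ])))
    p2_all <- c(p2_all, (3 * ct^2 - 1) / 2)
  }
  edges <- seq(0, max(r_all) + bin_width_nm, by = bin_width_nm)
  idx <- pmin(length(edges) - 1L, findInterval(r_all, edges))
  out <- tibble(idx = idx, p2 = p2_all) |>
    group_by(.data$idx) |>
    summarise(S = mean(.data$p2), n = dplyr::n(), .groups = "drop") |>
    mutate(r = (edges[.data$idx] + edges[.data$idx + 1L]) / 2,
           reliable = .data$n >= min_count) |>
    select("r", "S", "n", "reliable") |>
    arrange(.data$r)
  attr(out, "species") <- segment$species
  attr(out, "segment") <- segment
  class(out) <- c("order_profile", class(out))
  out
}

#' Distribution of the angle between two molecular vectors
#'
#' Pools, over molecules and frames, the angle between vector `a` (a bead
#' pair within a species) and either another bead-pair vector of the same
#' species or the effective normal at the midpoint of `a`. The histogram over
#' `[0, 180]` degrees is normalized to unit mass. Zero-length vectors are
#' excluded; their count is reported in the `"n_dropped"` attribute (with a
#' warning).
#'
#' @param trajectory A [droplet_trajectory()].
#' @param vector_a An [axis_segment()].
#' @param vector_b An [axis_segment()] of the same species, or
#'   `"effective_normal"`.
#' @param bins_deg Bin width in degrees.
#' @param com_include_protein Include protein in the particle COM.
#' @return A tibble with `angle_deg` (bin centers) and `prob` (sums to 1).
#' @export
angle_distribution <- function(trajectory, vector_a,
                               vector_b = "effective_normal", bins_deg = 2,
                               com_include_protein = FALSE) {
  sa <- segment_vectors(trajectory, vector_a)
  use_normal <- identical(vector_b, "effective_normal")
  if (!use_normal) {
    assert_that(identical(vector_b$species, vector_a$species),
                "both segments must belong to the same species")
    sb <- segment_vectors(trajectory, vector_b)
  }
  pcom <- particle_com(trajectory, include_protein = com_include_protein)
  nf <- n_frames(trajectory)
  ang <- c(); dropped <- 0L
  for (f in seq_len(nf)) {
    va <- matrix(sa$vecs[f, , ], ncol = 3L)
    vb <- if (use_normal) {
      effective_normal(matrix(sa$mids[f, , ], ncol = 3L), pcom[f, ])
    } else {
      matrix(sb$vecs[f, , ], ncol = 3L)
    }
    ok <- row_norms(va) > 1e-10 & row_norms(vb) > 1e-10
    dropped <- dropped + sum(!ok)
    ang <- c(ang, angle_deg(va[ok, , drop = FALSE], vb[ok, , drop = FALSE]))
  }
  if (dropped > 0) warning(sprintf("%d zero-length vectors excluded", dropped))
  edges <- seq(0, 180, by = bins_deg)
  if (edges[length(edges)] < 180) edges <- c(edges, 180)
  idx <- pmin(length(edges) - 1L, findInterval(ang, edges))
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  out <- tibble(angle_deg = (edges[-1] + edges[-length(edges)]) / 2,
                prob = counts / sum(counts))
  attr(out, "n_dropped") <- dropped
  out
}

#' Joint conformational map of ring orientation and ring-chain angle
#'
#' For cholesteryl ester (or any species with both a ring axis and a chain
#' axis), builds the joint normalized histogram of (theta, phi) where theta
#' is the angle between the ring axis and the effective normal and phi the
#' angle between the ring axis and the chain (oleate) vector. Molecules are
#' filtered by the region of their ring-axis midpoint.
#'
#' @param trajectory A [droplet_trajectory()].
#' @param species Species to map (default `"CE"`).
#' @param ring,chain [axis_segment()]s; default to the species' `ring` and
#'   `oleate` axes from [default_axis_definitions()].
#' @param region Optional region filter (`"core"`, `"intermediate"`,
#'   `"surface"`).
#' @param boundaries Region boundaries (nm).
#' @param bins_deg Bin width (degrees) on both axes.
#' @param com_include_protein Include protein in the particle COM.
#' @return A tibble of class `conformation_map` with `theta_deg`, `phi_deg`,
#'   `prob` (sums to 1).
#' @export
conformation_map <- function(trajectory, species = "CE", ring = NULL,
                             chain = NULL, region = NULL,
                             boundaries = c(3, 4), bins_deg = 5,
                             com_include_protein = FALSE) {
  ax <- default_axis_definitions()
  if (is.null(ring)) {
    r <- ax[ax$species == species & ax$axis == "ring", ]
    assert_that(nrow(r) == 1, paste("no default ring axis for", species))
    ring <- axis_segment(species, r$from, r$to)
  }
  if (is.null(chain)) {
    c_ <- ax[ax$species == species & ax$axis %in% c("oleate", "sn1"), ][1, ]
    assert_that(!is.na(c_$species), paste("no default chain axis for", species))
    chain <- axis_segment(species, c_$from, c_$to)
  }
  sr <- segment_vectors(trajectory, ring)
  sc <- segment_vectors(trajectory, chain)
  pcom <- particle_com(trajectory, include_protein = com_include_protein)
  nf <- n_frames(trajectory)
  th <- c(); ph <- c()
  for (f in seq_len(nf)) {
    mids <- matrix(sr$mids[f, , ], ncol = 3L)
    vr <- matrix(sr$vecs[f, , ], ncol = 3L)
    vc <- matrix(sc$vecs[f, , ], ncol = 3L)
    keep <- rep(TRUE, nrow(mids))
    if (!is.null(region)) {
      r <- row_norms(sweep(mids, 2, pcom[f, ]))
      keep <- region_label(r, boundaries) == region
    }
    if (!any(keep)) next
    nrm <- effective_normal(mids[keep, , drop = FALSE], pcom[f, ])
    th <- c(th, angle_deg(vr[keep, , drop = FALSE], nrm))
    ph <- c(ph, angle_deg(vr[keep, , drop = FALSE], vc[keep, , drop = FALSE]))
  }
  if (length(th) == 0) abort("empty region selection in conformation_map")
  edges <- seq(0, 180, by = bins_deg)
  ti <- pmin(length(edges) - 1L, findInterval(th, edges))
  pi_ <- pmin(length(edges) - 1L, findInterval(ph, edges))
  ctr <- (edges[-1] + edges[-length(edges)]) / 2
  grid <- tidyr::expand_grid(theta_i = seq_along(ctr), phi_i = seq_along(ctr))
  counts <- tibble(theta_i = ti, phi_i = pi_) |>
    count(.data$theta_i, .data$phi_i)
  out <- dplyr::left_join(grid, counts, by = c("theta_i", "phi_i")) |>
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n),
           theta_deg = ctr[.data$theta_i], phi_deg = ctr[.data$phi_i],
           prob = .data$n / sum(.data$n)) |>
    select("theta_deg", "phi_deg", "prob")
  attr(out, "species") <- species
  attr(out, "region") <- region
  class(out) <- c("conformation_map", class(out))
  out
}
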