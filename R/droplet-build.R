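#' Build a synthetic droplet topology and initial frame
#'
#' Realizes a [synthetic_spec()] as a bead-level structure with known ground
#' truth. Placement rules: TG/CE (and a core fraction of CHOL) anchors are
#' uniform in the core ball; POPC/PPC (and the surface fraction of CHOL)
#' anchors are uniform in radius over the surface shell; the protein chains
#' are great-circle bead bands just inside the particle radius. Molecules are
#' placed in antipodal pairs so the particle center of mass sits at the
#' origin by construction (a variance-reduction choice). Each molecule's axis
#' is drawn from [sample_orientations()] at the per-region target order
#' parameter, measured against the radial direction at the anchor; ring
#' lipids (CHOL, CE) are anchored by their ring-axis midpoint, the quantity
#' radial binning uses, so the prescribed order is recovered exactly up to
#' sampling noise.
#'
#' @param spec A [synthetic_spec()].
#' @return A single-frame [droplet_trajectory()] carrying the ground-truth
#'   placement in `attr(, "ground_truth")` (a tibble of per-molecule anchor
#'   radii, regions and axis angles).
#' @export
build_droplet <- function(spec) {
  assert_that(inherits(spec, "synthetic_spec"), "spec must be a synthetic_spec")
  set.seed(spec$seed)
  r1 <- spec$shell_radii[1]; r2 <- spec$shell_radii[2]; pr <- spec$particle_radius
  comp <- spec$composition
  n_core_chol <- round(sum(comp["CHOL"]) * (1 - spec$chol_surface_fraction))
  # packing sanity: ~1.5 nm^3 per core molecule, ~0.35 nm^2 per surface anchor
  n_core <- sum(comp[c("TG", "CE")]) + n_core_chol
  n_surf <- sum(comp[c("POPC", "PPC")]) + (comp[["CHOL"]] - n_core_chol)
  if (n_core * 0.35 > 4 / 3 * pi * r1^3 || n_surf * 0.12 > 4 * pi * r2^2) {
    abort("composition cannot be packed at these radii; increase particle_radius")
  }

  tpl <- bead_templates()
  axdef <- default_axis_definitions()
  lam <- lapply(spec$S_target, maier_saupe_lambda)

  plan <- list()
  add <- function(species, n, where) {
    if (n > 0) plan[[length(plan) + 1L]] <<- tibble(species = species,
                                                    where = where, n = n)
  }
  add("TG", comp[["TG"]], "core"); add("CE", comp[["CE"]], "core")
  add("CHOL", n_core_chol, "core")
  add("CHOL", comp[["CHOL"]] - n_core_chol, "shell")
  add("POPC", comp[["POPC"]], "shell"); add("PPC", comp[["PPC"]], "shell")
  plan <- dplyr::bind_rows(plan)

  beads <- list(); coords <- list(); truth <- list(); mol_id <- 0L
  for (i in seq_len(nrow(plan))) {
    sp <- plan$species[i]; n <- plan$n[i]
    # antipodal direction pairs
    ndir <- ceiling(n / 2)
    dirs <- random_unit_vectors(ndir)
    dirs <- rbind(dirs, -dirs)[seq_len(n), , drop = FALSE]
    rads <- if (plan$where[i] == "core") {
      rep(r1 * runif(ndir)^(1 / 3), length.out = n)
    } else {
      rep(runif(ndir, r2, pr), length.out = n)
    }
    region <- ifelse(rads < r1, "core", ifelse(rads < r2, "intermediate", "surface"))
    tb <- tpl[[sp]]
    offs <- as.matrix(tb[, c("x", "y", "z")])
    ax <- axdef[axdef$species == sp, ][1, ]  # ring axis for CHOL/CE, sn1/pn else
    anchor <- if (sp %in% c("CHOL", "CE")) {
      (offs[match(ax$from, tb$bead_name), ] + offs[match(ax$to, tb$bead_name), ]) / 2
    } else {
      colMeans(offs)
    }
    offs <- sweep(offs, 2, anchor)
    for (m in seq_len(n)) {
      mol_id <- mol_id + 1L
      e_r <- dirs[m, ]
      u_cos <- sample_cos_theta(1, lam[[region[m]]])
      phi <- runif(1, 0, 2 * pi)
      st <- sqrt(max(0, 1 - u_cos^2))
      local_axis <- c(st * cos(phi), st * sin(phi), u_cos)
      u <- as.vector(rotation_z_to(e_r) %*% local_axis)
      rot <- rotation_z_to(u)
      pos <- sweep(offs %*% t(rot), 2, rads[m] * e_r, `+`)
      beads[[mol_id]] <- tibble(molecule_id = mol_id, species = sp,
                                bead_name = tb$bead_name, moiety = tb$moiety)
      coords[[mol_id]] <- pos
      truth[[mol_id]] <- tibble(molecule_id = mol_id, species = sp,
                                radius_nm = rads[m], region = region[m],
                                cos_theta = u_cos)
    }
  }

  # protein chains: bead circles at +/- z0 just inside the particle radius
  hydro <- default_hydro_classes()
  hmap <- setNames(hydro$hydro_class, hydro$residue_name)
  seq1 <- strsplit(synthetic_apoa1_sequence(), "")[[1]]
  res3 <- aa1to3(seq1)
  nres <- length(res3)
  z0 <- 0.35
  rc <- sqrt(pr^2 - z0^2) - 0.1
  for (ch in seq_len(spec$n_protein_chains)) {
    mol_id <- mol_id + 1L
    sign_z <- if (ch %% 2 == 1) 1 else -1
    ang <- 2 * pi * (seq_len(nres) - 1L) / nres + (ch - 1) * pi / spec$n_protein_chains
    pos <- cbind(rc * cos(ang), rc * sin(ang), sign_z * z0)
    beads[[mol_id]] <- tibble(molecule_id = mol_id, species = "PROTEIN",
                              bead_name = "BB", moiety = "backbone",
                              residue_index = seq_len(nres),
                              residue_name = res3,
                              hydro_class = unname(hmap[res3]),
                              chain = LETTERS[ch])
    coords[[mol_id]] <- pos
  }

  top <- droplet_topology(dplyr::bind_rows(beads))
  xyz <- do.call(rbind, coords)
  traj <- droplet_trajectory(top, xyz, times_ns = 0)
  attr(traj, "ground_truth") <- dplyr::bind_rows(truth)
  attr(traj, "spec") <- spec
  traj
}

#' Build a synthetic droplet trajectory with ground-truth dynamics
#'
#' Extends [build_droplet()] in time: each molecule translates rigidly (fixed
#' orientation) with its center following Brownian motion — tangent-plane
#' steps on the sphere of its own anchor radius for surface-shell molecules
#' (coefficient `D2_true`), reflecting-boundary steps inside the core ball
#' for core molecules (`D3_true`). Protein beads are static. Frame times are
#' `0, dt_ns, ...` over `n_frames` frames.
#'
#' @param spec A [synthetic_spec()].
#' @return A [droplet_trajectory()] with the same `ground_truth` attribute as
#'   [build_droplet()].
#' @export
build_droplet_trajectory <- function(spec) {
  frame0 <- build_droplet(spec)
  truth <- attr(frame0, "ground_truth")
  top <- frame0$topology
  nf <- spec$n_frames
  coords <- array(NA_real_, dim = c(nf, nrow(top), 3L))
  coords[1, , ] <- frame0$coords[1, , ]
  if (nf > 1) {
    set.seed(spec$seed + 1L)
    surf <- truth$molecule_id[truth$region == "surface"]
    core <- truth$molecule_id[truth$region != "surface"]
    anchors0 <- t(vapply(truth$molecule_id, function(m) {
      idx <- which(top$molecule_id == m)
      colMeans(matrix(frame0$coords[1, idx, ], ncol = 3L))
    }, numeric(3)))
    paths <- array(0, dim = c(nf, nrow(truth), 3L))
    if (length(surf) > 0) {
      is_ <- match(surf, truth$molecule_id)
      paths[, is_, ] <- sphere_walk(anchors0[is_, , drop = FALSE],
                                    R = row_norms(anchors0[is_, , drop = FALSE]),
                                    D = spec$D2_true, dt_ns = spec$dt_ns,
                                    n_steps = nf - 1L)
    }
    if (length(core) > 0) {
      ic <- match(core, truth$molecule_id)
      paths[, ic, ] <- ball_walk(anchors0[ic, , drop = FALSE],
                                 R = spec$shell_radii[1],
                                 D = spec$D3_true, dt_ns = spec$dt_ns,
                                 n_steps = nf - 1L)
    }
    idx_list <- split(seq_len(nrow(top)), top$molecule_id)
    for (f in 2:nf) {
      coords[f, , ] <- coords[1, , ]
      for (k in seq_len(nrow(truth))) {
        idx <- idx_list[[as.character(truth$molecule_id[k])]]
        shift <- paths[f, k, ] - paths[1, k, ]
        coords[f, idx, ] <- sweep(matrix(coords[1, idx, ], ncol = 3L), 2, shift, `+`)
      }
    }
  }
  traj <- droplet_trajectory(top, coords,
                             times_ns = (seq_len(nf) - 1L) * spec$dt_ns)
  attr(traj, "ground_truth") <- truth
  attr(traj, "spec") <- spec
  traj
}
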