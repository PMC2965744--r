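#' Construct a droplet topology
#'
#' A topology is a tibble with one row per coarse-grained bead, carrying the
#' static description of the system: which molecule each bead belongs to, the
#' molecule's species, the bead and moiety labels, and (for protein beads)
#' residue annotations and hydrophobicity class. Bead ids are dense `1..N` in
#' file order (internal convention).
#'
#' @param beads A data frame with at least `molecule_id`, `species`,
#'   `bead_name`; optionally `moiety`, `residue_index`, `residue_name`,
#'   `hydro_class`, `chain`, `mass`.
#' @return A tibble of class `droplet_topology`.
#' @export
droplet_topology <- function(beads) {
  b <- as_tibble(beads)
  needed <- c("molecule_id", "species", "bead_name")
  assert_that(all(needed %in% names(b)),
              paste("topology needs columns:", paste(needed, collapse = ", ")))
  n <- nrow(b)
  b$bead_id <- seq_len(n)
  for (col in c("moiety", "residue_name", "hydro_class", "chain")) {
    if (!col %in% names(b)) b[[col]] <- NA_character_
  }
  if (!"residue_index" %in% names(b)) b$residue_index <- NA_integer_
  if (!"mass" %in% names(b)) b$mass <- 1
  bad_sp <- setdiff(unique(b$species), species_levels())
  assert_that(length(bad_sp) == 0,
              paste("unknown species:", paste(bad_sp, collapse = ", ")))
  # species constant within molecule
  nsp <- b |> distinct(.data$molecule_id, .data$species) |> count(.data$molecule_id)
  assert_that(all(nsp$n == 1), "molecule species must be constant within a molecule")
  lip <- b$species %in% c("POPC", "PPC", "CHOL", "CE", "TG")
  assert_that(!anyNA(b$moiety[lip]), "lipid beads must carry a moiety label")
  prot <- b$species == "PROTEIN"
  assert_that(!anyNA(b$residue_index[prot]) && !anyNA(b$residue_name[prot]),
              "PROTEIN beads must carry residue_index and residue_name")
  b <- b[, c("bead_id", "molecule_id", "species", "bead_name", "moiety",
             "residue_index", "residue_name", "hydro_class", "chain", "mass")]
  class(b) <- c("droplet_topology", class(tibble()))
  b
}

#' @export
print.droplet_topology <- function(x, ...) {
  cat(sprintf("<droplet_topology> %d beads, %d molecules\n",
              nrow(x), dplyr::n_distinct(x$molecule_id)))
  cen <- species_census(x)
  cat(paste(sprintf("%s=%d", cen$species, cen$n_molecules), collapse = "  "), "\n")
  NextMethod()
}

#' Count molecules and beads per species
#'
#' @param topology A [droplet_topology()].
#' @return A tibble with `species`, `n_molecules`, `n_beads`.
#' @export
species_census <- function(topology) {
  as_tibble(topology) |>
    group_by(.data$species) |>
    summarise(n_molecules = dplyr::n_distinct(.data$molecule_id),
              n_beads = dplyr::n(), .groups = "drop")
}

# Assign species/moiety (and hydro_class for protein) to parsed beads using a
# mapping table. Unknown residue names are an error listing the names.
assign_species <- function(parsed, bead_map = default_bead_map(),
                           hydro = default_hydro_classes()) {
  specific <- bead_map[!is.na(bead_map$bead_name), ]
  generic <- bead_map[is.na(bead_map$bead_name), c("residue_name", "species", "moiety")]
  p <- as_tibble(parsed)
  p$.row <- seq_len(nrow(p))
  m1 <- dplyr::left_join(p, specific, by = c("residue_name", "bead_name"))
  m2 <- dplyr::left_join(p, generic, by = "residue_name")
  miss <- is.na(m1$species)
  m1$species[miss] <- m2$species[miss]
  m1$moiety[miss] <- m2$moiety[miss]
  if (anyNA(m1$species)) {
    bad <- unique(paste0(p$residue_name[is.na(m1$species)], "/",
                         p$bead_name[is.na(m1$species)]))
    abort(paste("no species mapping for residue/bead name(s):",
                paste(head(bad, 10), collapse = ", ")))
  }
  m1 <- m1[order(m1$.row), ]
  m1$hydro_class <- NA_character_
  isp <- m1$species == "PROTEIN"
  if (any(isp)) {
    hmap <- setNames(hydro$hydro_class, hydro$residue_name)
    m1$hydro_class[isp] <- unname(hmap[m1$residue_name[isp]])
  }
  m1$.row <- NULL
  m1
}

# Derive molecule ids from residue numbering: for lipids one residue = one
# molecule; consecutive protein residues of one chain form one molecule.
derive_molecule_ids <- function(species, residue_serial, chain = NULL) {
  key <- ifelse(species == "PROTEIN",
                paste0("P", if (is.null(chain)) "" else chain),
                paste0("R", residue_serial))
  match(key, unique(key))
}
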