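#' Contact record container
#'
#' Holds per-(lipid molecule, frame) boolean contact (annular) states, the
#' frame times, and the cutoff that produced them.
#'
#' @param state `n_frames x n_lipids` logical matrix.
#' @param times_ns Frame times (ns).
#' @param cutoff_nm Cutoff used (NA for synthetic telegraph records).
#' @param molecule_ids,species Per-column molecule ids and species labels.
#' @return An object of class `contact_record`.
#' @export
contact_record <- function(state, times_ns, cutoff_nm, molecule_ids, species) {
  assert_that(is.matrix(state) && is.logical(state),
              "state must be a logical matrix (frames x lipids)")
  assert_that(nrow(state) == length(times_ns), "one time per frame required")
  assert_that(ncol(state) == length(molecule_ids) &&
                ncol(state) == length(species),
              "one molecule id and species per column required")
  structure(list(state = state, times_ns = as.numeric(times_ns),
                 cutoff_nm = cutoff_nm, molecule_ids = molecule_ids,
                 species = species),
            class = "contact_record")
}

#' @export
print.contact_record <- function(x, ...) {
  cat(sprintf("<contact_record> %d frames x %d lipids (cutoff %s nm), on-fraction %.3f\n",
              nrow(x$state), ncol(x$state),
              format(x$cutoff_nm), mean(x$state)))
  invisible(x)
}

#' Annular-lipid state time series
#'
#' A lipid is annular in a frame iff any of its beads lies within the cutoff
#' (strictly less than `cutoff_nm`, default 0.8 nm = 8 Angstrom) of any
#' protein bead.
#'
#' @param trajectory A [droplet_trajectory()] containing protein.
#' @param species Lipid species to monitor (default: all lipid species
#'   present).
#' @param cutoff_nm Contact cutoff (nm).
#' @return A [contact_record()].
#' @export
annular_states <- function(trajectory, species = NULL, cutoff_nm = 0.8) {
  top <- trajectory$topology
  prot <- which(top$species == "PROTEIN")
  if (length(prot) == 0) abort("no protein beads in the topology")
  species <- species %||% intersect(c("POPC", "PPC", "CHOL", "CE", "TG"),
                                    unique(top$species))
  lip <- which(top$species %in% species)
  assert_that(length(lip) > 0, "no lipid beads of the requested species")
  ids <- unique(top$molecule_id[lip])
  mol_of <- match(top$molecule_id[lip], ids)
  sp <- top$species[lip][match(ids, top$molecule_id[lip])]
  nf <- n_frames(trajectory)
  state <- matrix(FALSE, nf, length(ids))
  for (f in seq_len(nf)) {
    pr <- neighbor_pairs(matrix(trajectory$coords[f, lip, ], ncol = 3L),
                         matrix(trajectory$coords[f, prot, ], ncol = 3L),
                         cutoff_nm)
    if (nrow(pr) > 0) state[f, unique(mol_of[pr$i])] <- TRUE
  }
  contact_record(state, trajectory$times_ns, cutoff_nm, ids, sp)
}

#' Per-species annular counts and fractions
#'
#' @param record A [contact_record()].
#' @return A tibble with `species`, `n_total`, `mean_annular` (time-averaged
#'   count) and `fraction` (count / total).
#' @export
annular_summary <- function(record) {
  assert_that(ncol(record$state) > 0, "empty contact record")
  purrr::map_dfr(unique(record$species), function(sp) {
    cols <- which(record$species == sp)
    counts <- rowSums(record$state[, cols, drop = FALSE])
    tibble(species = sp, n_total = length(cols),
           mean_annular = mean(counts),
           fraction = mean(counts) / length(cols))
  })
}

# Merge off-gaps strictly shorter than `tol` frames into the surrounding
# contact interval (gaps at the series ends are not bridged).
merge_gaps <- function(x, tol) {
  if (tol <= 0 || !any(x) || all(x)) return(x)
  r <- rle(x)
  n <- length(r$lengths)
  interior <- seq_len(n) > 1 & seq_len(n) < n
  fill <- !r$values & interior & r$lengths < tol
  r$values[fill] <- TRUE
  inverse.rle(r)
}

#' Contact lifetime statistics with the gap-tolerance rule
#'
#' Dwell (lifetime) statistics of a boolean contact series. Following the
#' tolerance rule for couplings fluctuating around the cutoff, a non-contact
#' gap strictly shorter than `tolerance_frames` frames (default 10) does not
#' break the surrounding contact interval. Dwell times are merged run
#' lengths times the frame interval. Intervals touching either end of the
#' trajectory are censored: they are flagged, reported, and excluded from
#' the means by default (means including them are also returned).
#'
#' @param record A [contact_record()].
#' @param tolerance_frames Gap tolerance in frames (0 or 1 = no merging).
#' @return An object of class `lifetime_stats`: `mean_on_ns`, `mean_off_ns`
#'   (censored intervals excluded), `mean_on_all_ns`, `mean_off_all_ns`
#'   (included), `dwells` (tibble with `molecule_id`, `state`, `n_frames`,
#'   `duration_ns`, `censored`), `tolerance_frames`, `dt_ns`.
#' @export
contact_lifetimes <- function(record, tolerance_frames = 10) {
  assert_that(nrow(record$state) >= 2, "need at least 2 frames")
  dt <- record$times_ns[2] - record$times_ns[1]
  dw <- purrr::map_dfr(seq_len(ncol(record$state)), function(jcol) {
    x <- merge_gaps(record$state[, jcol], tolerance_frames)
    r <- rle(x)
    n <- length(r$lengths)
    tibble(molecule_id = record$molecule_ids[jcol],
           state = r$values, n_frames = r$lengths,
           duration_ns = r$lengths * dt,
           censored = seq_len(n) == 1L | seq_len(n) == n)
  })
  mean_st <- function(st, cens_ok) {
    d <- dw$duration_ns[dw$state == st & (cens_ok | !dw$censored)]
    if (length(d) == 0) NA_real_ else mean(d)
  }
  structure(
    list(mean_on_ns = mean_st(TRUE, FALSE), mean_off_ns = mean_st(FALSE, FALSE),
         mean_on_all_ns = mean_st(TRUE, TRUE),
         mean_off_all_ns = mean_st(FALSE, TRUE),
         dwells = dw, tolerance_frames = tolerance_frames, dt_ns = dt),
    class = "lifetime_stats")
}

#' @export
print.lifetime_stats <- function(x, ...) {
  cat(sprintf(
    "<lifetime_stats> mean contact %.4g ns, mean non-contact %.4g ns (tolerance %d frames; censored excluded)\n",
    x$mean_on_ns, x$mean_off_ns, x$tolerance_frames))
  invisible(x)
}

#' Per-residue-type lipid contact profile
#'
#' Counts (lipid bead, protein bead) pairs within the cutoff, aggregates by
#' protein residue type, averages over frames, and normalizes per residue:
#' the count for each residue type is divided by the number of residues of
#' that type present in the protein content of the topology. A
#' hydrophobic/hydrophilic rollup (same normalization, per residue of the
#' class) is attached as attribute `"hydro_rollup"`.
#'
#' @param trajectory A [droplet_trajectory()] with residue-annotated protein.
#' @param species Lipid species to profile (default `"CHOL"`).
#' @param cutoff_nm Contact cutoff (nm).
#' @return A tibble with `residue_name`, `hydro_class`, `n_residues`,
#'   `contacts_per_frame`, `contacts_per_residue`.
#' @export
residue_contact_profile <- function(trajectory, species = "CHOL",
                                    cutoff_nm = 0.8) {
  top <- trajectory$topology
  prot <- which(top$species == "PROTEIN")
  assert_that(length(prot) > 0, "no protein beads")
  if (anyNA(top$hydro_class[prot])) {
    bad <- unique(top$residue_name[prot][is.na(top$hydro_class[prot])])
    abort(paste("protein residues lacking hydro_class:", paste(bad, collapse = ", ")))
  }
  lip <- which(top$species %in% species)
  assert_that(length(lip) > 0, paste("no beads of species", species))
  nf <- n_frames(trajectory)
  hit_names <- character(0)
  for (f in seq_len(nf)) {
    pr <- neighbor_pairs(matrix(trajectory$coords[f, lip, ], ncol = 3L),
                         matrix(trajectory$coords[f, prot, ], ncol = 3L),
                         cutoff_nm)
    if (nrow(pr) > 0) hit_names <- c(hit_names, top$residue_name[prot][pr$j])
  }
  counts <- table(hit_names)
  counts <- setNames(as.numeric(counts), names(counts))
  res_tab <- as_tibble(top[prot, c("residue_name", "hydro_class", "chain",
                                   "residue_index")]) |>
    distinct(.data$chain, .data$residue_index, .data$residue_name,
             .data$hydro_class) |>
    count(.data$residue_name, .data$hydro_class, name = "n_residues")
  out <- res_tab |>
    mutate(contacts_per_frame = unname(ifelse(is.na(counts[.data$residue_name]),
                                              0, counts[.data$residue_name])) / nf,
           contacts_per_residue = .data$contacts_per_frame / .data$n_residues) |>
    arrange(dplyr::desc(.data$contacts_per_residue))
  rollup <- out |>
    group_by(.data$hydro_class) |>
    summarise(n_residues = sum(.data$n_residues),
              contacts_per_frame = sum(.data$contacts_per_frame),
              .groups = "drop") |>
    mutate(contacts_per_residue = .data$contacts_per_frame / .data$n_residues)
  attr(out, "hydro_rollup") <- rollup
  attr(out, "species") <- paste(species, collapse = "+")
  out
}

#' Percentage of lipid-protein contacts by lipid moiety
#'
#' For each lipid species, the percentage of its protein contacts (bead
#' pairs within the cutoff, pooled over frames) contributed by each moiety.
#' Rows sum to 100% per species.
#'
#' @param trajectory A [droplet_trajectory()].
#' @param cutoff_nm Contact cutoff (nm).
#' @return A tibble with `species`, `moiety`, `n_contacts`, `pct`.
#' @export
moiety_contact_fractions <- function(trajectory, cutoff_nm = 0.8) {
  top <- trajectory$topology
  prot <- which(top$species == "PROTEIN")
  assert_that(length(prot) > 0, "no protein beads")
  lip <- which(top$species %in% c("POPC", "PPC", "CHOL", "CE", "TG"))
  assert_that(length(lip) > 0, "no lipid beads")
  if (anyNA(top$moiety[lip])) abort("lipid beads without moiety labels")
  nf <- n_frames(trajectory)
  tallies <- list()
  for (f in seq_len(nf)) {
    pr <- neighbor_pairs(matrix(trajectory$coords[f, lip, ], ncol = 3L),
                         matrix(trajectory$coords[f, prot, ], ncol = 3L),
                         cutoff_nm)
    if (nrow(pr) > 0) {
      tallies[[length(tallies) + 1L]] <-
        tibble(species = top$species[lip][pr$i], moiety = top$moiety[lip][pr$i])
    }
  }
  if (length(tallies) == 0) {
    return(tibble(species = character(), moiety = character(),
                  n_contacts = integer(), pct = numeric()))
  }
  dplyr::bind_rows(tallies) |>
    count(.data$species, .data$moiety, name = "n_contacts") |>
    group_by(.data$species) |>
    mutate(pct = 100 * .data$n_contacts / sum(.data$n_contacts)) |>
    ungroup()
}

#' Contact counts between two bead groups over time
#'
#' Number of bead pairs within the cutoff between groups A and B in each
#' frame. Groups are species names or integer bead-id vectors; overlapping
#' groups are rejected unless `allow_overlap`.
#'
#' @param trajectory A [droplet_trajectory()].
#' @param group_a,group_b Species name(s) or integer bead ids.
#' @param cutoff_nm Contact cutoff (nm).
#' @param allow_overlap Permit overlapping groups.
#' @return A tibble with `frame`, `time_ns`, `n_contacts`.
#' @export
intergroup_contacts <- function(trajectory, group_a, group_b, cutoff_nm = 0.8,
                                allow_overlap = FALSE) {
  resolve <- function(g) {
    if (is.character(g)) which(trajectory$topology$species %in% g)
    else as.integer(g)
  }
  ia <- resolve(group_a); ib <- resolve(group_b)
  assert_that(length(ia) > 0, "group_a is empty")
  assert_that(length(ib) > 0, "group_b is empty")
  if (!allow_overlap && length(intersect(ia, ib)) > 0) {
    abort("groups overlap; pass allow_overlap = TRUE to permit this")
  }
  nf <- n_frames(trajectory)
  n <- vapply(seq_len(nf), function(f) {
    nrow(neighbor_pairs(matrix(trajectory$coords[f, ia, ], ncol = 3L),
                        matrix(trajectory$coords[f, ib, ], ncol = 3L),
                        cutoff_nm))
  }, integer(1))
  tibble(frame = seq_len(nf), time_ns = trajectory$times_ns, n_contacts = n)
}
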