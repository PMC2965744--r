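#' Read a structure file into a topology plus a single frame
#'
#' Parses a GRO or PDB structure, assigns species and moieties from the bead
#' mapping table, derives molecule ids (one lipid molecule per residue; one
#' protein molecule per chain), and returns a single-frame
#' [droplet_trajectory()]. Coordinates are converted to nm on ingest
#' (PDB stores \enc{Å}{Angstrom}).
#'
#' @param path Path to the structure file.
#' @param dialect `"gro"` or `"pdb"`.
#' @param bead_map Mapping table, see [default_bead_map()] / [read_bead_map()].
#' @param hydro Residue hydrophobicity table, see [default_hydro_classes()].
#' @return A single-frame [droplet_trajectory()]; the topology is in
#'   `$topology`.
#' @export
read_structure <- function(path, dialect = c("gro", "pdb"),
                           bead_map = default_bead_map(),
                           hydro = default_hydro_classes()) {
  dialect <- match.arg(dialect)
  assert_that(file.exists(path), paste("file not found:", path))
  parsed <- switch(dialect,
    gro = parse_gro_block(readLines(path), offset = 0L),
    pdb = parse_pdb(path)
  )
  build_topology_frame(parsed$atoms, parsed$coords, bead_map, hydro,
                       time_ns = parsed$time_ns %||% 0)
}

# atoms: tibble(residue_serial, residue_index, residue_name, bead_name, chain)
build_topology_frame <- function(atoms, coords, bead_map, hydro, time_ns = 0) {
  ann <- assign_species(atoms, bead_map, hydro)
  isp <- ann$species == "PROTEIN"
  # re-letter protein chains A, B, ... regardless of what precedes them
  if (any(isp)) {
    pc <- ann$chain[isp]
    ann$chain[isp] <- LETTERS[cumsum(c(TRUE, pc[-1] != pc[-length(pc)]))]
  }
  ann$chain[!isp] <- NA_character_
  ann$molecule_id <- derive_molecule_ids(ann$species, ann$residue_serial, ann$chain)
  ann$residue_index[!isp] <- NA_integer_
  ann$residue_name[!isp] <- NA_character_
  top <- droplet_topology(ann[, c("molecule_id", "species", "bead_name", "moiety",
                                  "residue_index", "residue_name", "hydro_class",
                                  "chain")])
  droplet_trajectory(top, coords, times_ns = time_ns)
}

# Parse one GRO frame from `lines` starting at 1-based index offset+1.
# Returns atoms tibble, coords (nm), time_ns (from a "t=" tag, ps -> ns),
# and the number of lines consumed.
parse_gro_block <- function(lines, offset = 0L) {
  need <- function(i) {
    if (i > length(lines)) abort(sprintf("GRO parse error at line %d: unexpected end of file", i))
    lines[i]
  }
  title <- need(offset + 1L)
  nat <- suppressWarnings(as.integer(trimws(need(offset + 2L))))
  if (is.na(nat) || nat < 1) {
    abort(sprintf("GRO parse error at line %d: expected atom count, got '%s'",
                  offset + 2L, lines[offset + 2L]))
  }
  time_ns <- NULL
  tm <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
  if (length(tm) == 1) time_ns <- as.numeric(sub("t=\\s*", "", tm)) / 1000
  rows <- offset + 2L + seq_len(nat)
  if (max(rows) + 1L > length(lines)) {
    abort(sprintf("GRO parse error: frame starting at line %d truncated", offset + 1L))
  }
  al <- lines[rows]
  bad <- which(nchar(al) < 44)
  if (length(bad) > 0) {
    abort(sprintf("GRO parse error at line %d: atom line shorter than 44 columns", rows[bad[1]]))
  }
  resid <- suppressWarnings(as.integer(substr(al, 1, 5)))
  resname <- trimws(substr(al, 6, 10))
  beadname <- trimws(substr(al, 11, 15))
  x <- suppressWarnings(as.numeric(substr(al, 21, 28)))
  y <- suppressWarnings(as.numeric(substr(al, 29, 36)))
  z <- suppressWarnings(as.numeric(substr(al, 37, 44)))
  bad <- which(is.na(resid) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad) > 0) {
    abort(sprintf("GRO parse error at line %d: malformed atom line", rows[bad[1]]))
  }
  new_res <- c(TRUE, resid[-1] != resid[-nat] | resname[-1] != resname[-nat])
  serial <- cumsum(new_res)
  # chain breaks: residue numbering restarting within a contiguous block
  restart <- c(FALSE, diff(resid) < 0) & new_res
  chain <- LETTERS[cumsum(c(TRUE, restart[-1])) |> pmin(26)]
  atoms <- tibble(residue_serial = serial, residue_index = resid,
                  residue_name = resname, bead_name = beadname, chain = chain)
  list(atoms = atoms, coords = cbind(x, y, z), time_ns = time_ns,
       n_lines = nat + 3L)
}

parse_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  nat <- nrow(at)
  resid <- as.integer(at$resno)
  resname <- trimws(at$resid)
  chain <- ifelse(is.na(at$chain) | at$chain == "", "A", at$chain)
  new_res <- c(TRUE, resid[-1] != resid[-nat] | resname[-1] != resname[-nat] |
                 chain[-1] != chain[-nat])
  atoms <- tibble(residue_serial = cumsum(new_res), residue_index = resid,
                  residue_name = resname, bead_name = trimws(at$elety),
                  chain = chain)
  list(atoms = atoms, coords = cbind(at$x, at$y, at$z) / 10, time_ns = 0)
}

#' Write a trajectory (or single frame) as a GRO file
#'
#' Multi-frame trajectories are written as concatenated GRO blocks with the
#' frame time on the title line (`t=` in ps, the GRO convention). Coordinates
#' are written at the format's 3-decimal nm precision.
#'
#' @param trajectory A [droplet_trajectory()].
#' @param path Output path.
#' @param frames Frame indices to write (default all).
#' @return `path`, invisibly.
#' @export
write_gro <- function(trajectory, path, frames = NULL) {
  top <- trajectory$topology
  frames <- frames %||% seq_len(n_frames(trajectory))
  resinfo <- gro_residue_numbering(top)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (f in frames) {
    xyz <- frame_coords(trajectory, f)
    writeLines(sprintf("droplet t= %.4f", trajectory$times_ns[f] * 1000), con)
    writeLines(sprintf("%d", nrow(top)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       resinfo$resid %% 100000L, substr(resinfo$resname, 1, 5),
                       substr(top$bead_name, 1, 5),
                       top$bead_id %% 100000L, xyz[, 1], xyz[, 2], xyz[, 3]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", 20, 20, 20), con)
  }
  invisible(path)
}

# residue numbers/names for writing: lipids numbered per molecule; protein
# residues numbered 1..n within each chain (restart marks the chain break).
gro_residue_numbering <- function(top) {
  resname <- ifelse(top$species == "PROTEIN", top$residue_name, top$species)
  resname[top$species == "WATER"] <- "W"
  isp <- top$species == "PROTEIN"
  resid <- integer(nrow(top))
  if (any(!isp)) {
    mol <- top$molecule_id[!isp]
    resid[!isp] <- match(mol, unique(mol))
  }
  if (any(isp)) resid[isp] <- top$residue_index[isp]
  list(resid = resid, resname = resname)
}

#' Write a single frame as a PDB file
#'
#' Coordinates are converted from nm to \enc{Å}{Angstrom}.
#'
#' @inheritParams write_gro
#' @param frame Frame index to write.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(trajectory, path, frame = 1L) {
  top <- trajectory$topology
  xyz <- frame_coords(trajectory, frame) * 10
  resinfo <- gro_residue_numbering(top)
  ali <- pdb_resname_aliases()
  hit <- resinfo$resname %in% names(ali)
  resinfo$resname[hit] <- unname(ali[resinfo$resname[hit]])
  chain <- ifelse(is.na(top$chain), "A", top$chain)
  bio3d::write.pdb(file = path, xyz = as.vector(t(xyz)),
                   resno = resinfo$resid, resid = resinfo$resname,
                   eleno = top$bead_id, elety = top$bead_name, chain = chain)
  invisible(path)
}
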