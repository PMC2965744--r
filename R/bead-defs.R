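#' Species, moiety and hydrophobicity vocabularies
#'
#' Controlled vocabularies used throughout the package. Lipid species follow
#' the five-component droplet composition (POPC, lyso-type PPC, cholesteryl
#' ester CE, free cholesterol CHOL, triglyceride TG) plus PROTEIN and WATER.
#' Moieties label chemically distinct parts of each lipid (polar headgroup,
#' glycerol backbone, acyl chains, sterol ring, ester linkage, oleate chain).
#'
#' @name vocabularies
#' @keywords internal
NULL

species_levels <- function() {
  c("POPC", "PPC", "CHOL", "CE", "TG", "PROTEIN", "WATER")
}

moiety_levels <- function() {
  c("headgroup", "glycerol", "sn1_chain", "sn2_chain", "sn3_chain",
    "sterol_ring", "sterol_tail", "ester", "oleate_chain",
    "backbone", "sidechain", "other")
}

hydro_levels <- function() c("hydrophobic", "hydrophilic")

# Synthetic apoA-I-like sequence: 243 residues, amphipathic-helix-like
# composition, no Ile or Cys (absent from the human apoA-I sequence), exactly
# 4 Trp. Generated once from a frozen shuffle and stored as a constant; it is
# NOT the human apoA-I sequence.
synthetic_apoa1_sequence <- function() {
  paste0(
    "PDLLRHDVVKDQPWEGTSLLAQVLKRDLSELLLGADPQSKLVAAHELEKNLKRAYEEAAL",
    "LNTQLRKNRLQKFGLEDASKATLKELLVSYRVDQSNLRDDGLADAEYESRLQPEESLKKL",
    "LNDRALRNNGSLAVVLSLTFHQESKLQEPQPHTGKRSHRQWYDERSEKLTGLWKMESYLP",
    "WGAAREPVQFRMFKQEALVMTKEEGGEKETPQQEYTTFSVREKFLLNVAAPNLYKLLKVA",
    "LQD"
  )
}

pdb_resname_aliases <- function() c(POPC = "POP", CHOL = "CHL")

aa1to3 <- function(x) {
  map <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
           E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
           M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
           Y = "TYR", V = "VAL")
  unname(map[x])
}

#' Residue hydrophobicity classification table
#'
#' Default mapping from 3-letter residue names to a two-class hydrophobicity
#' label. Trp, Phe, Val, Leu, Ile, Met and Ala are hydrophobic; all other
#' residues are hydrophilic. Tyr and His sit at the interface-hydrophobicity
#' borderline (Tyr is experimentally comparable to Phe on interfacial scales)
#' but are kept hydrophilic here; the table is editable, so alternative
#' conventions are a one-line change.
#'
#' @return A tibble with columns `residue_name` and `hydro_class`.
#' @export
#' @examples
#' default_hydro_classes()
default_hydro_classes <- function() {
  hydrophobic <- c("TRP", "PHE", "VAL", "LEU", "ILE", "MET", "ALA")
  all_res <- aa1to3(c("A","R","N","D","C","Q","E","G","H","I","L","K",
                      "M","F","P","S","T","W","Y","V"))
  tibble(
    residue_name = all_res,
    hydro_class = ifelse(all_res %in% hydrophobic, "hydrophobic", "hydrophilic")
  )
}

# Internal bead templates: one tibble per lipid species with bead names,
# moieties, and offsets (nm) in a molecule-local frame whose +z axis is the
# molecular axis (headgroup / hydroxyl end up). MARTINI-style bead names.
bead_templates <- function() {
  popc <- tibble(
    bead_name = c("NC3", "PO4", "GL1", "GL2",
                  "C1A", "C2A", "C3A", "C4A",
                  "C1B", "D2B", "C3B", "C4B"),
    moiety = c("headgroup", "headgroup", "glycerol", "glycerol",
               rep("sn1_chain", 4), rep("sn2_chain", 4)),
    x = c(0, 0, 0.12, -0.12, rep(0.12, 4), rep(-0.12, 4)),
    y = c(0, 0, 0.05, 0.05, rep(0.05, 4), rep(0.05, 4)),
    z = c(1.10, 0.80, 0.45, 0.45, 0.15, -0.15, -0.45, -0.75,
          0.15, -0.15, -0.45, -0.75)
  )
  ppc <- tibble(
    bead_name = c("NC3", "PO4", "GL1", "C1A", "C2A", "C3A", "C4A"),
    moiety = c("headgroup", "headgroup", "glycerol", rep("sn1_chain", 4)),
    x = c(0, 0, 0.10, rep(0.10, 4)),
    y = 0,
    z = c(1.10, 0.80, 0.45, 0.15, -0.15, -0.45, -0.75)
  )
  # CHOL ring axis runs R5 (chain-attached ring carbon) -> R1 (hydroxyl-
  # adjacent ring carbon); ROH is the hydroxyl bead, C1/C2 the short tail.
  chol <- tibble(
    bead_name = c("ROH", "R1", "R2", "R3", "R4", "R5", "C1", "C2"),
    moiety = c("sterol_ring", rep("sterol_ring", 5), rep("sterol_tail", 2)),
    x = c(0, 0, 0.15, -0.15, 0.10, 0, 0, 0),
    y = c(0, 0, 0.08, -0.08, -0.08, 0, 0, 0),
    z = c(0.90, 0.55, 0.25, 0.25, -0.10, -0.45, -0.80, -1.10)
  )
  # CE: sterol ring esterified at the hydroxyl position; oleate chain O1..O4
  # hangs off the ester bead. Ring axis R5 -> R1 as for CHOL.
  ce <- tibble(
    bead_name = c("EST", "R1", "R2", "R3", "R4", "R5", "C1", "C2",
                  "O1", "O2", "O3", "O4"),
    moiety = c("ester", rep("sterol_ring", 5), rep("sterol_tail", 2),
               rep("oleate_chain", 4)),
    x = c(0, 0, 0.15, -0.15, 0.10, 0, 0, 0, 0.18, 0.18, 0.18, 0.18),
    y = c(0, 0, 0.08, -0.08, -0.08, 0, 0, 0, 0, 0, 0, 0),
    z = c(0.75, 0.45, 0.20, 0.20, -0.15, -0.55, -0.85, -1.15,
          1.00, 1.30, 1.60, 1.90)
  )
  tg <- tibble(
    bead_name = c("ES1", "ES2", "ES3",
                  paste0("C", 1:4, "A"), paste0("C", 1:4, "B"),
                  paste0("C", 1:4, "C")),
    moiety = c(rep("ester", 3), rep("sn1_chain", 4), rep("sn2_chain", 4),
               rep("sn3_chain", 4)),
    x = c(0.20, -0.20, 0, rep(0.20, 4), rep(-0.20, 4), rep(0, 4)),
    y = c(0.10, 0.10, -0.20, rep(0.10, 4), rep(0.10, 4), rep(-0.20, 4)),
    z = c(0.30, 0.30, 0.30, 0.00, -0.30, -0.60, -0.90,
          0.00, -0.30, -0.60, -0.90, 0.00, -0.30, -0.60, -0.90)
  )
  list(POPC = popc, PPC = ppc, CHOL = chol, CE = ce, TG = tg)
}

#' Default bead-to-species and bead-to-moiety mapping table
#'
#' The mapping that drives species/moiety assignment when structures are read.
#' Rows map a residue name (and optionally a bead name) to a species and
#' moiety. Protein residues are covered generically by the 20 amino-acid
#' residue names; water by `W`/`SOL`. The table is plain data, so dialects
#' with different CG bead naming can supply their own (see
#' [read_bead_map()]).
#'
#' @return A tibble with columns `residue_name`, `bead_name` (`NA` matches any
#'   bead of that residue), `species`, `moiety`.
#' @export
default_bead_map <- function() {
  tpl <- bead_templates()
  lipid <- purrr::imap_dfr(tpl, function(tb, sp) {
    tibble(residue_name = sp, bead_name = tb$bead_name,
           species = sp, moiety = tb$moiety)
  })
  # 3-character PDB dialect aliases (PDB residue-name field is 3 columns)
  ali <- pdb_resname_aliases()
  lipid <- dplyr::bind_rows(lipid, lipid |>
    filter(.data$residue_name %in% names(ali)) |>
    mutate(residue_name = unname(ali[.data$residue_name])))
  aa <- aa1to3(c("A","R","N","D","C","Q","E","G","H","I","L","K",
                 "M","F","P","S","T","W","Y","V"))
  prot <- dplyr::bind_rows(
    tibble(residue_name = aa, bead_name = "BB", species = "PROTEIN",
           moiety = "backbone"),
    tibble(residue_name = aa, bead_name = NA_character_, species = "PROTEIN",
           moiety = "sidechain")
  )
  water <- tibble(residue_name = c("W", "SOL"), bead_name = NA_character_,
                  species = "WATER", moiety = "other")
  dplyr::bind_rows(lipid, prot, water)
}

#' Read a bead mapping table from a plain-text file
#'
#' The file is tab-separated with columns `residue_name`, `bead_name`,
#' `species`, `moiety`; an empty or `NA` `bead_name` matches every bead of the
#' residue. Lines starting with `#` are comments.
#'
#' @param path Path to a TSV mapping file.
#' @return A tibble in the layout of [default_bead_map()].
#' @export
read_bead_map <- function(path) {
  m <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       col_types = readr::cols(.default = "c"))
  needed <- c("residue_name", "bead_name", "species", "moiety")
  assert_that(all(needed %in% names(m)),
              paste("bead map must have columns:", paste(needed, collapse = ", ")))
  bad <- setdiff(unique(m$species), species_levels())
  assert_that(length(bad) == 0,
              paste("unknown species in bead map:", paste(bad, collapse = ", ")))
  as_tibble(m[needed])
}

#' Default axis definitions for ring-bearing and chain lipids
#'
#' Named bead pairs defining each species' molecular axis, drawn tail-to-head:
#' for CHOL from the chain-attached end of the ring (`R5`) to the
#' hydroxyl-adjacent ring bead (`R1`); the CE ring axis is the analogous
#' `R5 -> R1`; the CE oleate chain runs `O1 -> O4`; the POPC P-N vector runs
#' `PO4 -> NC3`. Which topology bead constitutes the ring start is a CG-mapping
#' choice, so the pairs are data, not code.
#'
#' @return A tibble with columns `species`, `axis`, `from`, `to`.
#' @export
default_axis_definitions <- function() {
  tibble(
    species = c("CHOL", "CE", "CE", "POPC", "POPC", "POPC", "PPC"),
    axis = c("ring", "ring", "oleate", "pn", "sn1", "sn2", "sn1"),
    from = c("R5", "R5", "O1", "PO4", "C1A", "C1B", "C1A"),
    to   = c("R1", "R1", "O4", "NC3", "C4A", "C4B", "C4A")
  )
}
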