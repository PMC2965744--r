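#' Root mean square fluctuation of protein beads
#'
#' Computes per-residue RMSF of the selected protein beads:
#' `RMSF_i = sqrt( < |x_i(t) - <x_i>|^2 > )`. By default each frame's
#' selection is first superposed onto the first frame by a least-squares
#' rigid-body fit (Kabsch rotation + translation) over all selected beads
#' jointly — the droplet tumbles freely, and without alignment RMSF would
#' measure rotation, not flexibility.
#'
#' @param trajectory A [droplet_trajectory()] with protein.
#' @param bead_name Protein bead name to select (default `"BB"`, the
#'   backbone bead).
#' @param align Superpose frames before measuring (default `TRUE`; requires
#'   at least 3 beads).
#' @return A tibble with `chain`, `residue_index`, `residue_name`,
#'   `rmsf_nm`.
#' @export
rmsf <- function(trajectory, bead_name = "BB", align = TRUE) {
  assert_that(n_frames(trajectory) >= 2, "need at least 2 frames for RMSF")
  top <- trajectory$topology
  sel <- which(top$species == "PROTEIN" & top$bead_name == bead_name)
  assert_that(length(sel) > 0, paste("no protein beads named", bead_name))
  if (align && length(sel) < 3) {
    abort("alignment needs at least 3 beads (rotation underdetermined)")
  }
  nf <- n_frames(trajectory)
  ref <- matrix(trajectory$coords[1, sel, ], ncol = 3L)
  stack <- array(NA_real_, dim = c(nf, length(sel), 3L))
  for (f in seq_len(nf)) {
    xyz <- matrix(trajectory$coords[f, sel, ], ncol = 3L)
    stack[f, , ] <- if (align) kabsch_fit(xyz, ref) else xyz
  }
  mean_pos <- apply(stack, c(2, 3), mean)
  dev2 <- vapply(seq_len(nf), function(f) {
    rowSums((matrix(stack[f, , ], ncol = 3L) - mean_pos)^2)
  }, numeric(length(sel)))
  if (is.null(dim(dev2))) dev2 <- matrix(dev2, nrow = length(sel))
  tibble(chain = top$chain[sel],
         residue_index = top$residue_index[sel],
         residue_name = top$residue_name[sel],
         rmsf_nm = sqrt(rowMeans(dev2)))
}
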