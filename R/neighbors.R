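#' Bead pairs within a distance cutoff
#'
#' Finds all pairs `(i in A, j in B)` with `|a_i - b_j| < cutoff` (strict
#' inequality). The default cell-list method bins beads into cubic cells of
#' edge `cutoff` and only examines the 27 neighboring cells; it returns
#' exactly the same pairs as the all-pairs method, which is retained as the
#' brute-force oracle.
#'
#' @param xa,xb Coordinate matrices (`n x 3`, nm).
#' @param cutoff_nm Distance cutoff (nm).
#' @param method `"cell"` (default) or `"brute"`.
#' @return A tibble with `i` (row in `xa`), `j` (row in `xb`), `dist_nm`,
#'   sorted by `(i, j)`.
#' @export
neighbor_pairs <- function(xa, xb, cutoff_nm, method = c("cell", "brute")) {
  method <- match.arg(method)
  if (is.null(dim(xa))) xa <- matrix(xa, ncol = 3L)
  if (is.null(dim(xb))) xb <- matrix(xb, ncol = 3L)
  assert_that(cutoff_nm > 0, "cutoff must be > 0")
  if (method == "brute" || nrow(xa) * nrow(xb) <= 10000) {
    return(neighbor_pairs_brute(xa, xb, cutoff_nm))
  }
  cell <- function(m) floor(m / cutoff_nm)
  ca <- cell(xa); cb <- cell(xb)
  tb <- tibble(j = seq_len(nrow(xb)), cx = cb[, 1], cy = cb[, 2], cz = cb[, 3])
  off <- tidyr::expand_grid(ox = -1:1, oy = -1:1, oz = -1:1)
  ta <- tibble(i = seq_len(nrow(xa)), ax = ca[, 1], ay = ca[, 2], az = ca[, 3]) |>
    tidyr::crossing(off) |>
    mutate(cx = .data$ax + .data$ox, cy = .data$ay + .data$oy,
           cz = .data$az + .data$oz)
  cand <- dplyr::inner_join(ta[, c("i", "cx", "cy", "cz")], tb,
                            by = c("cx", "cy", "cz"),
                            relationship = "many-to-many")
  if (nrow(cand) == 0) {
    return(tibble(i = integer(), j = integer(), dist_nm = numeric()))
  }
  d <- sqrt(rowSums((xa[cand$i, , drop = FALSE] - xb[cand$j, , drop = FALSE])^2))
  keep <- d < cutoff_nm
  tibble(i = cand$i[keep], j = cand$j[keep], dist_nm = d[keep]) |>
    arrange(.data$i, .data$j)
}

neighbor_pairs_brute <- function(xa, xb, cutoff_nm) {
  na <- nrow(xa); nb <- nrow(xb)
  if (na == 0 || nb == 0) {
    return(tibble(i = integer(), j = integer(), dist_nm = numeric()))
  }
  d2 <- outer(rowSums(xa^2), rep(1, nb)) + outer(rep(1, na), rowSums(xb^2)) -
    2 * xa %*% t(xb)
  hit <- which(d2 < cutoff_nm^2, arr.ind = TRUE)
  tibble(i = as.integer(hit[, 1]), j = as.integer(hit[, 2]),
         dist_nm = sqrt(pmax(0, d2[hit]))) |>
    arrange(.data$i, .data$j)
}
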