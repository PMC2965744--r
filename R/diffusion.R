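#' Jump-length sample at a fixed lag
#'
#' Collects the magnitudes of center-of-mass displacements
#' `r = |x(t + tau) - x(t)|` over all overlapping frame pairs at lag `tau`,
#' for all molecules of a species (trajectory method) or all walkers (data
#' frame method, as returned by [brownian_on_sphere()] /
#' [brownian_in_ball()]). Surface jumps are chord (3D Euclidean) lengths.
#'
#' @param x A [droplet_trajectory()] or a walker tibble with columns
#'   `walker`, `time_ns`, `x`, `y`, `z`.
#' @param lag_ns Lag time; must be an integer multiple of the frame interval.
#' @param ... Passed to methods.
#' @return An object of class `jump_sample`: list with `r` (nm), `tau_ns`,
#'   `n`, `species`, `region`.
#' @export
jump_lengths <- function(x, lag_ns, ...) UseMethod("jump_lengths")

lag_to_frames <- function(lag_ns, dt, n_frames) {
  k <- lag_ns / dt
  if (abs(k - round(k)) > 1e-6 || round(k) < 1) {
    abort(sprintf(
      "lag %.6g ns is not a frame multiple (frame interval %.6g ns); nearest valid lags: %.6g, %.6g",
      lag_ns, dt, max(1, floor(k)) * dt, ceiling(max(k, 1)) * dt))
  }
  k <- as.integer(round(k))
  assert_that(k < n_frames, "lag exceeds the trajectory length")
  k
}

new_jump_sample <- function(r, tau_ns, species = NA_character_,
                            region = NA_character_) {
  structure(list(r = r, tau_ns = tau_ns, n = length(r), species = species,
                 region = region),
            class = "jump_sample")
}

#' @export
print.jump_sample <- function(x, ...) {
  cat(sprintf("<jump_sample> %d jumps at tau = %.4g ns (species %s)\n",
              x$n, x$tau_ns, x$species))
  invisible(x)
}

#' @rdname jump_lengths
#' @param species Species whose molecule COMs to track.
#' @param region Optional region filter (`"core"`, `"intermediate"`,
#'   `"surface"`); a molecule contributes a pair if it is in the region at
#'   the pair's *start* frame.
#' @param boundaries Region boundaries (nm).
#' @param weights COM weighting (`"uniform"` or `"mass"`).
#' @param com_include_protein Include protein in the particle COM used for
#'   the region filter.
#' @export
jump_lengths.droplet_trajectory <- function(x, lag_ns, species, region = NULL,
                                            boundaries = c(3, 4),
                                            weights = "uniform",
                                            com_include_protein = FALSE, ...) {
  dt <- frame_interval(x)
  k <- lag_to_frames(lag_ns, dt, n_frames(x))
  top <- x$topology
  sel <- which(top$species %in% species)
  assert_that(length(sel) > 0, paste("no molecules of species", species))
  mc <- molecule_coms(x, sel, weights = weights)
  nf <- n_frames(x)
  starts <- seq_len(nf - k)
  assert_that(length(starts) >= 2, "need at least 2 usable frame pairs at this lag")
  keep <- NULL
  if (!is.null(region)) {
    pcom <- particle_com(x, include_protein = com_include_protein)
    keep <- vapply(starts, function(f) {
      r <- row_norms(sweep(matrix(mc$coms[f, , ], ncol = 3L), 2, pcom[f, ]))
      region_label(r, boundaries) == region
    }, logical(dim(mc$coms)[2]))
    if (is.null(dim(keep))) keep <- matrix(keep, nrow = 1)
    keep <- t(keep)  # starts x molecules
  }
  r <- c()
  for (i in seq_along(starts)) {
    f <- starts[i]
    d <- matrix(mc$coms[f + k, , ], ncol = 3L) - matrix(mc$coms[f, , ], ncol = 3L)
    rr <- row_norms(d)
    if (!is.null(keep)) rr <- rr[keep[i, ]]
    r <- c(r, rr)
  }
  new_jump_sample(r, k * dt, species = paste(species, collapse = "+"),
                  region = region %||% NA_character_)
}

#' @rdname jump_lengths
#' @export
jump_lengths.data.frame <- function(x, lag_ns, ...) {
  assert_that(all(c("walker", "time_ns", "x", "y", "z") %in% names(x)),
              "walker tibble needs columns walker, time_ns, x, y, z")
  x <- dplyr::arrange(x, .data$walker, .data$time_ns)
  tms <- sort(unique(x$time_ns))
  dt <- tms[2] - tms[1]
  k <- lag_to_frames(lag_ns, dt, length(tms))
  r <- x |>
    group_by(.data$walker) |>
    reframe(r = sqrt((dplyr::lead(.data$x, k) - .data$x)^2 +
                       (dplyr::lead(.data$y, k) - .data$y)^2 +
                       (dplyr::lead(.data$z, k) - .data$z)^2)) |>
    dplyr::pull(r)
  new_jump_sample(r[!is.na(r)], k * dt, species = "walker")
}

# Free-diffusion jump-length densities (the "two types of Gaussian
# functions"): in 2D, P(r) = r/(2 D tau) exp(-r^2 / (4 D tau)); in 3D,
# P(r) = 4 pi r^2 (4 pi D tau)^(-3/2) exp(-r^2 / (4 D tau)).
propagator_density <- function(r, D, tau, dimension) {
  s <- 4 * D * tau
  if (dimension == 2) {
    2 * r / s * exp(-r^2 / s)
  } else {
    4 * pi * r^2 * (pi * s)^(-3 / 2) * exp(-r^2 / s)
  }
}

#' Fit 2D and 3D free-diffusion propagators to a jump-length sample
#'
#' Least-squares fits of the two candidate jump-length densities to the
#' normalized histogram of the sample; the fit with the lower residual sum
#' of squares decides the dimensionality, and its `D` is reported. The 2D
#' form describes lateral diffusion along the lipid-water interface, the 3D
#' form isotropic diffusion in the particle core.
#'
#' @param sample A [jump_lengths()] sample.
#' @param n_bins Histogram bins (default 100).
#' @param min_jumps Minimum sample size (default 500).
#' @return An object of class `diffusion_fit` with elements `D` (nm^2/ns),
#'   `dimension` (2 or 3), `residuals` (named, both candidates),
#'   `D_candidates`, `tau_ns`, `n`, `species`, `region`, `histogram`.
#' @export
fit_propagator <- function(sample, n_bins = 100, min_jumps = 500) {
  assert_that(inherits(sample, "jump_sample"), "sample must be a jump_sample")
  r <- sample$r
  assert_that(length(r) >= min_jumps,
              sprintf("need >= %d jumps, got %d", min_jumps, length(r)))
  if (max(r) < 1e-12) abort("degenerate jump sample: all displacements are zero")
  tau <- sample$tau_ns
  edges <- seq(0, max(r) * (1 + 1e-9), length.out = n_bins + 1L)
  dl <- edges[2] - edges[1]
  counts <- tabulate(pmin(n_bins, findInterval(r, edges)), nbins = n_bins)
  dens <- counts / (length(r) * dl)
  ctr <- (edges[-1] + edges[-length(edges)]) / 2
  m2 <- mean(r^2)
  fit_one <- function(dimension) {
    d0 <- m2 / (2 * dimension * tau)
    obj <- function(ld) sum((propagator_density(ctr, 10^ld, tau, dimension) - dens)^2)
    o <- optimize(obj, interval = log10(d0) + c(-2, 2), tol = 1e-10)
    list(D = 10^o$minimum, ssr = o$objective)
  }
  f2 <- fit_one(2); f3 <- fit_one(3)
  dim_best <- if (f2$ssr <= f3$ssr) 2L else 3L
  structure(
    list(D = if (dim_best == 2) f2$D else f3$D, dimension = dim_best,
         residuals = c(`2` = f2$ssr, `3` = f3$ssr),
         D_candidates = c(`2` = f2$D, `3` = f3$D),
         tau_ns = tau, n = length(r), species = sample$species,
         region = sample$region,
         histogram = tibble(r = ctr, density = dens)),
    class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf(
    "<diffusion_fit> D = %.4g nm^2/ns (%dd fit; residuals 2d %.3g / 3d %.3g; n = %d, tau = %.4g ns)\n",
    x$D, x$dimension, x$residuals[["2"]], x$residuals[["3"]], x$n, x$tau_ns))
  invisible(x)
}

#' Diffusion coefficient versus lag time, with plateau diagnostic
#'
#' Runs [jump_lengths()] + [fit_propagator()] at each requested lag and flags
#' a plateau when the fitted `D(tau)` varies by less than 10% (relative
#' range) over the final half of the lag grid — the signature of genuinely
#' diffusive (hydrodynamic-limit) behavior, which for these particles sets
#' in at lags of the order of 100 ns.
#'
#' @param x Trajectory or walker tibble (see [jump_lengths()]).
#' @param lags_ns Vector of at least 3 lags.
#' @param flatness Relative variation defining a plateau (default 0.1).
#' @param ... Passed to [jump_lengths()] (e.g. `species`, `region`).
#' @return A tibble of class `diffusion_profile` with `lag_ns`, `D`,
#'   `dimension`, `resid_2d`, `resid_3d`, `n`; the plateau flag is in
#'   `attr(, "plateau")`.
#' @export
diffusion_vs_lag <- function(x, lags_ns, flatness = 0.1, ...) {
  assert_that(length(lags_ns) >= 3, "need at least 3 lags")
  lags_ns <- sort(lags_ns)
  rows <- purrr::map_dfr(lags_ns, function(lg) {
    ft <- fit_propagator(jump_lengths(x, lg, ...))
    tibble(lag_ns = lg, D = ft$D, dimension = ft$dimension,
           resid_2d = ft$residuals[["2"]], resid_3d = ft$residuals[["3"]],
           n = ft$n)
  })
  half <- rows$D[seq(ceiling(nrow(rows) / 2), nrow(rows))]
  plateau <- (max(half) - min(half)) / mean(half) < flatness
  attr(rows, "plateau") <- plateau
  attr(rows, "flatness") <- flatness
  class(rows) <- c("diffusion_profile", class(rows))
  rows
}

#' Dimension-normalized diffusion table
#'
#' Scales each fitted coefficient by the MSD-slope factor `2 d` (so that 2D
#' and 3D fits are comparable: the scaled value is the slope of the mean
#' squared displacement), alongside each species' mean COM radius. An
#' identity scale is available for reporting raw coefficients.
#'
#' @param fits A list of [fit_propagator()] results (or a single one).
#' @param mean_radius_nm Optional named vector of mean COM radii per species.
#' @param scale `"msd"` (`D * 2 d`) or `"identity"`.
#' @return A tibble with `species`, `region`, `dimension`, `D`, `D_scaled`,
#'   `r_mean_nm`.
#' @export
normalized_profile <- function(fits, mean_radius_nm = NULL,
                               scale = c("msd", "identity")) {
  scale <- match.arg(scale)
  if (inherits(fits, "diffusion_fit")) fits <- list(fits)
  assert_that(length(fits) > 0, "fits must be non-empty")
  purrr::map_dfr(fits, function(ft) {
    fac <- if (scale == "msd") 2 * ft$dimension else 1
    tibble(species = ft$species, region = ft$region,
           dimension = ft$dimension, D = ft$D, D_scaled = ft$D * fac,
           r_mean_nm = if (!is.null(mean_radius_nm) && ft$species %in% names(mean_radius_nm))
             mean_radius_nm[[ft$species]] else NA_real_)
  })
}
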