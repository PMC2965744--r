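#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a jump-length sample into its histogram
#'
#' @param x A [jump_lengths()] sample.
#' @param n_bins Histogram bins.
#' @param ... Unused.
#' @return A tibble with `r` (bin center, nm) and `density` (nm^-1).
#' @exportS3Method generics::tidy
tidy.jump_sample <- function(x, n_bins = 100, ...) {
  edges <- seq(0, max(x$r) * (1 + 1e-9), length.out = n_bins + 1L)
  dl <- edges[2] - edges[1]
  counts <- tabulate(pmin(n_bins, findInterval(x$r, edges)), nbins = n_bins)
  tibble(r = (edges[-1] + edges[-length(edges)]) / 2,
         density = counts / (length(x$r) * dl))
}

#' @exportS3Method generics::glance
glance.jump_sample <- function(x, ...) {
  tibble(tau_ns = x$tau_ns, n = x$n, mean_r2_nm2 = mean(x$r^2),
         species = x$species, region = x$region)
}

#' Tidy / glance methods for diffusion fits
#'
#' `tidy()` returns the fitted histogram with both candidate model curves;
#' `glance()` a one-row fit summary.
#'
#' @param x A [fit_propagator()] result.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.diffusion_fit <- function(x, ...) {
  h <- x$histogram
  h$fit_2d <- propagator_density(h$r, x$D_candidates[["2"]], x$tau_ns, 2)
  h$fit_3d <- propagator_density(h$r, x$D_candidates[["3"]], x$tau_ns, 3)
  h
}

#' @rdname tidy.diffusion_fit
#' @exportS3Method generics::glance
glance.diffusion_fit <- function(x, ...) {
  tibble(D = x$D, dimension = x$dimension,
         resid_2d = x$residuals[["2"]], resid_3d = x$residuals[["3"]],
         tau_ns = x$tau_ns, n = x$n, species = x$species, region = x$region)
}

#' Tidy / glance methods for lifetime statistics
#'
#' `tidy()` returns the full dwell table (one row per merged interval);
#' `glance()` the mean contact / non-contact lifetimes with and without
#' censored intervals.
#'
#' @param x A [contact_lifetimes()] result.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.lifetime_stats <- function(x, ...) x$dwells

#' @rdname tidy.lifetime_stats
#' @exportS3Method generics::glance
glance.lifetime_stats <- function(x, ...) {
  tibble(mean_on_ns = x$mean_on_ns, mean_off_ns = x$mean_off_ns,
         mean_on_all_ns = x$mean_on_all_ns, mean_off_all_ns = x$mean_off_all_ns,
         n_on = sum(x$dwells$state & !x$dwells$censored),
         n_off = sum(!x$dwells$state & !x$dwells$censored),
         n_censored = sum(x$dwells$censored),
         tolerance_frames = x$tolerance_frames, dt_ns = x$dt_ns)
}

#' @exportS3Method generics::glance
glance.sasa_result <- function(x, ...) {
  tot <- x$totals
  tibble(total_nm2 = tot[["total"]], hydrophobic_nm2 = tot[["hydrophobic"]],
         hydrophilic_nm2 = tot[["hydrophilic"]],
         hydrophobic_pct = 100 * tot[["hydrophobic"]] / tot[["total"]],
         hydrophilic_pct = 100 * tot[["hydrophilic"]] / tot[["total"]],
         probe_nm = x$probe_nm, n_points = x$n_points)
}
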