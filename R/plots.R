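#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col geom_raster
#'   geom_point labs theme_minimal scale_fill_viridis_c facet_wrap
#' @export
ggplot2::autoplot

#' Plot a radial density profile
#'
#' @param object A [radial_density()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.radial_profile <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$r, y = .data$density,
                                colour = .data$species)) +
    geom_line() +
    labs(x = "distance from particle COM (nm)",
         y = expression(number ~ density ~ (nm^-3)), colour = NULL) +
    theme_minimal()
}

#' Plot an order parameter profile
#'
#' Unreliable bins (below the minimum sample count) are drawn hollow.
#'
#' @param object An [order_parameter_profile()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.order_profile <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$r, y = .data$S)) +
    geom_line() +
    geom_point(aes(shape = .data$reliable)) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                guide = "none") +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    labs(x = "axis midpoint distance from particle COM (nm)",
         y = expression(S == group("<", (3 * cos^2 * theta - 1) / 2, ">")),
         title = attr(object, "species")) +
    theme_minimal()
}

#' Plot a conformational (theta, phi) map
#'
#' @param object A [conformation_map()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.conformation_map <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$theta_deg, y = .data$phi_deg,
                                fill = .data$prob)) +
    geom_raster() +
    scale_fill_viridis_c() +
    labs(x = "ring axis vs effective normal (deg)",
         y = "ring axis vs chain (deg)", fill = "probability",
         title = paste(attr(object, "species"),
                       attr(object, "region") %||% "all regions")) +
    theme_minimal()
}

#' Plot fitted diffusion coefficient versus lag
#'
#' @param object A [diffusion_vs_lag()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.diffusion_profile <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$lag_ns, y = .data$D)) +
    geom_line() + geom_point(aes(colour = factor(.data$dimension))) +
    ggplot2::scale_x_log10() +
    labs(x = "lag (ns)", y = expression(D ~ (nm^2 / ns)),
         colour = "fit dimension",
         subtitle = if (isTRUE(attr(object, "plateau")))
           "plateau: D(tau) level at long lags" else "no plateau") +
    theme_minimal()
}

#' Plot a diffusion fit against its jump-length histogram
#'
#' @param object A [fit_propagator()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.diffusion_fit <- function(object, ...) {
  h <- tidy(object) |>
    tidyr::pivot_longer(c("fit_2d", "fit_3d"), names_to = "model",
                        values_to = "fit")
  ggplot(h, aes(x = .data$r)) +
    geom_col(aes(y = .data$density), width = diff(h$r[1:2]),
             fill = "grey80") +
    geom_line(aes(y = .data$fit, colour = .data$model)) +
    labs(x = "jump length (nm)", y = "probability density",
         title = sprintf("D = %.3g nm^2/ns (%dd)", object$D, object$dimension)) +
    theme_minimal()
}

#' Plot per-residue RMSF profiles per chain
#'
#' @param object An [rmsf()] result tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_rmsf <- function(object, ...) {
  ggplot(object, aes(x = .data$residue_index, y = .data$rmsf_nm,
                     colour = .data$chain)) +
    geom_line() +
    labs(x = "residue", y = "RMSF (nm)", colour = "chain") +
    theme_minimal()
}

#' Plot annular-lipid counts over time
#'
#' @param record A [contact_record()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_annular_counts <- function(record, ...) {
  df <- purrr::map_dfr(unique(record$species), function(sp) {
    cols <- which(record$species == sp)
    tibble(time_ns = record$times_ns, species = sp,
           n_annular = rowSums(record$state[, cols, drop = FALSE]))
  })
  ggplot(df, aes(x = .data$time_ns, y = .data$n_annular,
                 colour = .data$species)) +
    geom_line() +
    labs(x = "time (ns)", y = "annular molecules", colour = NULL) +
    theme_minimal()
}
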