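#' Plot a DEC run's latent space
#'
#' Scatter of the first two latent coordinates coloured by hard cluster
#' label, with centroids overplotted.
#'
#' @param object an `ra_dec_run`.
#' @param dims which two latent dimensions to show.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ra_dec_run <- function(object, dims = c(1, 2), ...) {
  df <- tibble::tibble(x = object$Z[, dims[1]], y = object$Z[, dims[2]],
                       cluster = factor(object$labels))
  cen <- tibble::tibble(x = object$centroids[, dims[1]],
                        y = object$centroids[, dims[2]])
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   colour = .data$cluster)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_point(data = cen, ggplot2::aes(.data$x, .data$y),
                        inherit.aes = FALSE, shape = 4, size = 4,
                        stroke = 1.5) +
    ggplot2::labs(
      x = sprintf("latent dim %d", dims[1]),
      y = sprintf("latent dim %d", dims[2]),
      title = sprintf("DEC, k = %d (silhouette %.2f)", object$k,
                      object$silhouette)) +
    ggplot2::theme_minimal()
}

#' Forest plot of effect estimates
#'
#' @param estimates a tibble from [fit_cox()], [per_cluster_effects()] or
#'   `tidy()` on a validation result (needs `exposure`, `hr`, `ci_low`,
#'   `ci_high`; suppressed rows are dropped).
#' @param hr_col,lo_col,hi_col column names for the point estimate and CI
#'   (defaults suit crude estimates; use `"hr_adj"` etc. for adjusted).
#' @return A ggplot object.
#' @export
plot_effects <- function(estimates, hr_col = "hr", lo_col = "ci_low",
                         hi_col = "ci_high") {
  df <- estimates[!is.na(estimates[[hr_col]]), ]
  df$facet <- if ("outcome_type" %in% names(df)) df$outcome_type else ""
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[hr_col]],
                                   y = .data$exposure)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data[[lo_col]],
                                         xmax = .data[[hi_col]]),
                            height = 0.2) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~facet) +
    ggplot2::labs(x = "hazard ratio (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot cluster profiles as a heatmap of standardized means
#'
#' @param profiles output of [profile_clusters()].
#' @param run_id which run to show.
#' @return A ggplot object.
#' @export
plot_profiles <- function(profiles, run_id) {
  df <- profiles[profiles$run_id == run_id, ]
  # scale each feature's cluster means to [0, 1] across clusters for display
  df <- df |>
    dplyr::group_by(.data$feature) |>
    dplyr::mutate(rel = if (max(.data$value, na.rm = TRUE) >
                            min(.data$value, na.rm = TRUE)) {
      (.data$value - min(.data$value, na.rm = TRUE)) /
        (max(.data$value, na.rm = TRUE) - min(.data$value, na.rm = TRUE))
    } else 0.5) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$cluster), .data$feature,
                                   fill = .data$rel)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "relative\nlevel") +
    ggplot2::labs(x = "cluster", y = NULL, title = run_id) +
    ggplot2::theme_minimal()
}
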