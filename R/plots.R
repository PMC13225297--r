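condition_labels <- c(
  opaque = "Opaque",
  semi_transparent = "Semi-transparent",
  highly_transparent = "Highly transparent",
  absent = "Surface absent"
)

#' Plot mean matched distance against target distance
#'
#' The standard depth-matching figure: per-condition mean matches as a
#' function of target distance, the identity line for veridical matching,
#' a vertical marker at the surface position, and within-subject CI error
#' bars when present in the summary.
#'
#' @param summaries A [summarize_matches()] result.
#' @param surface_distance_m Surface position marker (meters); `NULL` to
#'   omit.
#' @return A ggplot object.
#' @export
plot_matches <- function(summaries, surface_distance_m = 1.2) {
  stopifnot(all(c("condition", "target_distance_m", "mean_matched_m")
                %in% names(summaries)))
  d <- dplyr::mutate(summaries, condition = order_conditions(.data$condition))
  p <- ggplot2::ggplot(d, ggplot2::aes(
    x = .data$target_distance_m, y = .data$mean_matched_m,
    colour = .data$condition, group = .data$condition
  )) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey30")
  if (!is.null(surface_distance_m)) {
    p <- p + ggplot2::geom_vline(xintercept = surface_distance_m,
                                 colour = "grey70", linewidth = 2,
                                 alpha = 0.5)
  }
  if ("ci_halfwidth_m" %in% names(d) && any(!is.na(d$ci_halfwidth_m))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_matched_m - .data$ci_halfwidth_m,
                   ymax = .data$mean_matched_m + .data$ci_halfwidth_m),
      width = 0.015
    )
  }
  p +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_viridis_d(labels = condition_labels, end = 0.9) +
    ggplot2::labs(x = "Target distance (m)", y = "Matched distance (m)",
                  colour = "Surface") +
    ggplot2::theme_minimal()
}

#' Plot signed differences from the surface-absent baseline
#'
#' @param differences A [signed_difference()] result.
#' @param surface_distance_m Surface position marker (meters); `NULL` to
#'   omit.
#' @return A ggplot object.
#' @export
plot_signed_differences <- function(differences, surface_distance_m = 1.2) {
  stopifnot(all(c("condition", "target_distance_m", "difference_m")
                %in% names(differences)))
  d <- dplyr::mutate(differences,
                     condition = order_conditions(.data$condition))
  p <- ggplot2::ggplot(d, ggplot2::aes(
    x = .data$target_distance_m, y = .data$difference_m,
    colour = .data$condition, group = .data$condition
  )) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey30")
  if (!is.null(surface_distance_m)) {
    p <- p + ggplot2::geom_vline(xintercept = surface_distance_m,
                                 colour = "grey70", linewidth = 2,
                                 alpha = 0.5)
  }
  p +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_viridis_d(labels = condition_labels, end = 0.9) +
    ggplot2::labs(x = "Target distance (m)",
                  y = "Baseline - condition match (m)",
                  colour = "Surface") +
    ggplot2::theme_minimal()
}

#' Plot the cue-integration components for one configuration
#'
#' Shows the occlusion prior, disparity likelihood, and resulting posterior
#' on the distance grid for a single target/surface configuration — the
#' model's workflow in one picture. Curves are peak-normalized for shared
#' axes; markers show the disparity-specified distance and the posterior
#' mode.
#'
#' @inheritParams predict_match
#' @return A ggplot object.
#' @export
plot_cue_integration <- function(mu_disp, sigma_disp, mu_surf, sigma_surf,
                                 sigma_opacity, grid = distance_grid()) {
  g <- as_grid_values(grid)
  prior <- prior_values(g, mu_surf, sigma_surf, sigma_opacity)
  lik <- stats::dnorm(g, mu_disp, sigma_disp)
  post <- prior * lik
  mode <- g[which.max(post)]
  d <- tibble::tibble(
    distance_m = rep(g, 3),
    value = c(prior / max(prior), lik / max(lik), post / max(post)),
    component = rep(c("Occlusion prior", "Disparity likelihood", "Posterior"),
                    each = length(g))
  )
  d$component <- factor(d$component, levels = c("Occlusion prior",
                                                "Disparity likelihood",
                                                "Posterior"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$distance_m, y = .data$value,
                                  colour = .data$component)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = mu_disp, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_vline(xintercept = mode, linetype = "dotted",
                        colour = "black") +
    ggplot2::labs(x = "Distance (m)", y = "Normalized value",
                  colour = NULL,
                  subtitle = sprintf(
                    "Disparity-specified %.2f m; predicted match %.3f m",
                    mu_disp, mode)) +
    ggplot2::theme_minimal()
}

#' Plot fitted fall-off parameters per condition
#'
#' Condition means of the fitted `sigma_opacity` with standard-error bars,
#' plus individual observers' fits as light points: the model-level summary
#' of how surface opacity modulates the occlusion prior.
#'
#' @param object An [fit_panel()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.occlusion_fit <- function(object, ...) {
  cm <- dplyr::mutate(object$condition_means,
                      condition = order_conditions(.data$condition))
  obs <- dplyr::mutate(object$sigma_opacity,
                       condition = order_conditions(.data$condition))
  ggplot2::ggplot(cm, ggplot2::aes(x = .data$condition,
                                   y = .data$mean_sigma_opacity)) +
    ggplot2::geom_jitter(
      data = obs,
      ggplot2::aes(y = .data$sigma_opacity),
      width = 0.08, colour = "grey70", size = 1.5
    ) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_sigma_opacity - .data$sem,
      ymax = .data$mean_sigma_opacity + .data$sem
    )) +
    ggplot2::scale_x_discrete(labels = condition_labels) +
    ggplot2::labs(x = NULL,
                  y = expression(sigma[opacity] ~ "(m)")) +
    ggplot2::theme_minimal()
}
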