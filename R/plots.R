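# ggplot2 visualisations for the main result types.

#' @describeIn assign_phase_bins Plot a phase-binned trace, accepted
#'   (expiration) samples highlighted.
#' @param object A `resp_phase` tibble.
#' @param ... Unused.
#' @export
autoplot.resp_phase <- function(object, ...) {
  df <- dplyr::mutate(object, state = dplyr::case_when(
    .data$bin == 0L ~ "unassigned",
    .data$accepted ~ "accepted",
    TRUE ~ "rejected"
  ))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$amplitude)) +
    ggplot2::geom_line(colour = "grey60", linewidth = 0.3) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$state), size = 0.8) +
    ggplot2::scale_colour_manual(values = c(
      accepted = "#1b9e77", rejected = "#d95f02", unassigned = "grey75"
    )) +
    ggplot2::labs(x = "time [s]", y = "amplitude",
                  colour = NULL,
                  title = "Respiratory phase binning (bins 41-100 accepted)") +
    ggplot2::theme_minimal()
}

#' @describeIn bland_altman Bland-Altman plot: paired differences against
#'   pair means with bias and 95% limits of agreement.
#' @param object A `bland_altman` object.
#' @param ... Unused.
#' @export
autoplot.bland_altman <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$bias, colour = "#1b9e77") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed", colour = "#d95f02") +
    ggplot2::labs(x = "mean of pair", y = "difference",
                  title = "Bland-Altman agreement") +
    ggplot2::theme_minimal()
}

#' Cohort signal-amplitude boxplots
#'
#' Draws per-subject boxplots (quartiles, 1.5 x IQR whiskers, raw extremes as
#' points) from [summarize_signal()] rows, faceted by modality, to show how
#' amplitude ranges spread across a cohort.
#'
#' @param summaries A tibble of [summarize_signal()] rows.
#' @return A ggplot object.
#' @export
plot_signal_summaries <- function(summaries) {
  ggplot2::ggplot(summaries, ggplot2::aes(x = .data$subject_id)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$w_low, ymax = .data$w_up),
                           width = 0.25, colour = "grey40") +
    ggplot2::geom_crossbar(
      ggplot2::aes(y = .data$q2, ymin = .data$q1, ymax = .data$q3),
      fill = "grey90", width = 0.6
    ) +
    ggplot2::geom_point(ggplot2::aes(y = .data$min), shape = 4, size = 1) +
    ggplot2::geom_point(ggplot2::aes(y = .data$max), shape = 4, size = 1) +
    ggplot2::facet_wrap(~modality, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "amplitude",
                  title = "Signal amplitude summaries per subject") +
    ggplot2::theme_minimal()
}

#' Line profiles and their sigmoid fits
#'
#' Overlays a sample of through-edge line profiles with the fitted logistic
#' curves, for eyeballing LLE fits.
#'
#' @param volume A `phantom_volume` or 4D array.
#' @param roi A [roi_spec()].
#' @param n_show Number of profiles to draw.
#' @return A ggplot object.
#' @export
plot_profile_fits <- function(volume, roi, n_show = 8) {
  profs <- extract_profiles(volume, roi)
  take <- unique(round(seq(1, ncol(profs), length.out = n_show)))
  df <- purrr::map_dfr(take, function(j) {
    p <- profs[, j]
    fit <- fit_sigmoid_profile(p)
    z <- seq_along(p)
    yhat <- if (fit$converged) {
      fit$b + fit$a / (1 + exp(-(z - fit$z0) / fit$w))
    } else rep(NA_real_, length(z))
    tibble(profile = factor(j), z = z, intensity = p, fitted = yhat)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z, group = .data$profile)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$intensity), size = 0.6, alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "#1b9e77") +
    ggplot2::labs(x = "z [voxel]", y = "intensity [a.u.]",
                  title = "Liver-lung edge profiles and sigmoid fits") +
    ggplot2::theme_minimal()
}
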