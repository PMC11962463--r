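#' Plot posterior intervals of the modulation weights
#'
#' @param object An [fit_joint_model()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ema_joint_fit <- function(object, ...) {
  d <- filter(object$summary, .data$term %in% object$data$beta_names)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$hdi_low, xmax = .data$hdi_high),
      height = 0.15) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "posterior mean (90% HDI)", y = NULL,
                  title = "State and trait modulation of choice sensitivities") +
    ggplot2::theme_minimal()
}

#' Plot generating versus recovered parameter values
#'
#' @param object An [run_parameter_recovery()] report.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ema_recovery_report <- function(object, ...) {
  lab <- object$report |>
    mutate(label = sprintf("r = %.2f", .data$r))
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$truth, y = .data$est)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.3, size = 0.7) +
    ggplot2::geom_text(data = lab, ggplot2::aes(label = .data$label),
                       x = -Inf, y = Inf, hjust = -0.2, vjust = 1.5) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "generating value", y = "posterior mean",
                  title = "Parameter recovery") +
    ggplot2::theme_minimal()
}

#' Plot the group-mean state autocorrelation profile
#'
#' @param object A `summary_acf` result from [state_autocorrelation()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ema_acf <- function(object, ...) {
  ggplot2::ggplot(object$summary, ggplot2::aes(x = factor(.data$lag),
                                               y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.15) +
    ggplot2::labs(x = "lag (occasions)", y = "mean autocorrelation",
                  title = "State motivation inertia") +
    ggplot2::theme_minimal()
}

#' Plot a participant's state series with game occasions marked
#'
#' @param cohort An [ema_cohort()].
#' @param participants Character vector of participant ids (default: first 4).
#' @return A ggplot.
#' @export
plot_state_series <- function(cohort, participants = NULL) {
  sc <- state_scores(cohort) |> filter(.data$valid)
  if (is.null(participants)) {
    participants <- head(unique(sc$participant_id), 4)
  }
  sc <- filter(sc, .data$participant_id %in% participants)
  games <- cohort$trials |>
    distinct(.data$participant_id, .data$occasion_index) |>
    filter(.data$participant_id %in% participants) |>
    inner_join(sc, by = c("participant_id", "occasion_index"))
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$occasion_index,
                                   y = .data$state_sum)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_point(data = games, colour = "darkorange", size = 2,
                        shape = 17) +
    ggplot2::facet_wrap(~participant_id) +
    ggplot2::labs(x = "occasion", y = "state motivation (sum score)",
                  title = "State reports (triangles: game occasions)") +
    ggplot2::theme_minimal()
}
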