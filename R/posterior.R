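#' Highest-density interval of a posterior sample
#'
#' The shortest contiguous interval covering the requested posterior mass:
#' with `n` sorted samples and window `g = ceiling(mass * n)`, all intervals
#' `[x[i], x[i + g]]` are enumerated and the narrowest returned; ties go to
#' the leftmost window.
#'
#' @param samples Numeric vector, at least 20 values.
#' @param mass Probability mass in (0, 1), default 0.90.
#' @return Length-2 numeric `c(lower, upper)`.
#' @examples
#' hdi(1:100, 0.90)  # [1, 91]
#' @export
hdi <- function(samples, mass = 0.90) {
  samples <- samples[!is.na(samples)]
  n <- length(samples)
  if (n < 20) abort("insufficient samples for an HDI (need >= 20)")
  if (mass <= 0 || mass >= 1) abort("mass must be in (0, 1)")
  xs <- sort(samples)
  gap <- ceiling(mass * n)
  if (gap >= n) abort("insufficient samples for the requested mass")
  widths <- xs[(gap + 1):n] - xs[1:(n - gap)]
  i <- which.min(widths)  # which.min takes the leftmost tie
  c(xs[i], xs[i + gap])
}

#' Probability of direction
#'
#' The proportion of posterior samples sharing the sign of the posterior
#' median - a posterior certainty-of-existence index in `[0.5, 1]`. Exact
#' zeros are counted with the median's sign; when the median is exactly
#' zero the majority sign's fraction is returned with a warning.
#'
#' @param samples Numeric vector, at least 20 values.
#' @return A proportion.
#' @examples
#' probability_of_direction(c(-1, 2, 3, 4, 5, 6, 7, 8, 9, 10,
#'                            11, 12, 13, 14, 15, 16, 17, 18, 19, 20))
#' @export
probability_of_direction <- function(samples) {
  samples <- samples[!is.na(samples)]
  if (length(samples) < 20) abort("insufficient samples (need >= 20)")
  med <- median(samples)
  s <- sign(med)
  if (s == 0) {
    warn("posterior median is exactly zero; returning the majority sign fraction")
    return(max(mean(samples > 0), mean(samples < 0)))
  }
  mean(samples * s > 0 | samples == 0)
}

#' Posterior summary of a draw vector
#'
#' @param samples Numeric vector of posterior draws.
#' @param term Optional label.
#' @param mass HDI mass.
#' @return One-row tibble: mean, sd, HDI bounds, probability of direction.
#' @export
posterior_summary <- function(samples, term = "parameter", mass = 0.90) {
  h <- hdi(samples, mass)
  tibble(term = term, mean = mean(samples), sd = sd(samples),
         hdi_low = h[1], hdi_high = h[2],
         p_direction = probability_of_direction(samples))
}

#' Posterior-predictive accuracy of the joint model
#'
#' Predicts each observation's modal outcome under the posterior-mean
#' parameters - choices from the per-cell posterior-mean sensitivities,
#' item endorsements from the posterior-mean latent state and difficulties -
#' and reports the fraction matched, aggregated per participant and then
#' averaged with its SEM.
#'
#' @param fit An [fit_joint_model()] result.
#' @return A list of class `ema_ppc`: `per_participant` tibble and
#'   `summary` tibble (`outcome`, `accuracy`, `sem`).
#' @export
posterior_predictive_accuracy <- function(fit) {
  data <- fit$data
  delta_mean <- colMeans(fit$hyper_draws[, paste0("delta", seq_len(data$M)),
                                         drop = FALSE])
  th <- fit$theta_mean[cbind(data$item_i + 1L, data$item_t + 1L)]
  p_item <- irt_endorsement_probability(th, delta_mean[data$item_m + 1L])
  item_hit <- as.integer(p_item > 0.5) == data$item_y

  cm <- fit$cell_means
  v <- cm$rew_sens[data$ch_cell + 1L] * data$ch_dr -
    cm$eff_sens[data$ch_cell + 1L] * data$ch_de
  choice_hit <- as.integer(v > 0) == data$ch_y

  per <- bind_rows(
    tibble(participant_id = data$ids[data$item_i + 1L],
           outcome = "endorsement", hit = item_hit),
    tibble(participant_id = data$ids[data$cell_i[data$ch_cell + 1L] + 1L],
           outcome = "choice", hit = choice_hit)
  ) |>
    group_by(.data$participant_id, .data$outcome) |>
    summarise(accuracy = mean(.data$hit), n = n(), .groups = "drop")
  summary <- per |>
    group_by(.data$outcome) |>
    summarise(accuracy = mean(.data$accuracy),
              sem = sd(.data$accuracy) / sqrt(n()), n = n(), .groups = "drop")
  structure(list(per_participant = per, summary = summary), class = "ema_ppc")
}

#' @export
print.ema_ppc <- function(x, ...) {
  cat("Posterior-predictive accuracy (modal prediction):\n")
  print(x$summary)
  invisible(x)
}
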