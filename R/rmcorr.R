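#' Repeated-measures (within-person) correlation
#'
#' Estimates the common within-person association between two repeatedly
#' measured variables by the analysis-of-covariance decomposition: `y` is
#' regressed on participant indicators plus a single shared slope for `x`,
#' and the correlation is `sign(slope) * sqrt(SS_x / (SS_x + SS_error))`.
#' This removes between-person differences and so respects the
#' non-independence of occasion-level data.
#'
#' Degrees of freedom follow the convention `n_pairs - n_participants - 1`,
#' the p-value is from the t distribution on those df, and the confidence
#' interval uses the normal approximation on the Fisher z-transform with
#' standard error `1 / sqrt(df - 1)`.
#'
#' @param data A data frame in long format.
#' @param x,y Column names (unquoted or character) of the paired measures.
#' @param id Column name of the participant identifier.
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row tibble of class `ema_rmcorr`: `r`, `df`, `conf.low`,
#'   `conf.high`, `p.value`, `n_pairs`, `n_participants`.
#' @examples
#' d <- data.frame(
#'   id = rep(1:3, each = 4),
#'   x = c(1, 2, 3, 4, 2, 3, 4, 5, 0, 1, 2, 3)
#' )
#' d$y <- d$x + rep(c(0, 5, 10), each = 4)
#' repeated_measures_correlation(d, x, y, id)
#' @export
repeated_measures_correlation <- function(data, x, y, id, conf_level = 0.95) {
  xs <- rlang::as_name(rlang::enquo(x))
  ys <- rlang::as_name(rlang::enquo(y))
  ids <- rlang::as_name(rlang::enquo(id))
  rmcorr_compute(data[[xs]], data[[ys]], data[[ids]], conf_level)
}

rmcorr_compute <- function(x, y, id, conf_level = 0.95) {
  df0 <- tibble(
    x = as.numeric(x),
    y = as.numeric(y),
    id = as.character(id)
  ) |>
    filter(!is.na(.data$x) & !is.na(.data$y))
  counts <- df0 |> count(.data$id) |> filter(.data$n >= 2)
  df0 <- filter(df0, .data$id %in% counts$id)
  if (nrow(counts) < 2) {
    abort("repeated-measures correlation needs >= 2 participants with >= 2 pairs")
  }
  if (sd(df0$x) == 0 || sd(df0$y) == 0) {
    abort("undefined correlation: no variance in x or y",
          class = "emamot_undefined_correlation")
  }
  within_var <- df0 |>
    group_by(.data$id) |>
    summarise(vx = var(.data$x), .groups = "drop")
  if (all(within_var$vx == 0, na.rm = TRUE)) {
    abort("undefined correlation: x is constant within every participant",
          class = "emamot_undefined_correlation")
  }
  fit <- lm(y ~ factor(id) + x, data = df0)
  an <- suppressWarnings(anova(fit))
  ss_x <- an["x", "Sum Sq"]
  ss_err <- an["Residuals", "Sum Sq"]
  slope <- coef(fit)[["x"]]
  r <- sign(slope) * sqrt(ss_x / (ss_x + ss_err))
  n_pairs <- nrow(df0)
  n_part <- length(unique(df0$id))
  dfree <- n_pairs - n_part - 1
  tval <- r * sqrt(dfree / max(1e-12, 1 - r^2))
  p <- 2 * pt(-abs(tval), dfree)
  zr <- atanh(min(1 - 1e-12, max(-1 + 1e-12, r)))
  zse <- 1 / sqrt(dfree - 1)
  zq <- qnorm(1 - (1 - conf_level) / 2)
  out <- tibble(
    r = r, df = dfree,
    conf.low = tanh(zr - zq * zse), conf.high = tanh(zr + zq * zse),
    p.value = p, n_pairs = n_pairs, n_participants = n_part
  )
  class(out) <- c("ema_rmcorr", class(out))
  out
}

#' Within-person correlations between motivation and covariate states
#'
#' Computes the repeated-measures correlation between the motivation
#' sum-score and each covariate state. Happiness and fatigue are paired at
#' every occasion; sleep quality (which refers to the previous night and is
#' asked in the morning only) is paired with the same morning's motivation.
#'
#' @param cohort An [ema_cohort()].
#' @return A tibble with one row per covariate (`happiness`, `fatigue`,
#'   `sleep`) and the [repeated_measures_correlation()] columns.
#' @export
state_covariate_rmcorr <- function(cohort) {
  sc <- state_scores(cohort) |> filter(.data$valid)
  run <- function(d, covariate) {
    res <- rmcorr_compute(d$state_sum, d[[covariate]], d$participant_id)
    mutate(res, covariate = covariate, .before = 1)
  }
  bind_rows(
    run(sc, "happiness"),
    run(sc, "fatigue"),
    run(filter(sc, .data$slot == "morning"), "sleep")
  )
}
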