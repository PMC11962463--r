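#' Two-way absolute-agreement single-measure ICC
#'
#' Intraclass correlation for test-retest agreement of a measure observed on
#' the same subjects under `k` conditions (here: games), computed from the
#' two-way random-effects mean squares:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))`.
#'
#' @param mat An `n x k` numeric matrix (subjects by conditions), complete
#'   cases only.
#' @return The ICC value, or `NA` when the between-subject variance is zero.
#' @export
icc_agreement <- function(mat) {
  mat <- mat[complete.cases(mat), , drop = FALSE]
  n <- nrow(mat); k <- ncol(mat)
  if (n < 3 || k < 2) return(NA_real_)
  grand <- mean(mat)
  row_m <- rowMeans(mat); col_m <- colMeans(mat)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((mat - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k / n * (msc - mse)
  if (abs(denom) < 1e-14 || (msr < 1e-14 && msc < 1e-14 && mse < 1e-14)) {
    return(NA_real_)
  }
  (msr - mse) / denom
}

#' Pairwise-game test-retest reliability
#'
#' Computes the two-way, absolute-agreement, single-measure ICC of a
#' per-participant-per-game measure for every 2-game combination (28 pairs
#' for 8 games), and aggregates the mean, SEM and a t-based 95% CI across
#' pairs.
#'
#' @param data A data frame with one row per participant x game.
#' @param id,game,value Column names (unquoted) of the participant id, game
#'   index and measure.
#' @param min_shared Minimum participants observed in both games of a pair.
#' @return A list of class `ema_icc`: `pairs` (tibble `game1`, `game2`,
#'   `icc`, `n`) and `summary` (mean, sem, conf.low, conf.high, n_pairs,
#'   n_undefined).
#' @export
icc_pairwise <- function(data, id, game, value, min_shared = 3) {
  ids <- rlang::as_name(rlang::enquo(id))
  gs <- rlang::as_name(rlang::enquo(game))
  vs <- rlang::as_name(rlang::enquo(value))
  wide <- tibble(
    id = as.character(data[[ids]]),
    game = data[[gs]],
    value = as.numeric(data[[vs]])
  ) |>
    tidyr::pivot_wider(names_from = "game", values_from = "value")
  games <- sort(as.numeric(setdiff(names(wide), "id")))
  if (length(games) < 2) abort("need >= 2 games for test-retest ICC")
  combos <- utils::combn(games, 2, simplify = FALSE)
  pairs <- purrr::map_dfr(combos, function(pr) {
    mat <- as.matrix(wide[, as.character(pr)])
    mat <- mat[complete.cases(mat), , drop = FALSE]
    icc <- if (nrow(mat) >= min_shared) icc_agreement(mat) else NA_real_
    tibble(game1 = pr[1], game2 = pr[2], icc = icc, n = nrow(mat))
  })
  vals <- pairs$icc[!is.na(pairs$icc)]
  n_undef <- sum(is.na(pairs$icc))
  if (n_undef > 0) {
    inform(sprintf("%d game pair(s) had undefined ICC (no between-person variance)",
                   n_undef))
  }
  if (!length(vals)) abort("ICC undefined for every game pair")
  sem <- sd(vals) / sqrt(length(vals))
  tq <- qt(0.975, max(1, length(vals) - 1))
  summary <- tibble(
    mean = mean(vals), sem = sem,
    conf.low = mean(vals) - tq * sem, conf.high = mean(vals) + tq * sem,
    n_pairs = length(vals), n_undefined = n_undef
  )
  structure(list(pairs = pairs, summary = summary), class = "ema_icc")
}

#' @export
print.ema_icc <- function(x, ...) {
  cat(sprintf("Pairwise-game ICC (two-way, absolute agreement, single measure)\n"))
  cat(sprintf("  mean = %.3f +- %.3f (SEM), 95%% CI [%.3f, %.3f], %d pairs\n",
              x$summary$mean, x$summary$sem, x$summary$conf.low,
              x$summary$conf.high, x$summary$n_pairs))
  invisible(x)
}

#' Test-retest reliability of behavioral summary measures
#'
#' Convenience wrapper around [icc_pairwise()] for the cohort's per-game
#' summary measures (probability of choosing the harder option, or response
#' vigor). Model-derived per-game parameters (reward/effort sensitivity)
#' can be assessed by passing their posterior means through `values`.
#'
#' @param cohort An [ema_cohort()].
#' @param measure `"p_harder"` or `"vigor"`, or `"custom"` with `values`.
#' @param values For `measure = "custom"`: a tibble with columns
#'   `participant_id`, `game_index`, `value`.
#' @return An `ema_icc` object, see [icc_pairwise()].
#' @export
test_retest_icc <- function(cohort, measure = c("p_harder", "vigor", "custom"),
                            values = NULL) {
  measure <- match.arg(measure)
  if (measure == "custom") {
    stopifnot(!is.null(values))
    return(icc_pairwise(values, "participant_id", "game_index", "value"))
  }
  summ <- compute_summary_measures(cohort)
  summ$value <- summ[[measure]]
  icc_pairwise(summ, "participant_id", "game_index", "value")
}
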