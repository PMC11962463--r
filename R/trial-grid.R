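#' Generate the 24-trial reward/effort design grid
#'
#' Builds the per-game trial design: pairs of options differing in reward
#' (coins, 1-7) and required effort (fraction of calibrated maximum,
#' 0.20-0.80), laid out on a factorial grid of reward-difference and
#' effort-difference levels. The two difference columns are decorrelated by
#' construction (balanced factorial plus a symmetry-checked remainder), and
#' the grid is rejected and redrawn until the Spearman rank correlation
#' between the reward and effort differences is at most `max_rho` in
#' magnitude - the property that makes the two sensitivities of the choice
#' model separately estimable.
#'
#' Catch trials contain a dominated option (the nominally "harder" route
#' offers *less* reward for *more* effort) and serve as attention checks;
#' they are excluded from all analyses.
#'
#' The same (reward, effort)-difference multiset is reused for every game of
#' a study; only the trial order is shuffled per game.
#'
#' @param n_trials Total trials per game (default 24, including catch).
#' @param n_catch Number of catch trials (default 2).
#' @param dr_levels Reward-difference levels in coins.
#' @param de_levels Effort-difference levels as fractions.
#' @param max_rho Maximum |Spearman rho| between the differences.
#' @param seed Optional seed for reproducibility.
#' @return A tibble with one row per trial: option rewards/efforts, the
#'   design differences `dr`/`de`, and `is_catch`.
#' @export
generate_trial_grid <- function(n_trials = 24, n_catch = 2,
                                dr_levels = c(1, 3, 5),
                                de_levels = c(0.2, 0.4, 0.6),
                                max_rho = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_scored <- n_trials - n_catch
  cells <- expand.grid(dr = dr_levels, de = de_levels)
  n_cells <- nrow(cells)
  if (n_scored < n_cells) {
    abort("design error: fewer scored trials than design cells")
  }
  base_rep <- n_scored %/% n_cells
  n_extra <- n_scored %% n_cells
  ok <- FALSE
  for (try in seq_len(200)) {
    idx <- rep(seq_len(n_cells), base_rep)
    if (n_extra > 0) idx <- c(idx, sample.int(n_cells, n_extra))
    dr <- cells$dr[idx]
    de <- cells$de[idx]
    rho <- if (length(unique(dr)) > 1 && length(unique(de)) > 1) {
      suppressWarnings(cor(dr, de, method = "spearman"))
    } else 0
    if (abs(rho) <= max_rho) { ok <- TRUE; break }
  }
  if (!ok) {
    abort("design error: could not decorrelate reward and effort differences",
          class = "emamot_design_error")
  }
  scored <- tibble(
    dr = dr,
    de = de,
    reward_easy = vapply(dr, function(d) sample.int(7L - d, 1L), integer(1)),
    effort_easy = vapply(de, function(d) {
      lo <- seq(0.2, 0.8 - d + 1e-9, by = 0.1)
      lo[sample.int(length(lo), 1L)]
    }, numeric(1))
  ) |>
    mutate(
      reward_hard = .data$reward_easy + .data$dr,
      effort_hard = round(.data$effort_easy + .data$de, 10),
      is_catch = FALSE
    )
  if (n_catch > 0) {
    catch <- tibble(
      dr = NA_real_, de = NA_real_,
      reward_easy = sample(5:7, n_catch, replace = TRUE),
      effort_easy = sample(c(0.2, 0.3), n_catch, replace = TRUE)
    ) |>
      mutate(
        reward_hard = sample(1:3, n_catch, replace = TRUE),
        effort_hard = sample(c(0.6, 0.7, 0.8), n_catch, replace = TRUE),
        is_catch = TRUE
      )
    scored <- bind_rows(scored, catch)
  }
  scored |>
    mutate(trial_index = dplyr::row_number() - 1L) |>
    select("trial_index", "reward_hard", "reward_easy",
           "effort_hard", "effort_easy", "dr", "de", "is_catch")
}

#' Standardize design differences by the grid's spread
#'
#' Scales reward and effort differences by their standard deviation over the
#' scored (non-catch) trials of the design so that the choice model's two
#' sensitivities live on comparable scales. Differences are scaled, not
#' centered: a zero difference must map to indifference.
#'
#' @param dr,de Reward (coins) and effort (fraction) differences.
#' @param grid A design grid from [generate_trial_grid()], or `NULL` to
#'   standardize by the sample SD of `dr`/`de` themselves.
#' @return A list with `dr_z`, `de_z`, and the scale factors `sd_dr`, `sd_de`.
#' @export
standardize_design <- function(dr, de, grid = NULL) {
  ref_dr <- if (is.null(grid)) dr else grid$dr[!grid$is_catch]
  ref_de <- if (is.null(grid)) de else grid$de[!grid$is_catch]
  sd_dr <- sd(ref_dr, na.rm = TRUE)
  sd_de <- sd(ref_de, na.rm = TRUE)
  if (!isTRUE(sd_dr > 0) || !isTRUE(sd_de > 0)) {
    abort("design error: degenerate design grid (zero spread)")
  }
  list(dr_z = dr / sd_dr, de_z = de / sd_de, sd_dr = sd_dr, sd_de = sd_de)
}
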