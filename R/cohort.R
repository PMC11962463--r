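#' EMA cohort container
#'
#' An `ema_cohort` bundles the three long-format tables of an ecological
#' momentary assessment (EMA) study of motivation and effort-based choice:
#'
#' * `states`: one row per participant x notification occasion with 7-point
#'   Likert responses to four motivation items (`m1`..`m4`; `m2` is a
#'   reverse-worded item stored *already reverse-scored*, i.e. higher is
#'   always more motivated), plus happiness, fatigue and (morning only)
#'   sleep-quality items, schedule metadata and a validity flag.
#' * `trials`: one row per choice trial of the effort-reward discounting
#'   game (two options differing in coin reward 1-7 and required effort as a
#'   fraction 0.20-0.80 of the participant's calibrated maximum).
#' * `traits`: one row per participant with a standardized trait-apathy
#'   factor score, demographics, and the calibrated maximum effort
#'   (button presses per 10 s).
#'
#' @param states,trials,traits Data frames following the documented schema
#'   (see [read_cohort()]).
#' @param provenance A list describing where the data came from.
#' @return An object of class `ema_cohort`.
#' @seealso [read_cohort()], [write_cohort()], [generate_cohort()]
#' @export
ema_cohort <- function(states, trials, traits, provenance = list(source = "memory")) {
  x <- structure(
    list(
      states = as_tibble(states),
      trials = as_tibble(trials),
      traits = as_tibble(traits),
      provenance = provenance
    ),
    class = "ema_cohort"
  )
  validate_cohort(x)
  x
}

MOT_ITEMS <- c("m1", "m2", "m3", "m4")
STATE_COLS <- c(
  "participant_id", "occasion_index", "day_index", "slot", "weekday",
  MOT_ITEMS, "happiness", "fatigue", "sleep", "valid"
)
TRIAL_COLS <- c(
  "participant_id", "game_index", "occasion_index", "trial_index",
  "reward_hard", "reward_easy", "effort_hard", "effort_easy",
  "chose_hard", "success", "mean_press_lag_ms", "n_presses", "is_catch"
)
TRAIT_COLS <- c("participant_id", "apathy", "age", "sex", "max_effort_baseline")
WEEKDAYS <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")

schema_abort <- function(table, row, column, msg) {
  abort(
    sprintf("schema error in %s, row %s, column %s: %s", table, row, column, msg),
    class = "emamot_schema_error"
  )
}

check_range <- function(df, table, column, lo, hi, integer = FALSE) {
  v <- df[[column]]
  bad <- which(!is.na(v) & (v < lo | v > hi | (integer & v != round(v))))
  if (length(bad)) {
    schema_abort(table, bad[1], column, sprintf(
      "value %s outside %s..%s", format(v[bad[1]]), lo, hi
    ))
  }
}

validate_cohort <- function(x) {
  for (nm in STATE_COLS) {
    if (!nm %in% names(x$states)) {
      abort(sprintf("states table is missing required column '%s'", nm),
            class = "emamot_schema_error")
    }
  }
  for (nm in TRIAL_COLS) {
    if (!nm %in% names(x$trials)) {
      abort(sprintf("trials table is missing required column '%s'", nm),
            class = "emamot_schema_error")
    }
  }
  for (nm in TRAIT_COLS) {
    if (!nm %in% names(x$traits)) {
      abort(sprintf("traits table is missing required column '%s'", nm),
            class = "emamot_schema_error")
    }
  }
  st <- x$states
  for (item in c(MOT_ITEMS, "happiness", "fatigue", "sleep")) {
    check_range(st, "states", item, 1, 7, integer = TRUE)
  }
  bad <- which(!st$slot %in% c("morning", "afternoon"))
  if (length(bad)) schema_abort("states", bad[1], "slot", "must be morning/afternoon")
  bad <- which(!st$weekday %in% WEEKDAYS)
  if (length(bad)) schema_abort("states", bad[1], "weekday", "unknown weekday label")
  bad <- which(!is.na(st$sleep) & st$slot != "morning")
  if (length(bad)) {
    schema_abort("states", bad[1], "sleep", "sleep item only valid at morning occasions")
  }
  dup <- st |> count(.data$participant_id, .data$occasion_index) |> filter(.data$n > 1)
  if (nrow(dup)) {
    abort(sprintf(
      "integrity error: duplicated occasion %d for participant %s",
      dup$occasion_index[1], dup$participant_id[1]
    ), class = "emamot_integrity_error")
  }

  tr <- x$trials
  check_range(tr, "trials", "reward_hard", 1, 7, integer = TRUE)
  check_range(tr, "trials", "reward_easy", 1, 7, integer = TRUE)
  check_range(tr, "trials", "effort_hard", 0, 1)
  check_range(tr, "trials", "effort_easy", 0, 1)
  ok_order <- tr$reward_hard >= tr$reward_easy & tr$effort_hard >= tr$effort_easy
  bad <- which(!tr$is_catch & !ok_order)
  if (length(bad)) {
    schema_abort("trials", bad[1], "reward_hard",
                 "non-catch trial violates reward/effort ordering")
  }
  bad <- which(tr$is_catch & ok_order)
  if (length(bad)) {
    schema_abort("trials", bad[1], "is_catch",
                 "catch trial must contain a dominated option")
  }

  tt <- x$traits
  if (anyDuplicated(tt$participant_id)) {
    abort("integrity error: duplicated participant in traits",
          class = "emamot_integrity_error")
  }
  bad <- which(!is.na(tt$max_effort_baseline) & tt$max_effort_baseline <= 0)
  if (length(bad)) schema_abort("traits", bad[1], "max_effort_baseline", "must be > 0")

  unknown <- setdiff(tr$participant_id, tt$participant_id)
  if (length(unknown)) {
    abort(sprintf("integrity error: trial references unknown participant '%s'",
                  unknown[1]), class = "emamot_integrity_error")
  }
  unknown <- setdiff(st$participant_id, tt$participant_id)
  if (length(unknown)) {
    abort(sprintf("integrity error: state report for unknown participant '%s'",
                  unknown[1]), class = "emamot_integrity_error")
  }
  key_st <- paste(st$participant_id, st$occasion_index)
  key_tr <- unique(paste(tr$participant_id, tr$occasion_index))
  miss <- setdiff(key_tr, key_st)
  if (length(miss)) {
    abort(sprintf("integrity error: trial occasion '%s' has no state report row",
                  miss[1]), class = "emamot_integrity_error")
  }
  invisible(x)
}

#' @export
print.ema_cohort <- function(x, ...) {
  cat("<ema_cohort>\n")
  cat(sprintf("  participants: %d\n", nrow(x$traits)))
  cat(sprintf("  state occasions: %d (%d valid)\n",
              nrow(x$states), sum(x$states$valid, na.rm = TRUE)))
  cat(sprintf("  trials: %d in %d games (%d catch)\n",
              nrow(x$trials),
              nrow(distinct(x$trials, .data$participant_id, .data$game_index)),
              sum(x$trials$is_catch)))
  cat(sprintf("  provenance: %s\n", x$provenance$source %||% "unknown"))
  invisible(x)
}

#' Number of scheduled occasions in a cohort
#'
#' The denominator of the per-participant validity fraction: the number of
#' occasions in the study schedule (baseline plus two notifications per day).
#' @param cohort An [ema_cohort()].
#' @return An integer count.
#' @export
n_occasions <- function(cohort) {
  n <- cohort$provenance$n_occasions
  if (!is.null(n)) return(as.integer(n))
  as.integer(max(cohort$states$occasion_index) + 1L)
}

#' Read a cohort from CSV files
#'
#' Reads the three long-format tables (`states.csv`, `trials.csv`,
#' `traits.csv`) and returns a validated [ema_cohort()]. Efforts are stored
#' as fractions in `[0, 1]`; the files may use either fractions or percents
#' (percent values are detected by exceeding 1 and divided by 100).
#'
#' The reverse-worded motivation item `m2` is assumed to hold the *raw*
#' response in the file and is reverse-scored at ingest
#' (`response -> 8 - response`) so that all downstream sums treat items
#' uniformly; set `reverse_m2 = FALSE` if the file already stores
#' reverse-scored values.
#'
#' @param state_path,trial_path,trait_path Paths to the three CSV files.
#' @param reverse_m2 Reverse-score item `m2` at ingest (default `TRUE`).
#' @return An [ema_cohort()].
#' @export
read_cohort <- function(state_path, trial_path, trait_path, reverse_m2 = TRUE) {
  for (p in c(state_path, trial_path, trait_path)) {
    if (!file.exists(p)) abort(sprintf("file not found: %s", p))
  }
  states <- readr::read_csv(state_path, show_col_types = FALSE)
  trials <- readr::read_csv(trial_path, show_col_types = FALSE)
  traits <- readr::read_csv(trait_path, show_col_types = FALSE)
  if (reverse_m2 && "m2" %in% names(states)) {
    states$m2 <- ifelse(is.na(states$m2), NA_integer_, 8L - as.integer(states$m2))
  }
  for (col in c("effort_hard", "effort_easy")) {
    if (col %in% names(trials) && any(trials[[col]] > 1, na.rm = TRUE)) {
      trials[[col]] <- trials[[col]] / 100
    }
  }
  ema_cohort(states, trials, traits,
             provenance = list(
               source = "file",
               paths = c(states = state_path, trials = trial_path, traits = trait_path)
             ))
}

#' Write a cohort to CSV files
#'
#' Inverse of [read_cohort()]: writes `states.csv`, `trials.csv` and
#' `traits.csv` into `dir`. With `reverse_m2 = TRUE` (default) the stored
#' `m2` column is converted back to the raw response scale so that a
#' write/read round trip is exact.
#'
#' @param cohort An [ema_cohort()].
#' @param dir Output directory (created if needed).
#' @param reverse_m2 Undo the ingest reverse-scoring of `m2` when writing.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir, reverse_m2 = TRUE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  states <- cohort$states
  if (reverse_m2) {
    states$m2 <- ifelse(is.na(states$m2), NA_integer_, 8L - as.integer(states$m2))
  }
  paths <- c(
    states = file.path(dir, "states.csv"),
    trials = file.path(dir, "trials.csv"),
    traits = file.path(dir, "traits.csv")
  )
  readr::write_csv(states, paths["states"])
  readr::write_csv(cohort$trials, paths["trials"])
  readr::write_csv(cohort$traits, paths["traits"])
  invisible(paths)
}

#' Apply participant-level validity filtering
#'
#' Removes participants who did not provide valid data at a minimum fraction
#' of the scheduled occasions (default 70%), and participants without a
#' trait-apathy estimate. Occasion-level validity (the `valid` flag) is
#' assumed to have been applied first: an occasion counts as valid when the
#' report was completed within its notification window, the game's
#' attention/catch criterion passed, and press data were non-degenerate.
#' Catch trials are flagged for downstream removal but kept in the table.
#'
#' The returned cohort carries an `exclusion_report` attribute listing each
#' removed participant and the reason. The operation is idempotent.
#'
#' @param cohort An [ema_cohort()].
#' @param min_valid_fraction Minimum fraction of scheduled occasions with
#'   valid data (default 0.70).
#' @return A filtered [ema_cohort()] with attribute `exclusion_report`.
#' @export
apply_validity_filter <- function(cohort, min_valid_fraction = 0.70) {
  n_occ <- n_occasions(cohort)
  frac <- cohort$states |>
    group_by(.data$participant_id) |>
    summarise(n_valid = sum(.data$valid, na.rm = TRUE), .groups = "drop") |>
    mutate(valid_fraction = .data$n_valid / n_occ)
  frac <- cohort$traits |>
    select("participant_id", "apathy") |>
    left_join(frac, by = "participant_id") |>
    mutate(
      n_valid = ifelse(is.na(.data$n_valid), 0L, .data$n_valid),
      valid_fraction = ifelse(is.na(.data$valid_fraction), 0, .data$valid_fraction)
    )
  excl <- frac |>
    mutate(reason = case_when(
      is.na(.data$apathy) ~ "no trait apathy estimate",
      .data$valid_fraction < min_valid_fraction ~
        sprintf("below %d%% valid", round(100 * min_valid_fraction)),
      TRUE ~ NA_character_
    )) |>
    filter(!is.na(.data$reason)) |>
    select("participant_id", "reason", "valid_fraction")
  keep <- setdiff(cohort$traits$participant_id, excl$participant_id)
  if (!length(keep)) {
    abort("validity filter removed every participant", class = "emamot_empty_cohort")
  }
  out <- structure(
    list(
      states = filter(cohort$states, .data$participant_id %in% keep),
      trials = filter(cohort$trials, .data$participant_id %in% keep),
      traits = filter(cohort$traits, .data$participant_id %in% keep),
      provenance = c(cohort$provenance[setdiff(names(cohort$provenance), "filtered")],
                     list(filtered = TRUE))
    ),
    class = "ema_cohort"
  )
  gt <- attr(cohort, "ground_truth", exact = TRUE)
  if (!is.null(gt)) attr(out, "ground_truth") <- gt
  attr(out, "exclusion_report") <- excl
  out
}

#' Per-occasion state scores
#'
#' Sum-scores the four motivation items (item `m2` has already been
#' reverse-scored at ingest) and z-scores the sum within person over that
#' participant's valid, complete occasions, so that within- and
#' between-person variation can be separated downstream.
#'
#' @param cohort An [ema_cohort()].
#' @return A tibble with one row per state report: `state_sum` (4-28),
#'   `state_z` (within-person z-score), covariate items and schedule columns.
#' @export
state_scores <- function(cohort) {
  cohort$states |>
    mutate(
      state_sum = .data$m1 + .data$m2 + .data$m3 + .data$m4,
      complete = .data$valid & !is.na(.data$state_sum)
    ) |>
    group_by(.data$participant_id) |>
    mutate(
      person_mean = mean(.data$state_sum[.data$complete]),
      person_sd = sd(.data$state_sum[.data$complete]),
      state_z = ifelse(.data$complete & .data$person_sd > 0,
                       (.data$state_sum - .data$person_mean) / .data$person_sd,
                       NA_real_)
    ) |>
    ungroup() |>
    arrange(.data$participant_id, .data$occasion_index)
}

#' Per-game behavioral summary measures
#'
#' Summarises each participant x game into the measures used by the
#' descriptive and regression analyses:
#'
#' * `willingness`: mean over non-catch trials of chosen-minus-unchosen
#'   effort, in percent (bounded to \[-60, 60\] on the 20-80% design grid);
#' * `p_harder`: proportion of non-catch trials on which the harder option
#'   was chosen;
#' * `success_rate`: proportion of successful effort executions;
#' * `vigor`: mean of per-trial vigor, where a trial's vigor is the
#'   cohort-wide maximum trial-mean press lag minus that trial's mean lag
#'   (larger = faster pressing);
#' * the game occasion's motivation sum-score (`state_sum`) and its
#'   within-person z-score (`state_z`), plus trait columns.
#'
#' @param cohort An [ema_cohort()].
#' @return A tibble with one row per participant x game.
#' @export
compute_summary_measures <- function(cohort) {
  tr <- filter(cohort$trials, !.data$is_catch)
  empty <- cohort$trials |>
    distinct(.data$participant_id, .data$game_index) |>
    anti_join(distinct(tr, .data$participant_id, .data$game_index),
              by = c("participant_id", "game_index"))
  if (nrow(empty)) {
    abort(sprintf(
      "undefined summary: game %d of participant %s has no non-catch trials",
      empty$game_index[1], empty$participant_id[1]
    ), class = "emamot_undefined_summary")
  }
  lag_ref <- max(tr$mean_press_lag_ms, na.rm = TRUE)
  game <- tr |>
    mutate(
      chosen_effort = ifelse(.data$chose_hard, .data$effort_hard, .data$effort_easy),
      unchosen_effort = ifelse(.data$chose_hard, .data$effort_easy, .data$effort_hard),
      vigor = lag_ref - .data$mean_press_lag_ms
    ) |>
    group_by(.data$participant_id, .data$game_index, .data$occasion_index) |>
    summarise(
      willingness = 100 * mean(.data$chosen_effort - .data$unchosen_effort),
      p_harder = mean(.data$chose_hard),
      success_rate = mean(.data$success),
      vigor = mean(.data$vigor, na.rm = TRUE),
      mean_press_lag_ms = mean(.data$mean_press_lag_ms, na.rm = TRUE),
      max_presses = max(.data$n_presses, na.rm = TRUE),
      n_trials = n(),
      .groups = "drop"
    )
  st <- state_scores(cohort) |>
    select("participant_id", "occasion_index", "day_index", "state_sum", "state_z")
  game |>
    left_join(st, by = c("participant_id", "occasion_index")) |>
    left_join(cohort$traits, by = "participant_id") |>
    arrange(.data$participant_id, .data$game_index)
}
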