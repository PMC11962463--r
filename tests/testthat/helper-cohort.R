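# hand-built fixtures; all values chosen so expected statistics can be
# computed by independent arithmetic in the tests

tiny_states <- function() {
  tibble::tribble(
    ~participant_id, ~occasion_index, ~day_index, ~slot, ~weekday,
    ~m1, ~m2, ~m3, ~m4, ~happiness, ~fatigue, ~sleep, ~valid,
    "A", 0L, 0L, "afternoon", "Thu", 5L, 6L, 4L, 7L, 5L, 3L, NA, TRUE,
    "A", 1L, 1L, "morning",   "Fri", 6L, 5L, 5L, 6L, 6L, 2L, 5L, TRUE,
    "A", 2L, 1L, "afternoon", "Fri", 3L, 4L, 2L, 5L, 4L, 5L, NA, TRUE,
    "B", 0L, 0L, "afternoon", "Thu", 2L, 3L, 1L, 2L, 3L, 6L, NA, TRUE,
    "B", 1L, 1L, "morning",   "Fri", 4L, 4L, 3L, 4L, 4L, 4L, 3L, TRUE,
    "B", 2L, 1L, "afternoon", "Fri", 1L, 2L, 2L, 3L, 2L, 6L, NA, FALSE
  )
}

tiny_trials <- function() {
  tibble::tribble(
    ~participant_id, ~game_index, ~occasion_index, ~trial_index,
    ~reward_hard, ~reward_easy, ~effort_hard, ~effort_easy,
    ~chose_hard, ~success, ~mean_press_lag_ms, ~n_presses, ~is_catch,
    "A", 0L, 0L, 0L, 5L, 2L, 0.8, 0.2, TRUE,  TRUE, 200, 40L, FALSE,
    "A", 0L, 0L, 1L, 4L, 3L, 0.6, 0.4, FALSE, TRUE, 250, 20L, FALSE,
    "A", 0L, 0L, 2L, 2L, 6L, 0.7, 0.2, FALSE, TRUE, 300, 15L, TRUE,
    "B", 0L, 0L, 0L, 5L, 2L, 0.8, 0.2, TRUE,  TRUE, 500, 45L, FALSE,
    "B", 0L, 0L, 1L, 4L, 3L, 0.6, 0.4, TRUE,  FALSE, 350, 30L, FALSE
  )
}

tiny_traits <- function() {
  tibble::tibble(
    participant_id = c("A", "B"),
    apathy = c(-0.5, 0.8),
    age = c(25L, 40L),
    sex = c("female", "male"),
    max_effort_baseline = c(70, 60)
  )
}

tiny_cohort <- function() {
  ema_cohort(tiny_states(), tiny_trials(), tiny_traits())
}

# small generated cohort reused across tests
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- apply_validity_filter(
        generate_cohort(generator_config(n_participants = 60), seed = 360)
      )
    }
    cache
  }
})

# cohort whose motivation items encode a prescribed integer sum score (4..28):
# items get floor(s/4) each plus the remainder spread one point at a time,
# so analyses driven by the sum score can be tested against crafted series
scored_cohort <- function(score, ids = NULL) {
  # score: matrix participants x occasions with integers in 4..28
  n <- nrow(score); T_occ <- ncol(score)
  if (is.null(ids)) ids <- sprintf("C%02d", seq_len(n))
  stopifnot(all(score >= 4 & score <= 28), T_occ %% 2 == 1)
  sched <- tibble::tibble(
    occasion_index = 0:(T_occ - 1),
    day_index = c(0L, rep(seq_len((T_occ - 1) %/% 2), each = 2L)),
    slot = c("afternoon", rep(c("morning", "afternoon"), (T_occ - 1) %/% 2))
  )
  sched$weekday <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")[
    ((sched$day_index + 3L) %% 7L) + 1L]
  states <- tidyr::expand_grid(participant_id = ids, sched)
  s <- as.vector(t(score))
  base <- s %/% 4L
  rem <- s %% 4L
  for (m in 1:4) {
    states[[paste0("m", m)]] <- as.integer(base + (rem >= m))
  }
  states$happiness <- 4L
  states$fatigue <- 4L
  states$sleep <- ifelse(states$slot == "morning", 4L, NA_integer_)
  states$valid <- TRUE
  traits <- tibble::tibble(
    participant_id = ids, apathy = 0, age = 30L, sex = "female",
    max_effort_baseline = 70
  )
  trials <- tiny_trials()[0, ]
  ema_cohort(states, trials, traits,
             provenance = list(source = "fixture", n_occasions = T_occ))
}
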