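test_that("write/read round trip preserves every field exactly", {
  co <- tiny_cohort()
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(file.path(dir, "states.csv"), file.path(dir, "trials.csv"),
                      file.path(dir, "traits.csv"))
  expect_equal(as.data.frame(back$states), as.data.frame(co$states))
  expect_equal(as.data.frame(back$trials), as.data.frame(co$trials))
  expect_equal(as.data.frame(back$traits), as.data.frame(co$traits))
})

test_that("m2 is reverse-scored at ingest and restored at write", {
  co <- tiny_cohort()
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  raw <- readr::read_csv(file.path(dir, "states.csv"), show_col_types = FALSE)
  expect_equal(raw$m2, 8L - co$states$m2)
})

test_that("schema violations are rejected with row-level diagnostics", {
  st <- tiny_states()
  st$m3[2] <- 9L
  expect_error(ema_cohort(st, tiny_trials(), tiny_traits()),
               "row 2.*m3.*outside 1..7", class = "emamot_schema_error")

  st2 <- tiny_states()
  st2$sleep[3] <- 4L  # afternoon occasion
  expect_error(ema_cohort(st2, tiny_trials(), tiny_traits()),
               class = "emamot_schema_error")

  tr <- tiny_trials()
  tr$participant_id[4] <- "ghost"
  expect_error(ema_cohort(tiny_states(), tr, tiny_traits()),
               "unknown participant 'ghost'", class = "emamot_integrity_error")

  tr2 <- tiny_trials()
  tr2$is_catch[1] <- TRUE  # ordered options cannot be a catch trial
  expect_error(ema_cohort(tiny_states(), tr2, tiny_traits()),
               class = "emamot_schema_error")

  expect_error(
    ema_cohort(tiny_states()[, -4], tiny_trials(), tiny_traits()),
    "missing required column", class = "emamot_schema_error"
  )
})

test_that("validity filter keeps complete participants and reports exclusions", {
  cfg <- generator_config(n_participants = 10, missingness = list(enabled = FALSE))
  co <- generate_cohort(cfg, seed = 1)
  # everyone fully valid -> retained
  fl <- apply_validity_filter(co)
  expect_equal(nrow(fl$traits), 10)
  expect_equal(nrow(attr(fl, "exclusion_report")), 0)

  # force one participant below 70%
  co$states$valid[co$states$participant_id == "P001"][1:20] <- FALSE
  fl2 <- apply_validity_filter(co)
  rep2 <- attr(fl2, "exclusion_report")
  expect_false("P001" %in% fl2$traits$participant_id)
  expect_match(rep2$reason[rep2$participant_id == "P001"], "below 70% valid")

  # idempotent
  fl3 <- apply_validity_filter(fl2)
  expect_equal(fl3$traits, fl2$traits)
  expect_equal(nrow(attr(fl3, "exclusion_report")), 0)
})

test_that("generator dropout at study scale retains about 83% of participants", {
  co <- generate_cohort(generator_config(), seed = 8311)
  fl <- apply_validity_filter(co)
  retention <- nrow(fl$traits) / nrow(co$traits)
  expect_gt(retention, 0.73)
  expect_lt(retention, 0.93)
})

test_that("summary measures follow their definitions", {
  co <- tiny_cohort()
  summ <- compute_summary_measures(co)
  # A: trial 1 chose hard (0.8 vs 0.2 -> +60), trial 2 chose easy (0.4 vs 0.6
  # -> -20); catch trial excluded; willingness = mean(60, -20) = 20
  a <- summ[summ$participant_id == "A", ]
  expect_equal(a$willingness, 20)
  expect_equal(a$p_harder, 0.5)
  # vigor reference: max non-catch trial-mean lag = 500
  expect_equal(a$vigor, mean(c(500 - 200, 500 - 250)))
  b <- summ[summ$participant_id == "B", ]
  expect_equal(b$willingness, mean(c(60, 20)))
  expect_equal(b$p_harder, 1)
  expect_equal(b$success_rate, 0.5)
  # bounds on the 20-80% grid
  gen <- compute_summary_measures(small_cohort())
  expect_true(all(gen$willingness >= -60 & gen$willingness <= 60))
})

test_that("a game with only catch trials is an undefined summary", {
  co <- tiny_cohort()
  co$trials <- co$trials[c(3, 4, 5), ]  # A's game is catch-only
  expect_error(compute_summary_measures(co), "no non-catch trials",
               class = "emamot_undefined_summary")
})

test_that("state scores z-score within person over valid occasions", {
  co <- tiny_cohort()
  sc <- state_scores(co)
  a <- sc[sc$participant_id == "A", ]
  sums <- c(5 + 6 + 4 + 7, 6 + 5 + 5 + 6, 3 + 4 + 2 + 5)
  expect_equal(a$state_sum, sums)
  expect_equal(a$state_z, (sums - mean(sums)) / sd(sums))
  # B's invalid occasion contributes nothing and gets NA z
  b <- sc[sc$participant_id == "B", ]
  expect_true(is.na(b$state_z[3]))
  expect_equal(b$person_mean[1], mean(b$state_sum[1:2]))
})
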