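test_that("identical seed and config give identical cohorts", {
  cfg <- generator_config(n_participants = 12, n_days = 4)
  a <- generate_cohort(cfg, seed = 99)
  b <- generate_cohort(cfg, seed = 99)
  expect_identical(a$states, b$states)
  expect_identical(a$trials, b$trials)
  expect_identical(a$traits, b$traits)
  expect_identical(attr(a, "ground_truth")$theta, attr(b, "ground_truth")$theta)
})

test_that("config validation rejects degenerate settings", {
  expect_error(generate_cohort(generator_config(n_participants = 1)), "config error")
  expect_error(generate_cohort(generator_config(n_days = 0)), "config error")
  expect_error(generate_cohort(generator_config(state = list(ar1 = 1.2))),
               "config error")
})

test_that("trial grid decorrelates reward and effort differences", {
  for (seed in 1:5) {
    g <- generate_trial_grid(24, 2, seed = seed)
    sc <- g[!g$is_catch, ]
    expect_lte(abs(suppressWarnings(cor(sc$dr, sc$de, method = "spearman"))), 0.1)
    expect_equal(nrow(g), 24)
    # catch trials contain a dominated option
    ca <- g[g$is_catch, ]
    expect_true(all(ca$reward_hard < ca$reward_easy & ca$effort_hard > ca$effort_easy))
    # options live on the coin and effort grids
    expect_true(all(g$reward_hard %in% 1:7 & g$reward_easy %in% 1:7))
    expect_true(all(g$effort_hard >= 0.2 - 1e-9 & g$effort_hard <= 0.8 + 1e-9))
  }
  expect_error(generate_trial_grid(8, 0), "design error")
})

test_that("all games share one design multiset in shuffled order", {
  co <- generate_cohort(generator_config(n_participants = 4,
                                         missingness = list(enabled = FALSE)),
                        seed = 5)
  key <- function(d) sort(paste(d$reward_hard, d$reward_easy,
                                d$effort_hard, d$effort_easy))
  games <- split(co$trials, interaction(co$trials$participant_id,
                                        co$trials$game_index, drop = TRUE))
  keys <- vapply(games, key, character(24))
  expect_true(all(apply(keys, 2, identical, keys[, 1])))
})

test_that("ground-truth sensitivities satisfy the modulation identity", {
  co <- generate_cohort(generator_config(n_participants = 20), seed = 21)
  gt <- attr(co, "ground_truth")
  b <- gt$config$choice
  ap <- gt$person_offsets$apathy_true[
    match(gt$cells$participant_id, gt$person_offsets$participant_id)]
  rebuilt <- b$beta_trait_rew * ap + gt$cells$rew_offset +
    b$beta_state_rew * gt$cells$z_current +
    b$beta_state_rew_past * gt$cells$z_past +
    b$beta_state_rew_future * gt$cells$z_future
  expect_equal(rebuilt, gt$cells$rew_sens, tolerance = 1e-12)
  rebuilt_e <- b$beta_trait_eff * ap + gt$cells$eff_offset +
    b$beta_state_eff * gt$cells$z_current
  expect_equal(rebuilt_e, gt$cells$eff_sens, tolerance = 1e-12)
})

test_that("choice frequencies converge to the Bernoulli-logit probabilities", {
  # one participant, many games at fixed sensitivities via near-zero spread
  cfg <- generator_config(
    n_participants = 40, n_days = 14,
    choice = list(person_sd_rew = 1e-6, person_sd_eff = 1e-6,
                  game_sd_rew = 1e-6, game_sd_eff = 1e-6,
                  beta_trait_rew = 0, beta_trait_eff = 0,
                  beta_state_rew = 0, beta_state_eff = 0),
    missingness = list(enabled = FALSE)
  )
  co <- generate_cohort(cfg, seed = 31)
  gt <- attr(co, "ground_truth")
  tr <- co$trials[!co$trials$is_catch, ]
  tr$dr <- tr$reward_hard - tr$reward_easy
  tr$de <- round(tr$effort_hard - tr$effort_easy, 10)
  freq <- aggregate(chose_hard ~ dr + de, tr, mean)
  n_cell <- aggregate(chose_hard ~ dr + de, tr, length)$chose_hard
  p <- trial_choice_probability(
    gt$config$choice$mu_rewsens, gt$config$choice$mu_effsens,
    freq$dr / gt$design_sd[["dr"]], freq$de / gt$design_sd[["de"]]
  )
  expect_true(all(abs(freq$chose_hard - p) < 4 / sqrt(n_cell) + 0.01))
})

test_that("state-choice coupling is null when the state weights are zero", {
  cfg <- generator_config(
    n_participants = 200,
    choice = list(beta_state_rew = 0, beta_state_eff = 0),
    missingness = list(enabled = FALSE)
  )
  co <- generate_cohort(cfg, seed = 77)
  summ <- compute_summary_measures(co)
  ok <- !is.na(summ$state_z)
  expect_lt(abs(cor(summ$state_z[ok], summ$willingness[ok])), 0.05)
})

test_that("state-willingness covariance increases with the reward coupling", {
  covs <- vapply(c(0, 0.4, 0.8), function(b) {
    co <- generate_cohort(generator_config(
      n_participants = 120,
      choice = list(beta_state_rew = b),
      missingness = list(enabled = FALSE)
    ), seed = 55)
    summ <- compute_summary_measures(co)
    ok <- !is.na(summ$state_z)
    cov(summ$state_z[ok], summ$willingness[ok])
  }, numeric(1))
  expect_true(all(diff(covs) > 0))
})

test_that("trait-dependent attrition removes more apathetic participants", {
  co <- generate_cohort(generator_config(n_participants = 300), seed = 41)
  fl <- apply_validity_filter(co)
  excluded <- setdiff(co$traits$participant_id, fl$traits$participant_id)
  mean_ex <- mean(co$traits$apathy[co$traits$participant_id %in% excluded],
                  na.rm = TRUE)
  mean_in <- mean(fl$traits$apathy, na.rm = TRUE)
  expect_gt(mean_ex, mean_in)
})

test_that("games are counterbalanced morning/afternoon within participant", {
  co <- generate_cohort(generator_config(n_participants = 10,
                                         missingness = list(enabled = FALSE)),
                        seed = 13)
  slots <- unique(co$trials[, c("participant_id", "game_index", "occasion_index")])
  slots <- merge(slots, co$states[, c("participant_id", "occasion_index", "slot")],
                 by = c("participant_id", "occasion_index"))
  counts <- table(slots$participant_id, slots$slot)
  expect_true(all(counts == 4))
})
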