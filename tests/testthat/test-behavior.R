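test_that("ICC equals 1 for duplicated data and matches the mean-squares oracle", {
  set.seed(10)
  x <- rnorm(6)
  expect_equal(icc_agreement(cbind(x, x)), 1, tolerance = 1e-12)
  mat <- cbind(x, x + rnorm(6, 0.3, 0.4))
  expect_equal(icc_agreement(mat), icc_oracle(mat), tolerance = 1e-8)
  # common affine rescaling of both games leaves the ICC unchanged
  expect_equal(icc_agreement(3.2 * mat - 7), icc_agreement(mat),
               tolerance = 1e-10)
})

test_that("pairwise-game ICC aggregates 28 pairs and degrades to ~0 on shuffles", {
  co <- small_cohort()
  icc <- test_retest_icc(co, "p_harder")
  expect_equal(nrow(icc$pairs), 28)
  expect_gt(icc$summary$mean, 0.3)
  # independently reshuffled measures per game destroy reliability
  summ <- compute_summary_measures(co)
  set.seed(2)
  shuf <- summ
  shuf$value <- ave(summ$p_harder, summ$game_index,
                    FUN = function(v) sample(v))
  icc0 <- icc_pairwise(shuf, "participant_id", "game_index", "value")
  expect_lt(abs(icc0$summary$mean), 0.15)
})

test_that("discounting ANOVA finds reward and effort effects when present", {
  co <- small_cohort()
  da <- discounting_anova(co)
  expect_true(all(da$term == c("dr", "de", "dr:de")))
  expect_lt(da$p.value[da$term == "dr"], 0.001)
  expect_lt(da$p.value[da$term == "de"], 0.001)
  expect_gt(da$eta_sq[da$term == "dr"], da$eta_sq[da$term == "dr:de"])
})

test_that("discounting ANOVA is flat when effort has no influence", {
  cfg <- generator_config(n_participants = 40,
                          choice = list(mu_effsens = 0, person_sd_eff = 1e-6,
                                        game_sd_eff = 1e-6, beta_trait_eff = 0,
                                        beta_state_eff = 0),
                          missingness = list(enabled = FALSE))
  co <- generate_cohort(cfg, seed = 6)
  da <- discounting_anova(co)
  expect_lt(da$eta_sq[da$term == "de"], 0.02)
  expect_gt(da$eta_sq[da$term == "dr"], 0.2)
})

test_that("constant choice probabilities are flagged, not crashed", {
  co <- small_cohort()
  co$trials$chose_hard <- TRUE
  da <- discounting_anova(co)
  expect_true(all(da$flagged))
})

test_that("success stability covers zero slope at default and flags separation", {
  co <- small_cohort()
  ss <- success_stability(co)
  expect_false(ss$separation)
  expect_gt(ss$mean_success, 0.95)
  expect_true(ss$conf.low < 0 & ss$conf.high > 0)
  # all-success cohort raises a separation warning
  co2 <- co
  co2$trials$success <- TRUE
  expect_warning(ss2 <- success_stability(co2),
                 class = "emamot_separation_warning")
  expect_true(ss2$separation)
  # injected decay by day is detected as a negative slope
  co3 <- co
  day <- (co3$trials$occasion_index + 1L) %/% 2L
  set.seed(4)
  co3$trials$success <- runif(nrow(co3$trials)) < plogis(3 - 0.4 * day)
  ss3 <- success_stability(co3)
  expect_lt(ss3$conf.high, 0)
})

test_that("calibration check is exact for identical maxima and degrades with noise", {
  co <- small_cohort()
  # make presses exactly effort * baseline: implied max == baseline
  tr <- co$trials
  base <- co$traits$max_effort_baseline[
    match(tr$participant_id, co$traits$participant_id)]
  eff <- ifelse(tr$chose_hard, tr$effort_hard, tr$effort_easy)
  co$trials$n_presses <- as.integer(round(eff * base * 10)) # keep integers exact
  co$traits$max_effort_baseline <- co$traits$max_effort_baseline * 10
  cc <- calibration_check(co)
  expect_equal(cc$r, 1, tolerance = 1e-6)
  expect_equal(cc$slope, 1, tolerance = 1e-6)
  expect_equal(cc$intercept, 0, tolerance = 1e-3)
  # correlation falls as daily noise grows
  rs <- vapply(c(5, 25, 60), function(s) {
    coN <- generate_cohort(generator_config(
      n_participants = 80, effort = list(daily_sd = s),
      missingness = list(enabled = FALSE)), seed = 17)
    calibration_check(coN)$r
  }, numeric(1))
  expect_true(all(diff(rs) < 0))
})

test_that("power-law practice fit is exact on its own curve and 0 when constant", {
  t <- 1:8
  w <- 30 - 20 * t^(-1)
  pl <- emamot:::power_law_r2(t, w)
  expect_equal(pl$r2, 1, tolerance = 1e-6)
  expect_equal(unname(pl$pars["a"]), 30, tolerance = 1e-3)
  expect_equal(unname(pl$pars["b"]), 20, tolerance = 1e-3)
  expect_equal(emamot:::power_law_r2(t, rep(12, 8))$r2, 0)
})

test_that("state-driven willingness beats the practice curve", {
  cfg <- generator_config(n_participants = 60,
                          choice = list(beta_state_rew = 1.2),
                          missingness = list(enabled = FALSE))
  co <- generate_cohort(cfg, seed = 23)
  pr <- practice_effect_comparison(co)
  expect_gt(pr$paired$mean_state_r2, pr$paired$mean_practice_r2)
  expect_gt(pr$paired$statistic, 0)
})

test_that("willingness mixed model recovers the state effect and trait sign", {
  co <- small_cohort()
  fe <- fit_state_choice_model(co, "willingness")
  expect_gt(fe$estimate[fe$term == "state_z"], 0)
  expect_lt(fe$p.value[fe$term == "state_z"], 0.05)
  expect_lt(fe$estimate[fe$term == "apathy"], 0)
  r2 <- attr(fe, "r2")
  expect_true(r2["marginal"] <= r2["conditional"])
})

test_that("trial-level logistic model recovers design coefficient signs", {
  for (seed in c(31, 32, 33)) {
    co <- apply_validity_filter(generate_cohort(
      generator_config(n_participants = 40), seed = seed))
    fe <- fit_state_choice_model(co, "p_harder_trial")
    expect_gt(fe$estimate[fe$term == "dr_z"], 0)
    expect_lt(fe$estimate[fe$term == "de_z"], 0)
    expect_lt(fe$p.value[fe$term == "dr_z"], 0.001)
  }
  # the state-by-options variant estimates the interaction terms
  co <- small_cohort()
  fe2 <- fit_state_choice_model(co, "p_harder_trial", model = "state_by_options")
  expect_true(all(c("state_z:dr_z", "state_z:de_z") %in% fe2$term))
})

test_that("vigor model finds faster pressing in higher states", {
  co <- small_cohort()
  fe <- fit_state_choice_model(co, "vigor")
  expect_gt(fe$estimate[fe$term == "state_z"], 0)
})

test_that("motivation adds explanatory power over rival states (LRT >= 0)", {
  co <- small_cohort()
  cmp <- compare_state_models(co, "happiness")
  expect_gte(cmp$chisq, 0)
  expect_lt(cmp$p.value, 0.05)
})
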