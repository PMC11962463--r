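test_that("hdi matches enumeration, picks leftmost ties, handles degenerate input", {
  expect_equal(hdi(1:100, 0.90), c(1, 91))
  expect_equal(hdi(rep(3.5, 25)), c(3.5, 3.5))
  set.seed(15)
  for (rep in 1:10) {
    x <- rnorm(57)
    expect_identical(hdi(x, 0.9), hdi_oracle(x, 0.9))
    expect_identical(hdi(x, 0.5), hdi_oracle(x, 0.5))
  }
  x <- rnorm(50000)
  h <- hdi(x, 0.90)
  expect_equal(h[1], -1.645, tolerance = 0.05)
  expect_equal(h[2], 1.645, tolerance = 0.05)
  expect_error(hdi(1:10), "insufficient")
})

test_that("probability of direction counts the median's sign", {
  expect_equal(probability_of_direction(1:25), 1)
  x <- c(-1, 2:20)  # median positive, 19/20 positive
  expect_equal(probability_of_direction(x), 19 / 20)
  set.seed(5)
  for (rep in 1:10) {
    y <- rnorm(41, mean = 0.3)
    med <- median(y)
    want <- mean(sign(y) == sign(med) | y == 0)
    expect_equal(probability_of_direction(y), want)
  }
  z <- rnorm(20000)
  expect_equal(probability_of_direction(z), 0.5, tolerance = 0.02)
})

test_that("split-Rhat and ESS separate mixed from unmixed chains", {
  set.seed(6)
  good <- matrix(rnorm(2000), ncol = 2)
  expect_lt(emamot:::split_rhat(good), 1.02)
  bad <- cbind(rnorm(1000), rnorm(1000, mean = 3))
  expect_gt(emamot:::split_rhat(bad), 1.5)
  expect_gt(emamot:::ess_basic(good), 1000)
  ar <- matrix(as.numeric(arima.sim(list(ar = 0.9), 1000)), ncol = 1)
  expect_lt(emamot:::ess_basic(ar), 300)
})

test_that("a prior-only fit reproduces the prior moments", {
  # a cohort with no valid occasions and no trials: only priors constrain
  st <- tiny_states()[1:4, ]
  st$valid <- FALSE
  co <- ema_cohort(st, tiny_trials()[0, ], tiny_traits())
  fit <- fit_joint_model(co, mcmc = mcmc_settings(chains = 2, warmup = 300,
                                                  iter = 400, l_max = 16),
                         seed = 88)
  bs <- fit$summary[fit$summary$term %in% fit$data$beta_names, ]
  expect_true(all(abs(bs$mean) < 0.25))
  expect_true(all(abs(bs$sd - 1) < 0.25))
  mu <- fit$summary[fit$summary$term == "mu_rew", ]
  expect_equal(mu$sd, 2, tolerance = 0.5)
})

test_that("duplicating participants tightens the state-weight interval", {
  des <- recovery_design(12, 6, 12)
  set.seed(33)
  p <- draw_prior_params(des$data)
  p$beta[["beta_state_rew"]] <- 0.5
  sim <- simulate_from_parameters(p, des)
  mc <- mcmc_settings(chains = 1, warmup = 250, iter = 300, l_max = 24)
  fit1 <- fit_joint_model(sim, mcmc = mc, seed = 1)

  # duplicate every participant under a new id
  dup <- function(d) {
    d2 <- d
    d2$participant_id <- paste0(d2$participant_id, "x")
    rbind(d, d2)
  }
  co2 <- ema_cohort(dup(sim$states), dup(sim$trials), dup(sim$traits),
                    provenance = list(n_occasions = 13))
  fit2 <- fit_joint_model(co2, mcmc = mc, seed = 1)
  w1 <- with(fit1$summary[fit1$summary$term == "beta_state_rew", ],
             hdi_high - hdi_low)
  w2 <- with(fit2$summary[fit2$summary$term == "beta_state_rew", ],
             hdi_high - hdi_low)
  expect_lt(w2, w1)
})

test_that("posterior predictive accuracy is ~1 for deterministic choices and ~0.5 at chance", {
  des <- recovery_design(15, 6, 16)
  set.seed(44)
  p <- draw_prior_params(des$data)
  mc <- mcmc_settings(chains = 1, warmup = 200, iter = 250, l_max = 16)

  p_sat <- p
  p_sat$beta[] <- 0
  p_sat$mu_rew <- 9; p_sat$mu_eff <- 0
  p_sat$sigma_rew <- p_sat$sigma_eff <- 1e-6
  p_sat$rew_offset[] <- 9; p_sat$eff_offset[] <- 0
  sim_sat <- simulate_from_parameters(p_sat, des)
  fit_sat <- fit_joint_model(sim_sat, mcmc = mc, seed = 2)
  ppc_sat <- posterior_predictive_accuracy(fit_sat)
  acc_sat <- ppc_sat$summary$accuracy[ppc_sat$summary$outcome == "choice"]
  expect_gt(acc_sat, 0.95)

  p_null <- p
  p_null$beta[] <- 0
  p_null$mu_rew <- 0; p_null$mu_eff <- 0
  p_null$sigma_rew <- p_null$sigma_eff <- 1e-6
  p_null$rew_offset[] <- 0; p_null$eff_offset[] <- 0
  sim_null <- simulate_from_parameters(p_null, des)
  fit_null <- fit_joint_model(sim_null, mcmc = mc, seed = 3)
  ppc_null <- posterior_predictive_accuracy(fit_null)
  acc_null <- ppc_null$summary$accuracy[ppc_null$summary$outcome == "choice"]
  # in-sample modal accuracy at chance sits slightly above 0.5 because the
  # per-game offsets absorb some choice noise; far below the saturated case
  expect_lt(abs(acc_null - 0.5), 0.12)
  expect_gt(acc_sat - acc_null, 0.3)
})

test_that("the recovery harness completes with minimal draws and reports shape", {
  rec <- run_parameter_recovery(
    n_participants = 8, n_days = 4, n_trials = 12, n_reps = 1,
    mcmc = mcmc_settings(chains = 1, warmup = 60, iter = 30, l_max = 8),
    seed = 12
  )
  expect_setequal(rec$report$parameter, c("rew_sens", "eff_sens", "theta"))
  expect_true(all(is.finite(rec$report$r)))
  expect_true(all(abs(rec$report$r) <= 1))
})

test_that("recovery improves with trials per game", {
  mc <- mcmc_settings(chains = 1, warmup = 250, iter = 250, l_max = 24)
  rs <- vapply(c(12, 24, 48), function(nt) {
    rec <- run_parameter_recovery(n_participants = 12, n_days = 6,
                                  n_trials = nt, n_reps = 1, mcmc = mc,
                                  seed = 500)
    rec$report$r[rec$report$parameter == "rew_sens"]
  }, numeric(1))
  expect_true(rs[3] > rs[1])
})

test_that("tidy and glance expose the fit summary and diagnostics", {
  des <- recovery_design(6, 4, 12)
  set.seed(3)
  p <- draw_prior_params(des$data)
  sim <- simulate_from_parameters(p, des)
  fit <- fit_joint_model(sim, mcmc = mcmc_settings(chains = 2, warmup = 100,
                                                   iter = 50, l_max = 8),
                         seed = 4)
  td <- tidy(fit)
  expect_true(all(c("term", "mean", "hdi_low", "hdi_high", "p_direction",
                    "rhat", "ess") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_draws, 100)
  expect_true(is.logical(gl$converged))
})

test_that("an empirical prior equal to the default reduces stage 2 to a plain fit", {
  co <- fixture_cohort()
  data1 <- prepare_joint_data(co, joint_model_spec("past_and_future"))
  spec2 <- joint_model_spec("past_and_future",
                            beta_prior_mean = c(beta_state_rew_past = 0,
                                                beta_state_rew_future = 0),
                            beta_prior_sd = c(beta_state_rew_past = 1,
                                              beta_state_rew_future = 1))
  data2 <- prepare_joint_data(co, spec2)
  expect_identical(data1$prior_beta_mean, data2$prior_beta_mean)
  expect_identical(data1$prior_beta_sd, data2$prior_beta_sd)
})
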