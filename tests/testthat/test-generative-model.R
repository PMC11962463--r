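test_that("endorsement and choice probabilities match analytic values", {
  expect_equal(irt_endorsement_probability(0.7, 0.7), 0.5)
  # independent evaluation: 1 / (1 + exp(-0.5))
  expect_equal(irt_endorsement_probability(1.0, 0.5), 1 / (1 + exp(-0.5)),
               tolerance = 1e-12)
  expect_equal(irt_endorsement_probability(1.0, 0.5), 0.6225, tolerance = 1e-4)
  expect_equal(irt_endorsement_probability(50, 0), 1, tolerance = 1e-12)
  expect_error(irt_endorsement_probability(0, -0.1), "delta")

  expect_equal(trial_choice_probability(0, 0, 2, 1), 0.5)
  expect_equal(trial_choice_probability(1, 0, 2, 3), 1 / (1 + exp(-2)))
  expect_equal(trial_choice_probability(1, 0, 2, 3), 0.8808, tolerance = 1e-4)
  p <- trial_choice_probability(1, c(0.5, 1, 2), 1, 1)
  expect_true(all(diff(p) < 0))
})

test_that("binarization maps the three 'true' categories to 1", {
  expect_equal(binarize_items(c(1, 2, 3, 4, 5, 6, 7)),
               c(0L, 0L, 0L, 0L, 1L, 1L, 1L))
  expect_true(is.na(binarize_items(NA)))
  # a raw reverse-worded response of 7 is stored as 8 - 7 = 1 -> disagreement
  expect_equal(binarize_items(8L - 7L), 0L)
})

test_that("joint log density equals the naive loop oracle", {
  co <- fixture_cohort()
  for (mode in c("current", "past_and_future")) {
    spec <- joint_model_spec(mode)
    data <- prepare_joint_data(co, spec)
    for (seed in 1:3) {
      p <- fixture_params(data, seed)
      got <- joint_log_density(co, p, spec, data = data)
      want <- naive_joint_lp(co, p, lag_mode = mode)
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("log density is prior-only for an empty cohort and additive in data", {
  co <- fixture_cohort()
  spec <- joint_model_spec()
  data <- prepare_joint_data(co, spec)
  p <- fixture_params(data, 4)
  lp_full <- joint_log_density(co, p, spec, data = data)

  # remove all observations: prior-only density
  d0 <- data
  d0$item_i <- d0$item_t <- d0$item_m <- d0$item_y <- integer(0)
  d0$ch_cell <- d0$ch_y <- integer(0)
  d0$ch_dr <- d0$ch_de <- numeric(0)
  lp_prior <- emamot:::emamot_lp_grad(emamot:::params_to_vector(p, data),
                                      unclass(d0), FALSE, FALSE)$lp
  # duplicating every observation doubles the likelihood part exactly
  d2 <- data
  for (nm in c("item_i", "item_t", "item_m", "item_y")) d2[[nm]] <- rep(d2[[nm]], 2)
  for (nm in c("ch_cell", "ch_y", "ch_dr", "ch_de")) d2[[nm]] <- rep(d2[[nm]], 2)
  lp_dup <- emamot:::emamot_lp_grad(emamot:::params_to_vector(p, data),
                                    unclass(d2), FALSE, FALSE)$lp
  expect_equal(lp_dup - lp_prior, 2 * (lp_full - lp_prior), tolerance = 1e-9)
})

test_that("non-finite parameters yield -Inf with the offending symbol named", {
  co <- fixture_cohort()
  data <- prepare_joint_data(co, joint_model_spec())
  p <- fixture_params(data, 2)
  p$mu_rew <- NaN
  expect_warning(lp <- joint_log_density(co, p, data = data), "mu_rew")
  expect_identical(lp, -Inf)
})

test_that("missing occasions have theta equal to the group mean exactly", {
  co <- fixture_cohort()  # B's occasion 2 is invalid
  data <- prepare_joint_data(co, joint_model_spec())
  p <- fixture_params(data, 5)
  expect_equal(p$theta_offset[2, 3], 0)  # no offset parameter exists there
  tz <- emamot:::theta_from_params(p, data)
  expect_equal(tz$theta[2, 3], p$theta_mu[3])
  # and that occasion contributes no item terms
  expect_false(any(data$item_i == 1L & data$item_t == 2L))
})

test_that("analytic gradient matches finite differences", {
  co <- fixture_cohort()
  data <- prepare_joint_data(co, joint_model_spec())
  p <- fixture_params(data, 6)
  v <- emamot:::params_to_vector(p, data)
  lg <- emamot:::emamot_lp_grad(v, unclass(data), TRUE, TRUE)
  eps <- 1e-6
  idx <- seq_along(v)
  fd <- vapply(idx, function(j) {
    vp <- v; vp[j] <- vp[j] + eps
    vm <- v; vm[j] <- vm[j] - eps
    (emamot:::emamot_lp_grad(vp, unclass(data), FALSE, TRUE)$lp -
       emamot:::emamot_lp_grad(vm, unclass(data), FALSE, TRUE)$lp) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(fd - lg$grad)), 1e-5)
})

test_that("model simulation is reproducible and matches analytic frequencies", {
  des <- recovery_design(3, 3, 12)
  set.seed(11)
  p <- draw_prior_params(des$data)
  set.seed(20)
  a <- simulate_from_parameters(p, des)
  set.seed(20)
  b <- simulate_from_parameters(p, des)
  expect_identical(a$states, b$states)
  expect_identical(a$trials, b$trials)

  # large-sample endorsement frequency: constant theta via zero offsets
  des2 <- recovery_design(120, 14, 12)
  p2 <- draw_prior_params(des2$data)
  p2$sigma_theta <- 1e-8
  p2$theta_offset[] <- 0
  p2$theta_mu[] <- 0.4
  p2$delta <- c(0.1, 0.5, 1, 1.5)
  set.seed(9)
  sim <- simulate_from_parameters(p2, des2)
  bin <- binarize_items(as.matrix(sim$states[, c("m1", "m2", "m3", "m4")]))
  freq <- colMeans(bin)
  expect_equal(unname(freq), plogis(0.4 - p2$delta), tolerance = 0.02)
})

test_that("zero state weight leaves simulated reward sensitivity flat in theta", {
  des <- recovery_design(50, 10, 12)
  set.seed(14)
  p <- draw_prior_params(des$data)
  p$beta[["beta_state_rew"]] <- 0
  p$beta[["beta_trait_rew"]] <- 0
  sim <- simulate_from_parameters(p, des)
  gt <- attr(sim, "ground_truth")
  # with both modulations off, rew_sens is exactly its offset: no theta path
  expect_equal(gt$cells$rew_sens, p$rew_offset, tolerance = 1e-12)
  expect_gt(sd(gt$cells$z_current), 0)
})
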