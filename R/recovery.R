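#' Parameter-recovery harness for the joint model
#'
#' For each replicate: draws a ground-truth parameter set from the model
#' priors, simulates a fully observed cohort on a fresh study design,
#' refits the joint model by MCMC, and pools the generating against the
#' recovered (posterior-mean) values of the per-participant-per-game reward
#' and effort sensitivities and the per-participant-per-occasion latent
#' state. Reports pooled Pearson r (with normal-approximation CI), bias and
#' RMSE per parameter.
#'
#' @param n_participants,n_days,n_trials Study design of each replicate.
#' @param n_reps Number of replicates.
#' @param spec A [joint_model_spec()].
#' @param mcmc An [mcmc_settings()]; short chains are typical here.
#' @param seed Optional seed.
#' @return An object of class `ema_recovery_report`: `report` tibble
#'   (parameter, r, conf.low, conf.high, bias, rmse, n), `pairs` (pooled
#'   truth/estimate pairs), `meta`.
#' @export
run_parameter_recovery <- function(n_participants = 40, n_days = 14,
                                   n_trials = 24, n_reps = 3,
                                   spec = joint_model_spec(),
                                   mcmc = mcmc_settings(chains = 2, warmup = 400,
                                                        iter = 400),
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pairs <- vector("list", n_reps)
  n_failed <- 0L
  for (r in seq_len(n_reps)) {
    design <- recovery_design(n_participants, n_days, n_trials, n_catch = 0,
                              spec = spec)
    truth <- draw_prior_params(design$data)
    cohort <- simulate_from_parameters(truth, design)
    fit <- fit_joint_model(cohort, spec = spec, mcmc = mcmc)
    if (any(!is.finite(fit$summary$mean))) {
      n_failed <- n_failed + 1L
      next
    }
    gt <- attr(cohort, "ground_truth")
    true_theta <- gt$theta[gt$valid]
    est_theta <- fit$theta_mean[fit$data$valid == 1L]
    key <- c("participant_id", "game_index")
    cell_truth <- gt$cells |> select(all_of(key), true_rew = "rew_sens",
                                     true_eff = "eff_sens")
    cell_est <- fit$cell_means |> select(all_of(key), est_rew = "rew_sens",
                                         est_eff = "eff_sens")
    cells <- inner_join(cell_truth, cell_est, by = key)
    pairs[[r]] <- bind_rows(
      tibble(parameter = "rew_sens", truth = cells$true_rew, est = cells$est_rew),
      tibble(parameter = "eff_sens", truth = cells$true_eff, est = cells$est_eff),
      tibble(parameter = "theta", truth = true_theta, est = est_theta)
    ) |> mutate(rep = r)
  }
  pairs <- bind_rows(pairs)
  if (!nrow(pairs)) abort("every recovery replicate failed")
  # correlate within replicate, then combine on the Fisher z scale, so the
  # reported r is the within-dataset recovery (pooling raw pairs across
  # replicates would inflate r through shared replicate-level scale)
  report <- pairs |>
    group_by(.data$parameter, .data$rep) |>
    summarise(z = atanh(cor(.data$truth, .data$est)), n = n(),
              bias = mean(.data$est - .data$truth),
              sse = sum((.data$est - .data$truth)^2), .groups = "drop") |>
    group_by(.data$parameter) |>
    summarise(
      zbar = sum(.data$z * (.data$n - 3)) / sum(.data$n - 3),
      se = 1 / sqrt(sum(.data$n - 3)),
      bias = sum(.data$bias * .data$n) / sum(.data$n),
      rmse = sqrt(sum(.data$sse) / sum(.data$n)),
      n = sum(.data$n), .groups = "drop"
    ) |>
    mutate(
      r = tanh(.data$zbar),
      conf.low = tanh(.data$zbar - qnorm(0.975) * .data$se),
      conf.high = tanh(.data$zbar + qnorm(0.975) * .data$se)
    ) |>
    select("parameter", "r", "conf.low", "conf.high", "bias", "rmse", "n")
  structure(
    list(report = report, pairs = pairs,
         meta = list(n_participants = n_participants, n_days = n_days,
                     n_trials = n_trials, n_reps = n_reps,
                     n_failed = n_failed, mcmc = mcmc, seed = seed)),
    class = "ema_recovery_report"
  )
}

#' @export
print.ema_recovery_report <- function(x, ...) {
  cat(sprintf("Parameter recovery over %d replicate(s) (%d failed):\n",
              x$meta$n_reps, x$meta$n_failed))
  print(x$report)
  invisible(x)
}

#' Past- versus future-state modulation of reward sensitivity
#'
#' Two-stage temporal analysis of the state-reward coupling. Stage 1 fits
#' the current-state model. Stage 2 replaces the current-state term with
#' the previous and next valid occasions' states in the same model, both
#' given the *empirical prior* - a normal with the stage-1 posterior mean
#' and SD of the current-state effect - and reports each term's posterior
#' summary plus the contrast draws (past minus future, and current minus
#' past across the two stages' independent draws).
#'
#' @param cohort An [ema_cohort()].
#' @param mcmc An [mcmc_settings()].
#' @param stage1 Optionally a pre-computed current-state [fit_joint_model()].
#' @param seed Optional seed.
#' @return A list of class `ema_lag_comparison`: `summary` (posterior
#'   summaries of the past and future terms), `contrasts`, `stage1`,
#'   `stage2`.
#' @export
lag_comparison <- function(cohort, mcmc = mcmc_settings(), stage1 = NULL,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(stage1)) {
    stage1 <- fit_joint_model(cohort, joint_model_spec("current"), mcmc)
  }
  cur <- stage1$beta_draws[, "beta_state_rew"]
  emp_mean <- mean(cur); emp_sd <- sd(cur)
  spec2 <- joint_model_spec(
    "past_and_future",
    beta_prior_mean = c(beta_state_rew_past = emp_mean,
                        beta_state_rew_future = emp_mean),
    beta_prior_sd = c(beta_state_rew_past = emp_sd,
                      beta_state_rew_future = emp_sd)
  )
  stage2 <- fit_joint_model(cohort, spec2, mcmc)
  past <- stage2$beta_draws[, "beta_state_rew_past"]
  fut <- stage2$beta_draws[, "beta_state_rew_future"]
  n <- min(length(cur), length(past))
  summary <- bind_rows(
    posterior_summary(past, "beta_state_rew_past"),
    posterior_summary(fut, "beta_state_rew_future"),
    posterior_summary(cur, "beta_state_rew_current")
  )
  contrasts <- bind_rows(
    posterior_summary(past - fut, "past_minus_future"),
    posterior_summary(cur[seq_len(n)] - past[seq_len(n)], "current_minus_past")
  )
  structure(list(summary = summary, contrasts = contrasts,
                 empirical_prior = c(mean = emp_mean, sd = emp_sd),
                 stage1 = stage1, stage2 = stage2),
            class = "ema_lag_comparison")
}

#' @export
print.ema_lag_comparison <- function(x, ...) {
  cat("Lagged-state modulation of reward sensitivity:\n")
  print(x$summary)
  cat("Contrasts:\n")
  print(x$contrasts)
  invisible(x)
}
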