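#' Pipeline configuration
#'
#' Bundles the options of [run_pipeline()]: which stages to run, the
#' generator configuration, model spec, MCMC settings and seed.
#'
#' @param stages Character vector among `"generate"`, `"describe"`,
#'   `"behavior"`, `"fit"`, `"recover"`.
#' @param generator A [generator_config()].
#' @param spec A [joint_model_spec()].
#' @param mcmc An [mcmc_settings()].
#' @param recovery Named list of recovery-harness sizes.
#' @param seed Integer seed recorded in the report.
#' @param out Optional path of the JSON report to write.
#' @param data_dir Optional directory: the generate stage writes the
#'   filtered cohort (`states.csv`, `trials.csv`, `traits.csv`) and a
#'   `ground_truth.json` with the generative coefficients there.
#' @return A list of class `ema_pipeline_config`.
#' @export
pipeline_config <- function(stages = c("generate", "describe", "behavior"),
                            generator = generator_config(),
                            spec = joint_model_spec(),
                            mcmc = mcmc_settings(),
                            recovery = list(n_participants = 20, n_days = 6,
                                            n_trials = 16, n_reps = 1),
                            seed = 1, out = NULL, data_dir = NULL) {
  known <- c("generate", "describe", "behavior", "fit", "recover")
  bad <- setdiff(stages, known)
  if (length(bad)) abort(sprintf("unknown stage '%s'", bad[1]))
  structure(list(stages = stages, generator = generator, spec = spec,
                 mcmc = mcmc, recovery = recovery, seed = seed, out = out,
                 data_dir = data_dir),
            class = "ema_pipeline_config")
}

num <- function(x) unname(round(as.numeric(x), 6))

#' Run the analysis pipeline end to end
#'
#' Executes the enabled stages in order - generate a synthetic cohort,
#' validity-filter it, compute the descriptive state analyses, the task
#' behavior analyses, optionally the joint-model fit and the recovery
#' harness - and returns a single machine-readable report keyed by
#' analysis. Identical config and seed give an identical report (except
#' the timing fields). If `config$out` is set, the report is also written
#' as JSON.
#'
#' @param config A [pipeline_config()].
#' @return A nested list report (invisibly also written to `config$out`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  report <- list(seed = config$seed, stages = config$stages, timing = list())
  stage <- function(name, f) {
    t0 <- Sys.time()
    out <- tryCatch(f(), error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = "emamot_stage_failure")
    })
    report$timing[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    out
  }
  cohort <- NULL
  if ("generate" %in% config$stages) {
    cohort <- stage("generate", function() {
      raw <- generate_cohort(config$generator, seed = config$seed)
      filtered <- apply_validity_filter(raw)
      report$generate <<- list(
        n_recruited = nrow(raw$traits),
        n_retained = nrow(filtered$traits),
        retention = num(nrow(filtered$traits) / nrow(raw$traits)),
        n_valid_states = sum(filtered$states$valid),
        n_trials = nrow(filtered$trials)
      )
      if (!is.null(config$data_dir)) {
        write_cohort(filtered, config$data_dir)
        gt <- attr(filtered, "ground_truth")
        jsonlite::write_json(
          list(betas = as.list(gt$betas), design_sd = as.list(gt$design_sd),
               seed = config$seed),
          file.path(config$data_dir, "ground_truth.json"),
          auto_unbox = TRUE, digits = NA
        )
      }
      filtered
    })
  }
  if ("describe" %in% config$stages) {
    stage("describe", function() {
      rmc <- state_covariate_rmcorr(cohort)
      sp <- between_person_spearman(cohort)
      tm <- trait_state_regression(cohort, "mean")
      ts <- trait_state_regression(cohort, "sd")
      wk <- weekday_analysis(cohort)
      ac <- state_autocorrelation(cohort, "summary_acf")
      wd <- state_autocorrelation(cohort, "within_day_model")
      report$describe <<- list(
        rmcorr = setNames(num(rmc$r), rmc$covariate),
        spearman_mean_states = setNames(
          num(sp$rho), paste(sp$var1, sp$var2, sep = "_")),
        trait_mean_state = list(beta = num(tm$estimate[tm$term == "apathy"]),
                                r2 = num(attr(tm, "r.squared"))),
        trait_sd_state = list(beta = num(ts$estimate[ts$term == "apathy"]),
                              r2 = num(attr(ts, "r.squared"))),
        weekday = list(F = num(wk$anova$statistic), p = num(wk$anova$p.value),
                       split_diff = num(wk$paired$estimate),
                       cohens_d = num(wk$paired$cohens_d)),
        acf = setNames(num(ac$summary$mean), paste0("lag", ac$summary$lag)),
        within_day = setNames(num(wd$estimate), wd$term)
      )
      NULL
    })
  }
  if ("behavior" %in% config$stages) {
    stage("behavior", function() {
      da <- discounting_anova(cohort)
      ss <- success_stability(cohort)
      cc <- calibration_check(cohort)
      icc <- test_retest_icc(cohort, "p_harder")
      pr <- practice_effect_comparison(cohort)
      will <- fit_state_choice_model(cohort, "willingness")
      trial <- fit_state_choice_model(cohort, "p_harder_trial")
      report$behavior <<- list(
        discounting_anova = setNames(
          lapply(seq_len(nrow(da)), function(i)
            list(F = num(da$statistic[i]), eta_sq = num(da$eta_sq[i]))),
          da$term),
        success = list(slope = num(ss$estimate), mean = num(ss$mean_success)),
        calibration_r = num(cc$r),
        icc_p_harder = num(icc$summary$mean),
        practice = list(practice_r2 = num(pr$paired$mean_practice_r2),
                        state_minus_practice_r2 = num(pr$paired$estimate)),
        willingness_fixed_effects = setNames(num(will$estimate), will$term),
        trial_fixed_effects = setNames(num(trial$estimate), trial$term)
      )
      NULL
    })
  }
  if ("fit" %in% config$stages) {
    stage("fit", function() {
      fit <- fit_joint_model(cohort, config$spec, config$mcmc,
                             seed = config$seed)
      ppc <- posterior_predictive_accuracy(fit)
      bs <- filter(fit$summary, .data$term %in% fit$data$beta_names)
      report$fit <<- list(
        betas = setNames(
          lapply(seq_len(nrow(bs)), function(i)
            list(mean = num(bs$mean[i]), sd = num(bs$sd[i]),
                 hdi90 = c(num(bs$hdi_low[i]), num(bs$hdi_high[i])),
                 p_direction = num(bs$p_direction[i]))),
          bs$term),
        converged = fit$converged,
        ppc_accuracy = setNames(num(ppc$summary$accuracy), ppc$summary$outcome)
      )
      NULL
    })
  }
  if ("recover" %in% config$stages) {
    stage("recover", function() {
      rec <- do.call(run_parameter_recovery, c(
        config$recovery, list(spec = config$spec, mcmc = config$mcmc,
                              seed = config$seed)
      ))
      report$recover <<- setNames(num(rec$report$r), rec$report$parameter)
      NULL
    })
  }
  if (!is.null(config$out)) {
    jsonlite::write_json(report, config$out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  report
}
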