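#' Repeated-measures ANOVA of reward-effort discounting
#'
#' Checks that the task elicits discounting: the per-participant mean
#' probability of choosing the harder option, in each cell of the
#' reward-difference x effort-difference design, is rank-transformed and
#' submitted to a repeated-measures ANOVA with both differences and their
#' interaction as within-participant factors.
#'
#' @param cohort An [ema_cohort()] (catch trials are removed internally).
#' @return A tibble with one row per effect: `df1`, `df2`, `statistic` (F),
#'   `p.value`, `eta_sq` (SS_effect / SS_total), `flagged` if degenerate.
#' @export
discounting_anova <- function(cohort) {
  cells <- cohort$trials |>
    filter(!.data$is_catch) |>
    mutate(
      dr = factor(.data$reward_hard - .data$reward_easy),
      de = factor(round(.data$effort_hard - .data$effort_easy, 10))
    ) |>
    group_by(.data$participant_id, .data$dr, .data$de) |>
    summarise(p_harder = mean(.data$chose_hard), .groups = "drop")
  design <- tidyr::expand_grid(dr = unique(cells$dr), de = unique(cells$de))
  missing_cell <- anti_join(design, distinct(cells, .data$dr, .data$de),
                            by = c("dr", "de"))
  if (nrow(missing_cell)) {
    abort(sprintf("cell-coverage error: no data in design cell dr=%s, de=%s",
                  missing_cell$dr[1], missing_cell$de[1]),
          class = "emamot_cell_coverage")
  }
  if (var(cells$p_harder) < 1e-14) {
    return(tibble(
      term = c("dr", "de", "dr:de"), df1 = NA_integer_, df2 = NA_integer_,
      statistic = NA_real_, p.value = NA_real_, eta_sq = 0, flagged = TRUE
    ))
  }
  cells$rank_p <- rank(cells$p_harder)
  cells$participant_id <- factor(cells$participant_id)
  av <- suppressWarnings(aov(
    rank_p ~ dr * de + Error(participant_id / (dr * de)), data = cells
  ))
  sm <- summary(av)
  ss_total <- sum(vapply(sm, function(s) sum(s[[1]][["Sum Sq"]]), numeric(1)))
  pull_effect <- function(term) {
    for (s in sm) {
      tab <- s[[1]]
      rows <- trimws(rownames(tab))
      if (term %in% rows) {
        i <- match(term, rows)
        resid <- match("Residuals", rows)
        return(tibble(
          term = term, df1 = tab$Df[i], df2 = tab$Df[resid],
          statistic = tab$`F value`[i], p.value = tab$`Pr(>F)`[i],
          eta_sq = tab$`Sum Sq`[i] / ss_total, flagged = FALSE
        ))
      }
    }
    tibble(term = term, df1 = NA_integer_, df2 = NA_integer_,
           statistic = NA_real_, p.value = NA_real_, eta_sq = NA_real_,
           flagged = TRUE)
  }
  bind_rows(pull_effect("dr"), pull_effect("de"), pull_effect("dr:de"))
}

#' Stability of trial success over the study
#'
#' Binomial regression of per-game success counts on study day, to confirm
#' choices reflect reward-effort (not probability) discounting. Also reports
#' the proportion of trials in which the pressed count exceeded the
#' calibrated maximum.
#'
#' @param cohort An [ema_cohort()].
#' @return A tibble with the day slope (`estimate`, 95% CI, `p.value`),
#'   `prop_exceed_max`, and `separation` flag (no failures anywhere: slope
#'   unidentified, a warning is raised).
#' @export
success_stability <- function(cohort) {
  tr <- filter(cohort$trials, !.data$is_catch) |>
    left_join(select(cohort$traits, "participant_id", "max_effort_baseline"),
              by = "participant_id")
  per_game <- tr |>
    group_by(.data$participant_id, .data$game_index) |>
    summarise(
      succ = sum(.data$success), fail = sum(!.data$success),
      day = first(.data$occasion_index + 1L) %/% 2L,
      .groups = "drop"
    )
  prop_exceed <- mean(tr$n_presses > tr$max_effort_baseline, na.rm = TRUE)
  if (sum(per_game$fail) == 0) {
    warn("complete separation: every trial succeeded; day slope unidentified",
         class = "emamot_separation_warning")
    return(tibble(estimate = NA_real_, conf.low = NA_real_, conf.high = NA_real_,
                  p.value = NA_real_, mean_success = 1,
                  prop_exceed_max = prop_exceed, separation = TRUE))
  }
  fit <- glm(cbind(succ, fail) ~ day, family = binomial(), data = per_game)
  sm <- summary(fit)$coefficients
  est <- sm["day", "Estimate"]; se <- sm["day", "Std. Error"]
  tibble(
    estimate = est,
    conf.low = est - qnorm(0.975) * se, conf.high = est + qnorm(0.975) * se,
    p.value = sm["day", "Pr(>|z|)"],
    mean_success = sum(per_game$succ) / sum(per_game$succ + per_game$fail),
    prop_exceed_max = prop_exceed, separation = FALSE
  )
}

#' Maximum-effort calibration check
#'
#' Each game's implied maximum press count (the largest trial-level
#' `n_presses / chosen effort fraction`) estimates that day's true maximum.
#' The baseline calibrated maximum should predict the mean implied maximum
#' over all subsequent games; the least-squares fit is reported for
#' comparison with the identity line.
#'
#' @param cohort An [ema_cohort()].
#' @return A tibble: Pearson `r` with 95% CI and `p.value`, `slope`,
#'   `intercept`, `n`.
#' @export
calibration_check <- function(cohort) {
  implied <- cohort$trials |>
    filter(!.data$is_catch, .data$game_index > 0) |>
    mutate(chosen_effort = ifelse(.data$chose_hard, .data$effort_hard,
                                  .data$effort_easy)) |>
    group_by(.data$participant_id, .data$game_index) |>
    summarise(day_max = max(.data$n_presses / .data$chosen_effort),
              .groups = "drop") |>
    group_by(.data$participant_id) |>
    summarise(mean_max = mean(.data$day_max), .groups = "drop") |>
    left_join(cohort$traits, by = "participant_id")
  if (nrow(implied) < 3) {
    abort("calibration check needs >= 3 participants",
          class = "emamot_insufficient_data")
  }
  ct <- cor.test(implied$max_effort_baseline, implied$mean_max)
  fit <- lm(mean_max ~ max_effort_baseline, data = implied)
  tibble(
    r = unname(ct$estimate), conf.low = ct$conf.int[1], conf.high = ct$conf.int[2],
    p.value = ct$p.value, slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]), n = nrow(implied)
  )
}

power_law_r2 <- function(t, w) {
  if (length(unique(w)) == 1 || var(w) < 1e-14) {
    return(list(r2 = 0, converged = TRUE, pars = c(a = w[1], b = 0, cc = 1)))
  }
  st <- list(a = max(w), b = max(max(w) - min(w), 0.1), cc = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(w ~ a - b * t^(-cc), start = st,
                      lower = c(a = -Inf, b = 0, cc = 0.01),
                      upper = c(a = Inf, b = Inf, cc = 10),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    lf <- lm(w ~ log(t))
    return(list(r2 = summary(lf)$r.squared, converged = FALSE,
                pars = c(a = NA, b = NA, cc = NA)))
  }
  r2 <- 1 - sum(residuals(fit)^2) / sum((w - mean(w))^2)
  list(r2 = r2, converged = TRUE, pars = coef(fit))
}

#' Practice effects versus state effects on willingness
#'
#' Fits, per participant, (a) a plateauing power-law practice curve
#' `willingness_t = a - b t^(-c)` (b, c >= 0) over game order by bounded
#' least squares, and (b) the state alternative `willingness ~ state_z`,
#' then compares the two R-squared vectors with a paired t test
#' (state minus practice).
#'
#' @param cohort An [ema_cohort()].
#' @param min_games Minimum games per participant (default 4).
#' @return A list of class `ema_practice`: `per_participant` (tibble with
#'   `practice_r2`, `state_r2`, `converged`) and `paired` (t test of the
#'   R-squared difference).
#' @export
practice_effect_comparison <- function(cohort, min_games = 4) {
  summ <- compute_summary_measures(cohort) |>
    filter(!is.na(.data$willingness))
  per <- summ |>
    group_by(.data$participant_id) |>
    filter(n() >= min_games) |>
    group_modify(function(d, key) {
      t <- d$game_index + 1
      pl <- power_law_r2(t, d$willingness)
      ok <- !is.na(d$state_z)
      state_r2 <- if (sum(ok) >= 3 && var(d$state_z[ok]) > 0) {
        summary(lm(willingness ~ state_z, data = d[ok, ]))$r.squared
      } else NA_real_
      tibble(practice_r2 = pl$r2, state_r2 = state_r2,
             converged = pl$converged, n_games = nrow(d))
    }) |>
    ungroup()
  both <- filter(per, !is.na(.data$state_r2))
  dd <- both$state_r2 - both$practice_r2
  tt <- t.test(dd)
  paired <- tibble(
    mean_practice_r2 = mean(per$practice_r2),
    mean_state_r2 = mean(both$state_r2),
    estimate = mean(dd), conf.low = tt$conf.int[1], conf.high = tt$conf.int[2],
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p.value = tt$p.value, n = length(dd)
  )
  structure(list(per_participant = per, paired = paired),
            class = "ema_practice")
}

#' @export
print.ema_practice <- function(x, ...) {
  cat(sprintf(
    "Practice power-law mean R^2 = %.3f; state-model mean R^2 = %.3f\n",
    x$paired$mean_practice_r2, x$paired$mean_state_r2))
  cat(sprintf("Paired t(%d) = %.2f, p = %.3g, mean R^2 difference = %.3f\n",
              x$paired$df, x$paired$statistic, x$paired$p.value,
              x$paired$estimate))
  invisible(x)
}

covariate_z <- function(cohort, var) {
  state_scores(cohort) |>
    group_by(.data$participant_id) |>
    mutate(cov_z = {
      v <- .data[[var]]
      ok <- .data$valid & !is.na(v)
      m <- mean(v[ok]); s <- sd(v[ok])
      ifelse(ok & s > 0, (v - m) / s, NA_real_)
    }) |>
    ungroup() |>
    select("participant_id", "occasion_index", "cov_z")
}

nakagawa_r2 <- function(fit, logistic = FALSE) {
  vf <- var(as.numeric(predict(fit, re.form = NA)))
  vc <- lme4::VarCorr(fit)
  vr <- sum(vapply(vc, function(m) sum(diag(m)), numeric(1)))
  ve <- if (logistic) pi^2 / 3 else attr(vc, "sc")^2
  c(marginal = vf / (vf + vr + ve), conditional = (vf + vr) / (vf + vr + ve))
}

fixef_table <- function(fit, logistic = FALSE) {
  sm <- summary(fit)$coefficients
  est <- sm[, "Estimate"]; se <- sm[, "Std. Error"]
  p <- if (logistic) sm[, "Pr(>|z|)"] else sm[, "Pr(>|t|)"]
  tibble(
    term = rownames(sm), estimate = unname(est), std.error = unname(se),
    conf.low = unname(est - qnorm(0.975) * se),
    conf.high = unname(est + qnorm(0.975) * se),
    p.value = unname(p)
  )
}

#' Mixed-effects models linking states, traits and behavior
#'
#' Fits the hierarchical regressions of behavior on within-person
#' normalized state motivation and trait apathy:
#'
#' * `outcome = "willingness"`: per-game willingness (chosen minus unchosen
#'   effort, %) on state x trait with age and sex covariates, a
#'   person-specific random state slope and random intercept.
#' * `outcome = "p_harder_trial"`: trial-level logistic model of choosing
#'   the harder option. `model = "main"` uses reward/effort differences,
#'   their interaction, state, trait and state x trait; `model =
#'   "state_by_options"` instead estimates the state x reward-difference
#'   and state x effort-difference interactions.
#' * `outcome = "vigor"`: trial-level press vigor on state x trait.
#'
#' Reward/effort differences are centered and scaled by the design-grid SD.
#' Linear models use REML with Satterthwaite p-values; the logistic model
#' uses Laplace ML with Wald p-values. If the full random structure fails
#' to converge the model is refitted with independent, then
#' intercept-only, random effects and flagged.
#'
#' @param cohort An [ema_cohort()] (validity-filtered).
#' @param outcome One of `"willingness"`, `"p_harder_trial"`, `"vigor"`.
#' @param model `"main"` or `"state_by_options"` (trial-level only).
#' @return A tibble of fixed effects with 95% CIs and p-values; attributes
#'   `n_obs`, `r2` (marginal/conditional), `fit` (the merMod), and
#'   `simplified` when the random structure was reduced.
#' @export
fit_state_choice_model <- function(cohort,
                                   outcome = c("willingness", "p_harder_trial",
                                               "vigor"),
                                   model = c("main", "state_by_options")) {
  outcome <- match.arg(outcome)
  model <- match.arg(model)
  summ <- compute_summary_measures(cohort)
  simplified <- FALSE
  if (outcome == "willingness") {
    d <- filter(summ, !is.na(.data$state_z), !is.na(.data$apathy))
    forms <- list(
      willingness ~ state_z * apathy + age + sex + (1 + state_z | participant_id),
      willingness ~ state_z * apathy + age + sex + (1 + state_z || participant_id),
      willingness ~ state_z * apathy + age + sex + (1 | participant_id)
    )
    fit <- NULL
    for (k in seq_along(forms)) {
      fit <- tryCatch(
        lmerTest::lmer(forms[[k]], data = d,
                       control = lme4::lmerControl(check.conv.singular = "ignore")),
        error = function(e) NULL, warning = function(w) NULL
      )
      if (!is.null(fit)) { simplified <- k > 1; break }
    }
    out <- fixef_table(fit)
    attr(out, "r2") <- nakagawa_r2(fit)
  } else {
    tr <- cohort$trials |>
      filter(!.data$is_catch) |>
      mutate(dr = .data$reward_hard - .data$reward_easy,
             de = .data$effort_hard - .data$effort_easy)
    std <- standardize_design(tr$dr, tr$de)
    tr <- tr |>
      mutate(
        dr_z = (.data$dr - mean(.data$dr)) / std$sd_dr,
        de_z = (.data$de - mean(.data$de)) / std$sd_de
      ) |>
      left_join(select(state_scores(cohort), "participant_id",
                       "occasion_index", "state_z"),
                by = c("participant_id", "occasion_index")) |>
      left_join(cohort$traits, by = "participant_id") |>
      filter(!is.na(.data$state_z), !is.na(.data$apathy))
    if (outcome == "p_harder_trial") {
      form <- if (model == "main") {
        chose_hard ~ dr_z * de_z + state_z * apathy + (1 | participant_id)
      } else {
        chose_hard ~ state_z * dr_z + state_z * de_z + dr_z:de_z +
          (1 | participant_id)
      }
      fit <- lme4::glmer(form, data = tr, family = binomial(),
                         control = lme4::glmerControl(check.conv.singular = "ignore"))
      out <- fixef_table(fit, logistic = TRUE)
      attr(out, "r2") <- nakagawa_r2(fit, logistic = TRUE)
    } else {
      lag_ref <- max(tr$mean_press_lag_ms, na.rm = TRUE)
      tr$vigor <- lag_ref - tr$mean_press_lag_ms
      fit <- tryCatch(
        lmerTest::lmer(vigor ~ state_z * apathy + (1 + state_z | participant_id),
                       data = tr,
                       control = lme4::lmerControl(check.conv.singular = "ignore")),
        error = function(e) NULL, warning = function(w) NULL
      )
      if (is.null(fit)) {
        simplified <- TRUE
        fit <- lmerTest::lmer(vigor ~ state_z * apathy + (1 | participant_id),
                              data = tr,
                              control = lme4::lmerControl(check.conv.singular = "ignore"))
      }
      out <- fixef_table(fit)
      attr(out, "r2") <- nakagawa_r2(fit)
    }
  }
  attr(out, "n_obs") <- stats::nobs(fit)
  attr(out, "fit") <- fit
  attr(out, "simplified") <- simplified
  class(out) <- c("ema_fixef", class(out))
  out
}

#' Likelihood-ratio comparison of motivation against a rival state
#'
#' Tests whether state motivation explains willingness over and above a
#' covariate state (happiness, fatigue, or sleep quality): both models share
#' the rival state's within-person z-score, trait apathy and demographic
#' covariates with a random intercept; the larger model adds state
#' motivation. Models are fitted by maximum likelihood and compared by a
#' likelihood-ratio test (1 df).
#'
#' @param cohort An [ema_cohort()].
#' @param rival `"happiness"`, `"fatigue"`, or `"sleep"`.
#' @return A tibble: `chisq`, `df`, `p.value`, log-likelihoods.
#' @export
compare_state_models <- function(cohort,
                                 rival = c("happiness", "fatigue", "sleep")) {
  rival <- match.arg(rival)
  d <- compute_summary_measures(cohort) |>
    left_join(covariate_z(cohort, rival), by = c("participant_id", "occasion_index")) |>
    filter(!is.na(.data$state_z), !is.na(.data$cov_z), !is.na(.data$apathy))
  m0 <- lme4::lmer(willingness ~ cov_z + apathy + age + sex + (1 | participant_id),
                   data = d, REML = FALSE,
                   control = lme4::lmerControl(check.conv.singular = "ignore"))
  m1 <- update(m0, . ~ . + state_z)
  an <- anova(m0, m1)
  tibble(
    rival = rival,
    chisq = an$Chisq[2], df = an$Df[2], p.value = an$`Pr(>Chisq)`[2],
    logLik_rival = as.numeric(logLik(m0)), logLik_full = as.numeric(logLik(m1))
  )
}
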