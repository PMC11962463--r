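#' Between-person Spearman correlations of study-mean states
#'
#' Rank-correlates the person means (over the full study) of the motivation
#' sum-score, happiness, fatigue and sleep quality.
#'
#' @param cohort An [ema_cohort()].
#' @return A tibble with one row per variable pair: `rho`, `p.value`, `n`.
#' @export
between_person_spearman <- function(cohort) {
  means <- state_scores(cohort) |>
    filter(.data$valid) |>
    group_by(.data$participant_id) |>
    summarise(
      motivation = mean(.data$state_sum, na.rm = TRUE),
      happiness = mean(.data$happiness, na.rm = TRUE),
      fatigue = mean(.data$fatigue, na.rm = TRUE),
      sleep = mean(.data$sleep, na.rm = TRUE),
      .groups = "drop"
    )
  if (nrow(means) < 3) abort("between-person correlation needs >= 3 participants")
  vars <- c("motivation", "happiness", "fatigue", "sleep")
  pairs <- utils::combn(vars, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    x <- means[[pr[1]]]; y <- means[[pr[2]]]
    keep <- complete.cases(x, y)
    x <- x[keep]; y <- y[keep]
    if (length(unique(rank(x))) < 2 || length(unique(rank(y))) < 2) {
      abort(sprintf("undefined rank correlation for %s-%s (ties only)",
                    pr[1], pr[2]), class = "emamot_undefined_correlation")
    }
    ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
    tibble(var1 = pr[1], var2 = pr[2],
           rho = unname(ct$estimate), p.value = ct$p.value, n = length(x))
  })
}

coef_table <- function(fit, conf_level = 0.95) {
  sm <- summary(fit)$coefficients
  ci <- suppressMessages(confint(fit, level = conf_level))
  tibble(
    term = rownames(sm),
    estimate = sm[, 1],
    std.error = sm[, 2],
    conf.low = ci[rownames(sm), 1],
    conf.high = ci[rownames(sm), 2],
    p.value = sm[, ncol(sm)]
  )
}

#' Trait apathy as a predictor of mean or variability of state motivation
#'
#' Ordinary least squares of the person-level mean (or SD) of the *unscaled*
#' motivation sum-score on the trait-apathy factor score, with age and sex
#' as covariates.
#'
#' @param cohort An [ema_cohort()].
#' @param target `"mean"` (study-mean state) or `"sd"` (its SD).
#' @return A tibble of coefficients (`estimate`, 95% CI, `p.value`) with the
#'   model R-squared attached as attribute `r.squared` and column
#'   `r.squared` on the apathy row.
#' @export
trait_state_regression <- function(cohort, target = c("mean", "sd")) {
  target <- match.arg(target)
  person <- state_scores(cohort) |>
    filter(.data$valid, !is.na(.data$state_sum)) |>
    group_by(.data$participant_id) |>
    summarise(value = if (target == "mean") mean(.data$state_sum) else
      sd(.data$state_sum), n_occ = n(), .groups = "drop") |>
    filter(.data$n_occ >= 2) |>
    left_join(cohort$traits, by = "participant_id") |>
    filter(!is.na(.data$apathy))
  fit <- lm(value ~ apathy + age + sex, data = person)
  if (any(is.na(coef(fit)))) {
    abort("rank-deficient design in trait-state regression",
          class = "emamot_rank_deficiency")
  }
  out <- coef_table(fit)
  r2 <- summary(fit)$r.squared
  out$r.squared <- ifelse(out$term == "apathy", r2, NA_real_)
  attr(out, "r.squared") <- r2
  attr(out, "n") <- nrow(person)
  out
}

#' Weekday structure of state motivation
#'
#' One-way ANOVA of participant-by-weekday means of the within-person
#' normalized state, plus a paired t test comparing each participant's mean
#' over Monday-Wednesday against Thursday-Sunday (with Cohen's d on the
#' paired differences). The difference is reported as first-part minus
#' second-part, so a late-week uplift appears as a negative mean difference.
#'
#' @param cohort An [ema_cohort()].
#' @return A list of class `ema_weekday` with elements `anova` (tibble:
#'   `df1`, `df2`, `statistic`, `p.value`, `eta_sq`) and `paired` (tibble:
#'   `estimate` = mean difference, CI, `statistic`, `df`, `p.value`,
#'   `cohens_d`, `n_dropped`).
#' @export
weekday_analysis <- function(cohort) {
  # constant-state participants get z = 0 (centered constant), so a fully
  # flat cohort yields F = 0 rather than an empty design
  sc <- state_scores(cohort) |>
    filter(.data$complete) |>
    mutate(state_z = ifelse(!is.na(.data$state_z), .data$state_z,
                            ifelse(.data$person_sd == 0, 0, NA_real_))) |>
    filter(!is.na(.data$state_z))
  cell <- sc |>
    group_by(.data$participant_id, .data$weekday) |>
    summarise(z = mean(.data$state_z), .groups = "drop") |>
    mutate(weekday = factor(.data$weekday, levels = WEEKDAYS))
  if (nrow(cell) == 0 || !isTRUE(var(cell$z) >= 1e-14)) {
    an_tbl <- tibble(df1 = length(unique(cell$weekday)) - 1L,
                     df2 = nrow(cell) - length(unique(cell$weekday)),
                     statistic = 0, p.value = 1, eta_sq = 0)
  } else {
    av <- anova(lm(z ~ weekday, data = cell))
    an_tbl <- tibble(
      df1 = av["weekday", "Df"], df2 = av["Residuals", "Df"],
      statistic = av["weekday", "F value"], p.value = av["weekday", "Pr(>F)"],
      eta_sq = av["weekday", "Sum Sq"] / sum(av[["Sum Sq"]])
    )
  }
  split_means <- sc |>
    mutate(part = ifelse(.data$weekday %in% c("Mon", "Tue", "Wed"),
                         "first", "second")) |>
    group_by(.data$participant_id, .data$part) |>
    summarise(z = mean(.data$state_z), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "part", values_from = "z")
  n_dropped <- sum(!complete.cases(split_means))
  if (n_dropped > 0) {
    inform(sprintf(
      "%d participant(s) missing one week part entirely; dropped from paired test",
      n_dropped
    ))
  }
  split_means <- filter(split_means, complete.cases(split_means))
  diffs <- split_means$first - split_means$second
  if (length(diffs) < 2 || sd(diffs) == 0) {
    paired <- tibble(
      estimate = mean(diffs), conf.low = mean(diffs), conf.high = mean(diffs),
      statistic = 0, df = length(diffs) - 1L, p.value = 1,
      cohens_d = 0, n = length(diffs), n_dropped = n_dropped
    )
    return(structure(list(anova = an_tbl, paired = paired),
                     class = "ema_weekday"))
  }
  tt <- t.test(diffs)
  paired <- tibble(
    estimate = mean(diffs),
    conf.low = tt$conf.int[1], conf.high = tt$conf.int[2],
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p.value = tt$p.value,
    cohens_d = mean(diffs) / sd(diffs),
    n = length(diffs), n_dropped = n_dropped
  )
  structure(list(anova = an_tbl, paired = paired), class = "ema_weekday")
}

#' @export
print.ema_weekday <- function(x, ...) {
  cat("Weekday ANOVA on participant-weekday mean normalized state:\n")
  cat(sprintf("  F(%d, %d) = %.2f, p = %.3g, eta^2 = %.3f\n",
              x$anova$df1, x$anova$df2, x$anova$statistic,
              x$anova$p.value, x$anova$eta_sq))
  cat("Paired t, (Mon-Wed) - (Thu-Sun) person means:\n")
  cat(sprintf("  t(%d) = %.2f, p = %.3g, mean diff = %.3f [%.3f, %.3f], d = %.2f\n",
              x$paired$df, x$paired$statistic, x$paired$p.value,
              x$paired$estimate, x$paired$conf.low, x$paired$conf.high,
              x$paired$cohens_d))
  invisible(x)
}

#' Autocorrelation (inertia) of state motivation
#'
#' Two complementary views of how motivational state persists over
#' occasions:
#'
#' * `summary_acf`: fits the sample autocorrelation function per person on
#'   the person-centered state series (lags 1-4) and summarises the group
#'   mean and SEM per lag. Participants with constant series are dropped and
#'   counted.
#' * `within_day_model`: regresses the afternoon state on the same day's
#'   morning state, trait apathy and their interaction, with a
#'   person-specific morning-state slope shrunk toward the group slope
#'   (random slope, no intercept: person-centering already removes baseline
#'   level differences).
#'
#' @param cohort An [ema_cohort()].
#' @param mode `"summary_acf"` or `"within_day_model"`.
#' @param max_lag Maximum lag for `summary_acf`.
#' @return For `summary_acf`, a list of class `ema_acf` with `profiles`
#'   (participant x lag) and `summary` (lag, mean, sem, n). For
#'   `within_day_model`, a tibble of fixed effects with Wald CIs.
#' @export
state_autocorrelation <- function(cohort,
                                  mode = c("summary_acf", "within_day_model"),
                                  max_lag = 4) {
  mode <- match.arg(mode)
  sc <- state_scores(cohort) |> filter(.data$valid, !is.na(.data$state_z))
  if (mode == "summary_acf") {
    prof <- sc |>
      group_by(.data$participant_id) |>
      arrange(.data$occasion_index, .by_group = TRUE) |>
      group_modify(function(d, key) {
        if (nrow(d) < max_lag + 2 || sd(d$state_z) == 0) {
          return(tibble(lag = integer(), acf = numeric()))
        }
        a <- acf(d$state_z, lag.max = max_lag, plot = FALSE)
        tibble(lag = seq_len(max_lag), acf = as.numeric(a$acf)[-1])
      }) |>
      ungroup()
    if (!nrow(prof)) {
      abort("undefined ACF: no participant has a usable series",
            class = "emamot_undefined_acf")
    }
    summ <- prof |>
      group_by(.data$lag) |>
      summarise(mean = mean(.data$acf), sem = sd(.data$acf) / sqrt(n()),
                n = n(), .groups = "drop")
    structure(list(profiles = prof, summary = summ), class = "ema_acf")
  } else {
    pairs <- sc |>
      filter(.data$day_index > 0) |>
      select("participant_id", "day_index", "slot", "state_z") |>
      tidyr::pivot_wider(names_from = "slot", values_from = "state_z") |>
      filter(!is.na(.data$morning) & !is.na(.data$afternoon)) |>
      left_join(cohort$traits, by = "participant_id") |>
      filter(!is.na(.data$apathy))
    fit <- lmerTest::lmer(
      afternoon ~ 0 + morning + apathy + morning:apathy +
        (0 + morning | participant_id),
      data = pairs,
      control = lme4::lmerControl(check.conv.singular = "ignore")
    )
    sm <- summary(fit)$coefficients
    ci <- confint(fit, parm = "beta_", method = "Wald")
    out <- tibble(
      term = rownames(sm),
      estimate = sm[, "Estimate"],
      std.error = sm[, "Std. Error"],
      conf.low = ci[rownames(sm), 1],
      conf.high = ci[rownames(sm), 2],
      p.value = sm[, "Pr(>|t|)"]
    )
    attr(out, "n_pairs") <- nrow(pairs)
    out
  }
}

#' @export
print.ema_acf <- function(x, ...) {
  cat("State autocorrelation, group summary:\n")
  print(x$summary)
  invisible(x)
}
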