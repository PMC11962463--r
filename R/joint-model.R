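#' Endorsement probability of the one-parameter IRT state model
#'
#' The probability that a binarized motivation item is endorsed given the
#' latent motivational state `theta` and the item difficulty `delta`:
#' `plogis(theta - delta)`.
#'
#' @param theta Latent state (any real).
#' @param delta Item difficulty, must be `>= 0`.
#' @return Probability in (0, 1); vectorized.
#' @export
irt_endorsement_probability <- function(theta, delta) {
  if (any(delta < 0)) abort("item difficulty delta must be >= 0")
  plogis(theta - delta)
}

#' Binarize Likert motivation responses to endorsement indicators
#'
#' A 7-point response is an endorsement when it falls in any of the "true"
#' categories (slightly/mostly/totally true: codes 5-7); all other
#' categories, including the neutral midpoint, count as disagreement.
#' Reverse-scored items must already be reverse-scored (as done at ingest).
#' Missing responses propagate as `NA`.
#'
#' @param responses Integer vector (or matrix/data frame) of responses 1-7.
#' @return 0/1 indicators of the same shape.
#' @export
binarize_items <- function(responses) {
  if (is.data.frame(responses)) responses <- as.matrix(responses)
  out <- ifelse(is.na(responses), NA_integer_, as.integer(responses >= 5))
  out
}

#' Probability of choosing the harder option
#'
#' The linear effort-discounting choice rule: the harder option's subjective
#' value advantage is `v = rewSens * dr - effSens * de` (reward and effort
#' option differences, typically standardized by the design-grid SD), and
#' the choice follows a Bernoulli-logit: `P(harder) = plogis(v)`.
#'
#' @param rew_sens,eff_sens Reward and effort sensitivities.
#' @param dr,de Option differences in reward and effort (design units).
#' @return Probability of choosing the harder option; vectorized.
#' @export
trial_choice_probability <- function(rew_sens, eff_sens, dr, de) {
  plogis(rew_sens * dr - eff_sens * de)
}

#' Specification of the joint state-choice model
#'
#' Fixes the structural choices of the joint hierarchical model before
#' fitting: which state lags modulate reward sensitivity, whether the
#' latent state is within-person z-scored before entering the choice model,
#' whether design differences are standardized by the grid SD, and any
#' prior overrides for the modulation weights (used by the two-stage lag
#' comparison, where the lagged terms inherit the empirical prior of the
#' current-state effect).
#'
#' @param lag_mode `"current"` (reward sensitivity modulated by the
#'   occasion's state), `"past_and_future"` (the current term is replaced by
#'   the previous and next valid occasions' states), or `"past_two"`
#'   (previous and second-previous).
#' @param normalize_theta Within-person z-score theta before the choice
#'   model (default `TRUE`, decorrelating state from trait).
#' @param standardize_design Scale reward/effort differences by the design
#'   grid SD (default `TRUE`); they are never centered, since a zero
#'   difference must mean indifference.
#' @param beta_prior_mean,beta_prior_sd Optional named numeric vectors
#'   overriding the default normal(0, 1) priors on any modulation weight.
#' @return An object of class `ema_model_spec`.
#' @export
joint_model_spec <- function(lag_mode = c("current", "past_and_future", "past_two"),
                             normalize_theta = TRUE,
                             standardize_design = TRUE,
                             beta_prior_mean = NULL, beta_prior_sd = NULL) {
  lag_mode <- match.arg(lag_mode)
  structure(
    list(
      lag_mode = lag_mode,
      normalize_theta = normalize_theta,
      standardize_design = standardize_design,
      beta_prior_mean = beta_prior_mean,
      beta_prior_sd = beta_prior_sd
    ),
    class = "ema_model_spec"
  )
}

beta_names <- function(lag_mode) {
  switch(lag_mode,
    current = c("beta_trait_rew", "beta_trait_eff",
                "beta_state_rew", "beta_state_eff"),
    past_and_future = c("beta_trait_rew", "beta_trait_eff",
                        "beta_state_rew_past", "beta_state_rew_future",
                        "beta_state_eff"),
    past_two = c("beta_trait_rew", "beta_trait_eff",
                 "beta_state_rew_past", "beta_state_rew_past2",
                 "beta_state_eff")
  )
}

#' Assemble the model data block from a cohort
#'
#' Converts a cohort into the index structure consumed by the joint model:
#' binarized item observations at valid occasions, non-catch choice trials
#' with standardized design differences, per-participant-per-game cells
#' with their current / previous-valid / next-valid state occasions, and the
#' validity mask that implements the missing-data rule (a missing occasion's
#' state equals the group mean exactly and contributes no item terms).
#'
#' @param cohort An [ema_cohort()].
#' @param spec A [joint_model_spec()].
#' @return A list (class `ema_joint_data`) of index vectors and metadata.
#' @export
prepare_joint_data <- function(cohort, spec = joint_model_spec()) {
  ids <- cohort$traits$participant_id
  N <- length(ids)
  T_occ <- n_occasions(cohort)
  apathy <- cohort$traits$apathy
  if (any(is.na(apathy))) {
    warn("participants without trait apathy treated as trait 0; filter first")
    apathy[is.na(apathy)] <- 0
  }

  st <- cohort$states
  items <- as.matrix(st[, MOT_ITEMS])
  bin <- binarize_items(items)
  row_i <- match(st$participant_id, ids)
  row_t <- st$occasion_index + 1L

  valid <- matrix(0L, N, T_occ)
  has_item <- st$valid & rowSums(!is.na(bin)) > 0
  valid[cbind(row_i[has_item], row_t[has_item])] <- 1L

  keep <- which(has_item)
  item_i <- integer(0); item_t <- integer(0); item_m <- integer(0); item_y <- integer(0)
  for (m in seq_len(ncol(bin))) {
    ok <- keep[!is.na(bin[keep, m])]
    item_i <- c(item_i, row_i[ok] - 1L)
    item_t <- c(item_t, st$occasion_index[ok])
    item_m <- c(item_m, rep(m - 1L, length(ok)))
    item_y <- c(item_y, bin[ok, m])
  }

  off_idx <- matrix(-1L, N, T_occ)
  off_cells <- which(valid == 1L)
  off_idx[off_cells] <- seq_along(off_cells) - 1L

  tr <- filter(cohort$trials, !.data$is_catch)
  tr$dr <- tr$reward_hard - tr$reward_easy
  tr$de <- tr$effort_hard - tr$effort_easy
  if (nrow(tr) == 0) {
    tr$dr_z <- numeric(0); tr$de_z <- numeric(0)
    design_sd <- c(dr = 1, de = 1)
  } else if (spec$standardize_design) {
    std <- standardize_design(tr$dr, tr$de)
    tr$dr_z <- std$dr_z; tr$de_z <- std$de_z
    design_sd <- c(dr = std$sd_dr, de = std$sd_de)
  } else {
    tr$dr_z <- tr$dr; tr$de_z <- tr$de
    design_sd <- c(dr = 1, de = 1)
  }

  cells <- tr |>
    distinct(.data$participant_id, .data$game_index, .data$occasion_index) |>
    arrange(.data$participant_id, .data$game_index)
  ci <- match(cells$participant_id, ids) - 1L
  tc <- cells$occasion_index
  lag_occ <- function(i0, t0, dir, steps = 1) {
    v <- which(valid[i0 + 1L, ] == 1L) - 1L
    v <- if (dir < 0) rev(v[v < t0]) else v[v > t0]
    if (length(v) >= steps) v[steps] else -1L
  }
  tp <- mapply(lag_occ, ci, tc, MoreArgs = list(dir = -1, steps = 1))
  tf <- mapply(lag_occ, ci, tc, MoreArgs = list(dir = 1, steps = 1))
  tp2 <- mapply(lag_occ, ci, tc, MoreArgs = list(dir = -1, steps = 2))
  if (spec$lag_mode != "current") {
    n_nolag <- sum(tp < 0) + if (spec$lag_mode == "past_and_future")
      sum(tf < 0) else sum(tp2 < 0)
    if (n_nolag > 0) {
      inform(sprintf(
        "%d game cell(s) lack a lagged state occasion; their lag term is 0",
        n_nolag))
    }
  }
  cell_key <- paste(cells$participant_id, cells$game_index)
  ch_cell <- match(paste(tr$participant_id, tr$game_index), cell_key) - 1L

  nb <- length(beta_names(spec$lag_mode))
  pbm <- rep(0, nb); pbs <- rep(1, nb)
  names(pbm) <- names(pbs) <- beta_names(spec$lag_mode)
  if (!is.null(spec$beta_prior_mean)) {
    pbm[names(spec$beta_prior_mean)] <- spec$beta_prior_mean
  }
  if (!is.null(spec$beta_prior_sd)) {
    pbs[names(spec$beta_prior_sd)] <- spec$beta_prior_sd
  }

  structure(list(
    N = N, T = T_occ, M = ncol(bin), nb = nb,
    lag_mode = match(spec$lag_mode, c("current", "past_and_future", "past_two")) - 1L,
    n_off = length(off_cells), n_cell = nrow(cells),
    valid = valid, off_idx = off_idx,
    item_i = item_i, item_t = item_t, item_m = item_m, item_y = item_y,
    ap = as.numeric(apathy),
    cell_i = as.integer(ci), cell_tc = as.integer(tc),
    cell_tp = as.integer(tp), cell_tf = as.integer(tf),
    cell_tp2 = as.integer(tp2),
    ch_cell = as.integer(ch_cell), ch_y = as.integer(tr$chose_hard),
    ch_dr = as.numeric(tr$dr_z), ch_de = as.numeric(tr$de_z),
    prior_beta_mean = unname(pbm), prior_beta_sd = unname(pbs),
    prior_theta_mu_sd = 1, prior_mu_sd = 2,
    ids = ids, cells = cells, design_sd = design_sd,
    beta_names = beta_names(spec$lag_mode), spec = spec
  ), class = "ema_joint_data")
}

# dimension of the unconstrained parameter vector
joint_dim <- function(data) {
  data$T + data$n_off + 1L + data$M + data$nb + 2L + 2L + 2L * data$n_cell
}

# pack a constrained parameter list into the unconstrained vector
params_to_vector <- function(params, data) {
  off <- params$theta_offset  # N x T matrix on the natural scale
  idx <- which(data$off_idx >= 0)
  off_raw <- numeric(data$n_off)
  off_raw[data$off_idx[idx] + 1L] <- off[idx] / params$sigma_theta
  c(
    params$theta_mu,
    off_raw,
    log(params$sigma_theta),
    log(params$delta),
    params$beta[data$beta_names],
    params$mu_rew, params$mu_eff,
    log(params$sigma_rew), log(params$sigma_eff),
    (params$rew_offset - params$mu_rew) / params$sigma_rew,
    (params$eff_offset - params$mu_eff) / params$sigma_eff
  )
}

# unpack the unconstrained vector into a constrained parameter list
vector_to_params <- function(vec, data) {
  T_occ <- data$T
  i <- 0L
  take <- function(n) { out <- vec[(i + 1L):(i + n)]; i <<- i + n; out }
  theta_mu <- take(T_occ)
  off_raw <- take(data$n_off)
  sigma_theta <- exp(take(1L))
  delta <- exp(take(data$M))
  beta <- setNames(take(data$nb), data$beta_names)
  mu_rew <- take(1L); mu_eff <- take(1L)
  sigma_rew <- exp(take(1L)); sigma_eff <- exp(take(1L))
  rew_raw <- take(data$n_cell); eff_raw <- take(data$n_cell)
  off <- matrix(0, data$N, T_occ)
  idx <- which(data$off_idx >= 0)
  off[idx] <- sigma_theta * off_raw[data$off_idx[idx] + 1L]
  list(
    theta_mu = theta_mu, theta_offset = off, sigma_theta = sigma_theta,
    delta = delta, beta = beta, mu_rew = mu_rew, mu_eff = mu_eff,
    sigma_rew = sigma_rew, sigma_eff = sigma_eff,
    rew_offset = mu_rew + sigma_rew * rew_raw,
    eff_offset = mu_eff + sigma_eff * eff_raw
  )
}

# theta matrix and within-person z-score implied by a parameter list
theta_from_params <- function(params, data) {
  th <- sweep(params$theta_offset, 2, params$theta_mu, "+")
  z <- matrix(0, data$N, data$T)
  for (i in seq_len(data$N)) {
    v <- which(data$valid[i, ] == 1L)
    if (length(v) > 1) {
      s <- sd(th[i, v])
      if (s > 1e-10) z[i, ] <- (th[i, ] - mean(th[i, v])) / s
    }
  }
  list(theta = th, z = z)
}

# per-cell sensitivities implied by a parameter list (Eq. 4 identity)
sensitivities_from_params <- function(params, data) {
  tz <- theta_from_params(params, data)
  z <- if (data$spec$normalize_theta) tz$z else tz$theta
  zat <- function(tvec) ifelse(tvec >= 0, z[cbind(data$cell_i + 1L, tvec + 1L)], 0)
  zc <- zat(data$cell_tc)
  b <- params$beta
  br <- switch(data$spec$lag_mode,
    current = b[["beta_state_rew"]] * zc,
    past_and_future = b[["beta_state_rew_past"]] * zat(data$cell_tp) +
      b[["beta_state_rew_future"]] * zat(data$cell_tf),
    past_two = b[["beta_state_rew_past"]] * zat(data$cell_tp) +
      b[["beta_state_rew_past2"]] * zat(data$cell_tp2)
  )
  ap <- data$ap[data$cell_i + 1L]
  tibble(
    participant_id = data$cells$participant_id,
    game_index = data$cells$game_index,
    occasion_index = data$cells$occasion_index,
    rew_sens = b[["beta_trait_rew"]] * ap + params$rew_offset + br,
    eff_sens = b[["beta_trait_eff"]] * ap + params$eff_offset +
      b[["beta_state_eff"]] * zc,
    z_current = zc
  )
}

#' Joint log density of the state-choice model
#'
#' Evaluates the fully normalized joint log density: Bernoulli log-masses of
#' all binarized item endorsements under the IRT model, Bernoulli log-masses
#' of all non-catch choices under the state-modulated discounting model, and
#' all prior log densities, at a constrained parameter list.
#'
#' @param cohort An [ema_cohort()].
#' @param params A parameter list as produced by [draw_prior_params()] (or
#'   a fit's posterior draws): `theta_mu`, `theta_offset`, `sigma_theta`,
#'   `delta`, `beta`, `mu_rew`, `mu_eff`, `sigma_rew`, `sigma_eff`,
#'   `rew_offset`, `eff_offset`.
#' @param spec A [joint_model_spec()].
#' @param data Optional pre-built [prepare_joint_data()] block.
#' @return The log density (scalar). Non-finite parameter values yield
#'   `-Inf` with a warning naming the offending component.
#' @export
joint_log_density <- function(cohort, params, spec = joint_model_spec(),
                              data = NULL) {
  if (is.null(data)) data <- prepare_joint_data(cohort, spec)
  for (nm in names(params)) {
    if (any(!is.finite(params[[nm]]))) {
      warn(sprintf("non-finite value in parameter '%s'; density is -Inf", nm))
      return(-Inf)
    }
  }
  vec <- params_to_vector(params, data)
  emamot_lp_grad(vec, unclass(data), want_grad = FALSE, jacobian = FALSE)$lp
}

#' Draw a parameter set from the model priors
#'
#' Samples every model parameter from its prior distribution: standard
#' normal group-mean states, half-normal(0, 1) scales, truncated-normal(0,1)
#' item difficulties, normal(0, 1) modulation weights (or the spec's
#' overrides), normal(0, 2) population mean sensitivities, and hierarchical
#' per-cell offsets. Used as the ground-truth generator of the
#' parameter-recovery harness.
#'
#' @param data A [prepare_joint_data()] block.
#' @return A constrained parameter list.
#' @export
draw_prior_params <- function(data) {
  sigma_theta <- abs(rnorm(1))
  off <- matrix(0, data$N, data$T)
  idx <- which(data$off_idx >= 0)
  off[idx] <- rnorm(length(idx), 0, sigma_theta)
  sigma_rew <- abs(rnorm(1)); sigma_eff <- abs(rnorm(1))
  mu_rew <- rnorm(1, 0, data$prior_mu_sd); mu_eff <- rnorm(1, 0, data$prior_mu_sd)
  list(
    theta_mu = rnorm(data$T, 0, data$prior_theta_mu_sd),
    theta_offset = off, sigma_theta = sigma_theta,
    delta = abs(rnorm(data$M)),
    beta = setNames(rnorm(data$nb, data$prior_beta_mean, data$prior_beta_sd),
                    data$beta_names),
    mu_rew = mu_rew, mu_eff = mu_eff,
    sigma_rew = sigma_rew, sigma_eff = sigma_eff,
    rew_offset = rnorm(data$n_cell, mu_rew, sigma_rew),
    eff_offset = rnorm(data$n_cell, mu_eff, sigma_eff)
  )
}

#' Simulate a cohort from explicit model parameters
#'
#' Forward-samples item endorsements and choices from exactly the densities
#' that [joint_log_density()] scores: endorsements are Bernoulli with
#' probability [irt_endorsement_probability()], choices Bernoulli-logit in
#' the state-modulated discounting value. Endorsed items are emitted as
#' Likert response 5 and non-endorsed as 2, so that [binarize_items()]
#' recovers the simulated indicators exactly.
#'
#' @param params A constrained parameter list (see [draw_prior_params()]).
#' @param design A design from [recovery_design()] (a skeleton cohort plus
#'   data block).
#' @return An [ema_cohort()] with the generating `params` and implied
#'   sensitivities attached as attribute `ground_truth`.
#' @export
simulate_from_parameters <- function(params, design) {
  data <- design$data
  tz <- theta_from_params(params, data)
  sens <- sensitivities_from_params(params, data)
  cohort <- design$cohort

  st <- cohort$states
  ri <- match(st$participant_id, data$ids)
  rt <- st$occasion_index + 1L
  th <- tz$theta[cbind(ri, rt)]
  vv <- data$valid[cbind(ri, rt)] == 1L
  for (m in seq_len(data$M)) {
    p <- irt_endorsement_probability(th, params$delta[m])
    y <- rbinom(length(p), 1, p)
    st[[MOT_ITEMS[m]]] <- ifelse(vv, ifelse(y == 1L, 5L, 2L), NA_integer_)
  }
  cohort$states <- st

  if (!nrow(cohort$trials)) {
    warn("design has no game occasions; simulated cohort has no choices")
  } else {
    tr <- cohort$trials
    key <- paste(tr$participant_id, tr$game_index)
    ci <- match(key, paste(sens$participant_id, sens$game_index))
    dr <- (tr$reward_hard - tr$reward_easy) / data$design_sd[["dr"]]
    de <- (tr$effort_hard - tr$effort_easy) / data$design_sd[["de"]]
    p <- trial_choice_probability(sens$rew_sens[ci], sens$eff_sens[ci], dr, de)
    tr$chose_hard <- runif(nrow(tr)) < p
    cohort$trials <- tr
  }
  attr(cohort, "ground_truth") <- structure(
    list(params = params, theta = tz$theta, theta_z = tz$z,
         valid = data$valid == 1L, cells = sens, config = NULL,
         betas = params$beta, design_sd = data$design_sd),
    class = "ema_ground_truth"
  )
  cohort
}

#' Skeleton design for model-based simulation and recovery
#'
#' Builds a fully observed study skeleton (no missingness): every
#' participant responds at all occasions and plays every game, with a fresh
#' decorrelated trial grid. Trait apathy is drawn standard normal.
#'
#' @param n_participants,n_days Study size (29 occasions for 14 days).
#' @param n_trials,n_catch Trials per game (recovery designs default to no
#'   catch trials, which carry no model information).
#' @param spec A [joint_model_spec()].
#' @return A list with `cohort` (skeleton [ema_cohort()]) and `data` (its
#'   [prepare_joint_data()] block).
#' @export
recovery_design <- function(n_participants = 40, n_days = 14, n_trials = 24,
                            n_catch = 0, spec = joint_model_spec()) {
  sched <- build_schedule(n_days)
  T_occ <- nrow(sched)
  ids <- sprintf("S%03d", seq_len(n_participants))
  traits <- tibble(
    participant_id = ids, apathy = rnorm(n_participants),
    age = 30L, sex = "female", max_effort_baseline = 70
  )
  states <- tidyr::expand_grid(participant_id = ids, sched) |>
    mutate(m1 = 5L, m2 = 5L, m3 = 5L, m4 = 5L,
           happiness = 4L, fatigue = 4L,
           sleep = ifelse(.data$slot == "morning", 4L, NA_integer_),
           valid = TRUE)
  grid <- generate_trial_grid(n_trials, n_catch)
  n_games <- 1L + n_days %/% 2L
  game_days <- c(0L, seq(2L, by = 2L, length.out = n_games - 1L))
  game_occ <- c(0L, 2L * game_days[-1])  # afternoon games
  games <- tidyr::expand_grid(participant_id = ids,
                              game_index = seq_len(n_games) - 1L) |>
    mutate(occasion_index = game_occ[.data$game_index + 1L])
  trials <- tidyr::expand_grid(games, grid) |>
    mutate(chose_hard = TRUE, success = TRUE,
           mean_press_lag_ms = 250, n_presses = 40L) |>
    select(all_of(TRIAL_COLS))
  cohort <- ema_cohort(select(states, all_of(STATE_COLS)), trials, traits,
                       provenance = list(source = "design", n_occasions = T_occ))
  list(cohort = cohort, data = prepare_joint_data(cohort, spec))
}
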