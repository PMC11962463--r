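# independent oracles and model fixtures shared across test files

# independent least-squares oracle for the repeated-measures correlation:
# explicit design matrices and sums of squares, no shared code path
rmcorr_oracle <- function(x, y, id) {
  id <- factor(id)
  D <- model.matrix(~ id)
  full <- cbind(D, x)
  beta_full <- solve(crossprod(full), crossprod(full, y))
  ss_err <- sum((y - full %*% beta_full)^2)
  beta_red <- solve(crossprod(D), crossprod(D, y))
  ss_red <- sum((y - D %*% beta_red)^2)
  ss_x <- ss_red - ss_err
  sign(beta_full[length(beta_full)]) * sqrt(ss_x / (ss_x + ss_err))
}


# textbook mean-squares oracle via aov(), an independent route to the
# two-way absolute-agreement single-measure ICC
icc_oracle <- function(mat) {
  d <- data.frame(
    y = as.vector(mat),
    subject = factor(rep(seq_len(nrow(mat)), ncol(mat))),
    rater = factor(rep(seq_len(ncol(mat)), each = nrow(mat)))
  )
  tab <- anova(lm(y ~ subject + rater, d))
  msr <- tab["subject", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  n <- nrow(mat); k <- ncol(mat)
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}


# brute-force window enumeration, independent of hdi()'s implementation
hdi_oracle <- function(x, mass) {
  xs <- sort(x)
  n <- length(xs)
  gap <- ceiling(mass * n)
  best <- c(-Inf, Inf)
  for (i in seq_len(n - gap)) {
    if (xs[i + gap] - xs[i] < best[2] - best[1]) best <- c(xs[i], xs[i + gap])
  }
  best
}


# naive loop-based oracle for the joint log density: works directly off the
# cohort tables, recomputing binarization, z-scoring and standardization with
# elementary R, independent of the package's index structures
naive_joint_lp <- function(cohort, params, lag_mode = "current") {
  traits <- cohort$traits
  ids <- traits$participant_id
  T_occ <- n_occasions(cohort)
  lp <- 0
  lp <- lp + sum(dnorm(params$theta_mu, 0, 1, log = TRUE))
  lp <- lp + log(2) + dnorm(params$sigma_theta, 0, 1, log = TRUE)
  lp <- lp + log(2) + dnorm(params$sigma_rew, 0, 1, log = TRUE)
  lp <- lp + log(2) + dnorm(params$sigma_eff, 0, 1, log = TRUE)
  lp <- lp + sum(log(2) + dnorm(params$delta, 0, 1, log = TRUE))
  lp <- lp + sum(dnorm(params$beta, 0, 1, log = TRUE))
  lp <- lp + dnorm(params$mu_rew, 0, 2, log = TRUE) +
    dnorm(params$mu_eff, 0, 2, log = TRUE)
  lp <- lp + sum(dnorm(params$rew_offset, params$mu_rew, params$sigma_rew,
                       log = TRUE))
  lp <- lp + sum(dnorm(params$eff_offset, params$mu_eff, params$sigma_eff,
                       log = TRUE))

  st <- cohort$states
  items <- as.matrix(st[, c("m1", "m2", "m3", "m4")])
  valid <- matrix(FALSE, length(ids), T_occ)
  for (r in seq_len(nrow(st))) {
    i <- match(st$participant_id[r], ids)
    t <- st$occasion_index[r] + 1
    valid[i, t] <- isTRUE(st$valid[r]) && any(!is.na(items[r, ]))
  }
  theta <- matrix(rep(params$theta_mu, each = length(ids)), length(ids), T_occ)
  theta <- theta + params$theta_offset
  for (i in seq_along(ids)) {
    for (t in seq_len(T_occ)) {
      if (valid[i, t]) {
        lp <- lp + dnorm(params$theta_offset[i, t], 0, params$sigma_theta,
                         log = TRUE)
      }
    }
  }
  for (r in seq_len(nrow(st))) {
    i <- match(st$participant_id[r], ids)
    t <- st$occasion_index[r] + 1
    if (!valid[i, t]) next
    for (m in 1:4) {
      resp <- items[r, m]
      if (is.na(resp)) next
      y <- as.integer(resp >= 5)
      p <- plogis(theta[i, t] - params$delta[m])
      lp <- lp + y * log(p) + (1 - y) * log(1 - p)
    }
  }

  zfun <- function(i, t) {
    v <- which(valid[i, ])
    if (length(v) < 2) return(0)
    s <- sd(theta[i, v])
    if (s < 1e-10) return(0)
    (theta[i, t] - mean(theta[i, v])) / s
  }
  prev_v <- function(i, t) {
    v <- which(valid[i, ]); v <- v[v < t]
    if (length(v)) max(v) else NA
  }
  next_v <- function(i, t) {
    v <- which(valid[i, ]); v <- v[v > t]
    if (length(v)) min(v) else NA
  }

  tr <- cohort$trials[!cohort$trials$is_catch, ]
  sd_dr <- sd(tr$reward_hard - tr$reward_easy)
  sd_de <- sd(tr$effort_hard - tr$effort_easy)
  cells <- unique(tr[, c("participant_id", "game_index", "occasion_index")])
  cells <- cells[order(cells$participant_id, cells$game_index), ]
  for (c0 in seq_len(nrow(cells))) {
    i <- match(cells$participant_id[c0], ids)
    t <- cells$occasion_index[c0] + 1
    zc <- zfun(i, t)
    br <- if (lag_mode == "current") {
      params$beta[["beta_state_rew"]] * zc
    } else {
      tp <- prev_v(i, t); tf <- next_v(i, t)
      params$beta[["beta_state_rew_past"]] * (if (is.na(tp)) 0 else zfun(i, tp)) +
        params$beta[["beta_state_rew_future"]] * (if (is.na(tf)) 0 else zfun(i, tf))
    }
    rs <- params$beta[["beta_trait_rew"]] * traits$apathy[i] +
      params$rew_offset[c0] + br
    es <- params$beta[["beta_trait_eff"]] * traits$apathy[i] +
      params$eff_offset[c0] + params$beta[["beta_state_eff"]] * zc
    rows <- which(tr$participant_id == cells$participant_id[c0] &
                    tr$game_index == cells$game_index[c0])
    for (r in rows) {
      v <- rs * (tr$reward_hard[r] - tr$reward_easy[r]) / sd_dr -
        es * (tr$effort_hard[r] - tr$effort_easy[r]) / sd_de
      p <- plogis(v)
      lp <- lp + ifelse(tr$chose_hard[r], log(p), log(1 - p))
    }
  }
  lp
}

fixture_cohort <- function() {
  st <- tiny_states()
  tr <- tiny_trials()
  # add a second game for A at occasion 2 so lags are exercised
  extra <- tr[1:2, ]
  extra$game_index <- 1L
  extra$occasion_index <- 2L
  extra$chose_hard <- c(TRUE, TRUE)
  ema_cohort(st, rbind(tr, extra), tiny_traits())
}

fixture_params <- function(data, seed = 1) {
  set.seed(seed)
  draw_prior_params(data)
}

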