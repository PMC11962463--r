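#' MCMC settings for the joint model
#'
#' Defaults are 4 chains of 1,000 warmup and 1,000 sampling iterations of
#' adaptive Hamiltonian Monte Carlo (dual-averaging step size targeting an
#' acceptance rate of 0.8, diagonal metric estimated during warmup,
#' leapfrog path length jittered uniformly up to `l_max`). Shorter chains
#' are appropriate for simulation harnesses.
#'
#' @param chains,warmup,iter Chain count and lengths.
#' @param l_max Maximum leapfrog steps per proposal.
#' @param target_accept Dual-averaging acceptance target.
#' @param init_step Initial step size.
#' @return A list of class `ema_mcmc_settings`.
#' @export
mcmc_settings <- function(chains = 4, warmup = 1000, iter = 1000,
                          l_max = 24, target_accept = 0.8, init_step = 0.1) {
  structure(list(chains = chains, warmup = warmup, iter = iter, l_max = l_max,
                 target_accept = target_accept, init_step = init_step),
            class = "ema_mcmc_settings")
}

# split-chain potential scale reduction factor
split_rhat <- function(mat) {
  n <- nrow(mat)
  if (n < 4) return(NA_real_)
  half <- n %/% 2
  sub <- do.call(cbind, lapply(seq_len(ncol(mat)), function(c) {
    cbind(mat[seq_len(half), c], mat[(n - half + 1):n, c])
  }))
  m <- ncol(sub); nn <- nrow(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, var)
  w <- mean(vars)
  b <- nn * var(means)
  if (w < 1e-300) return(NA_real_)
  sqrt((nn - 1) / nn + b / (w * nn))
}

# effective sample size via Geyer's initial positive sequence, per chain
ess_basic <- function(mat) {
  n <- nrow(mat); m <- ncol(mat)
  if (n < 8) return(NA_real_)
  rho_sum <- 0
  ok <- TRUE
  max_lag <- min(n - 2, 200)
  ac <- vapply(seq_len(m), function(c) {
    a <- acf(mat[, c], lag.max = max_lag, plot = FALSE, demean = TRUE)
    as.numeric(a$acf)
  }, numeric(max_lag + 1))
  rho <- rowMeans(ac)
  tau <- 1
  k <- 2
  while (k + 1 <= length(rho)) {
    pair <- rho[k] + rho[k + 1]
    if (pair < 0) break
    tau <- tau + 2 * pair
    k <- k + 2
  }
  max(1, n * m / tau)
}

init_vector <- function(data, scale = 0.2) {
  dim <- joint_dim(data)
  v <- rnorm(dim, 0, scale)
  # start variance parameters near their prior medians
  o_lst <- data$T + data$n_off + 1L
  v[o_lst] <- log(0.7) + rnorm(1, 0, 0.1)
  o_lsre <- data$T + data$n_off + 1L + data$M + data$nb + 2L
  v[o_lsre + 1L] <- log(0.7) + rnorm(1, 0, 0.1)
  v[o_lsre + 2L] <- log(0.7) + rnorm(1, 0, 0.1)
  v
}

# posterior mean theta, z, and per-cell sensitivities from raw draws
derive_posterior_means <- function(draws, data) {
  D <- nrow(draws)
  T_occ <- data$T
  o_tm <- 0L
  o_off <- T_occ
  o_lst <- o_off + data$n_off
  o_del <- o_lst + 1L
  o_beta <- o_del + data$M
  o_mu <- o_beta + data$nb
  o_lsre <- o_mu + 2L
  o_rraw <- o_lsre + 2L
  o_eraw <- o_rraw + data$n_cell

  TM <- draws[, o_tm + seq_len(T_occ), drop = FALSE]
  sig_t <- exp(draws[, o_lst + 1L])
  sig_R <- exp(draws[, o_lsre + 1L]); sig_E <- exp(draws[, o_lsre + 2L])
  mu_R <- draws[, o_mu + 1L]; mu_E <- draws[, o_mu + 2L]
  B <- draws[, o_beta + seq_len(data$nb), drop = FALSE]
  colnames(B) <- data$beta_names

  theta_mean <- matrix(NA_real_, data$N, T_occ)
  z_need <- unique(c(data$cell_tc, data$cell_tp, data$cell_tf, data$cell_tp2))
  z_need <- z_need[z_need >= 0]
  Zc <- matrix(0, D, data$n_cell)  # z at current occasion per cell
  Zp <- matrix(0, D, data$n_cell); Zf <- matrix(0, D, data$n_cell)
  Z2 <- matrix(0, D, data$n_cell)
  for (i in seq_len(data$N)) {
    v <- which(data$valid[i, ] == 1L)
    if (length(v)) {
      K <- data$off_idx[i, v] + 1L
      THv <- TM[, v, drop = FALSE] +
        sig_t * draws[, o_off + K, drop = FALSE]
    } else THv <- NULL
    full <- TM
    if (length(v)) full[, v] <- THv
    theta_mean[i, ] <- colMeans(full)
    if (length(v) > 1) {
      m <- rowMeans(THv)
      s <- sqrt(rowSums((THv - m)^2) / (length(v) - 1))
      s[s < 1e-10] <- Inf
      cells_i <- which(data$cell_i + 1L == i)
      zat <- function(tv) {
        out <- numeric(D)
        if (tv >= 0) out <- (full[, tv + 1L] - m) / s
        out
      }
      for (c0 in cells_i) {
        Zc[, c0] <- zat(data$cell_tc[c0])
        Zp[, c0] <- zat(data$cell_tp[c0])
        Zf[, c0] <- zat(data$cell_tf[c0])
        Z2[, c0] <- zat(data$cell_tp2[c0])
      }
    }
  }
  RewOff <- mu_R + sig_R * draws[, o_rraw + seq_len(data$n_cell), drop = FALSE]
  EffOff <- mu_E + sig_E * draws[, o_eraw + seq_len(data$n_cell), drop = FALSE]
  ap <- data$ap[data$cell_i + 1L]
  lag_mode <- data$lag_mode
  BR <- if (lag_mode == 0) {
    B[, 3] * Zc
  } else if (lag_mode == 1) {
    B[, 3] * Zp + B[, 4] * Zf
  } else {
    B[, 3] * Zp + B[, 4] * Z2
  }
  b_sE <- if (lag_mode == 0) 4L else 5L
  Rew <- RewOff + BR + outer(B[, 1], ap)
  Eff <- EffOff + B[, b_sE] * Zc + outer(B[, 2], ap)
  cell_means <- data$cells |>
    mutate(
      rew_sens = colMeans(Rew), eff_sens = colMeans(Eff),
      rew_sens_sd = apply(Rew, 2, sd), eff_sens_sd = apply(Eff, 2, sd),
      z_current = colMeans(Zc)
    )
  deltas <- exp(draws[, o_del + seq_len(data$M), drop = FALSE])
  colnames(deltas) <- paste0("delta", seq_len(data$M))
  list(theta_mean = theta_mean, cell_means = cell_means,
       beta_draws = B,
       hyper_draws = cbind(sigma_theta = sig_t, mu_rew = mu_R, mu_eff = mu_E,
                           sigma_rew = sig_R, sigma_eff = sig_E, deltas))
}

#' Fit the joint state-choice model by Hamiltonian Monte Carlo
#'
#' Samples the posterior of the joint hierarchical model: group-mean latent
#' state per occasion plus person offsets (the missing-data rule holds
#' exactly: occasions without data have no offset), item difficulties,
#' trait/state modulation weights, and hierarchical per-participant-per-game
#' sensitivity offsets. Summaries report the posterior mean, SD, 90%
#' highest-density interval, probability of direction, split-Rhat and
#' effective sample size for every interpretable parameter, plus posterior
#' means of the latent state matrix and the per-cell sensitivities.
#'
#' The fit is flagged unconverged when any modulation weight has
#' `rhat > 1.01` or effective sample size `< 400`, or when divergent
#' transitions occurred.
#'
#' @param cohort An [ema_cohort()] (validity-filtered).
#' @param spec A [joint_model_spec()].
#' @param mcmc An [mcmc_settings()].
#' @param seed Optional seed.
#' @param data Optional pre-built data block (overrides `cohort`).
#' @return An object of class `ema_joint_fit`.
#' @export
fit_joint_model <- function(cohort, spec = joint_model_spec(),
                            mcmc = mcmc_settings(), seed = NULL, data = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(data)) data <- prepare_joint_data(cohort, spec)
  dlist <- unclass(data)
  chains <- vector("list", mcmc$chains)
  diags <- vector("list", mcmc$chains)
  for (c in seq_len(mcmc$chains)) {
    init <- init_vector(data)
    res <- emamot_hmc(dlist, init, mcmc$warmup, mcmc$iter,
                      mcmc$l_max, mcmc$target_accept, mcmc$init_step)
    chains[[c]] <- res$draws
    diags[[c]] <- tibble(chain = c, step_size = res$step_size,
                         accept_rate = res$accept_rate,
                         n_divergent = res$n_divergent)
  }
  diags <- bind_rows(diags)
  all_draws <- do.call(rbind, chains)
  pm <- derive_posterior_means(all_draws, data)

  named_draws <- cbind(pm$beta_draws, pm$hyper_draws)
  iter <- mcmc$iter
  summary <- purrr::map_dfr(colnames(named_draws), function(nm) {
    x <- named_draws[, nm]
    mat <- matrix(x, nrow = iter)
    h <- hdi(x, 0.90)
    tibble(
      term = nm, mean = mean(x), sd = sd(x),
      hdi_low = h[1], hdi_high = h[2],
      p_direction = probability_of_direction(x),
      rhat = split_rhat(mat), ess = ess_basic(mat)
    )
  })
  beta_sum <- filter(summary, .data$term %in% data$beta_names)
  converged <- all(beta_sum$rhat <= 1.01, na.rm = TRUE) &&
    all(beta_sum$ess >= 400, na.rm = TRUE) && sum(diags$n_divergent) == 0
  structure(
    list(
      summary = summary, beta_draws = pm$beta_draws,
      hyper_draws = pm$hyper_draws,
      theta_mean = `dimnames<-`(pm$theta_mean, list(data$ids, NULL)),
      cell_means = pm$cell_means,
      diagnostics = diags, converged = converged,
      data = data, spec = spec, mcmc = mcmc, n_draws = nrow(all_draws)
    ),
    class = "ema_joint_fit"
  )
}

#' @export
print.ema_joint_fit <- function(x, ...) {
  cat(sprintf("<ema_joint_fit> %d draws (%d chains), lag mode '%s'%s\n",
              x$n_draws, x$mcmc$chains, x$spec$lag_mode,
              if (x$converged) "" else " [convergence flagged]"))
  print(filter(x$summary, .data$term %in% x$data$beta_names), n = Inf)
  invisible(x)
}

#' @rdname fit_joint_model
#' @param x An `ema_joint_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.ema_joint_fit <- function(x, ...) {
  x$summary
}

#' @rdname fit_joint_model
#' @exportS3Method generics::glance
glance.ema_joint_fit <- function(x, ...) {
  tibble(
    n_draws = x$n_draws, chains = x$mcmc$chains,
    max_rhat = max(x$summary$rhat, na.rm = TRUE),
    min_ess = min(x$summary$ess, na.rm = TRUE),
    n_divergent = sum(x$diagnostics$n_divergent),
    accept_rate = mean(x$diagnostics$accept_rate),
    converged = x$converged
  )
}
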