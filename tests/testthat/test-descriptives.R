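test_that("rmcorr is 1 for a perfect common slope with person intercepts", {
  d <- data.frame(id = rep(c("a", "b"), each = 3),
                  x = c(1, 2, 3, 4, 5, 6))
  d$y <- d$x + rep(c(0, 10), each = 3)
  res <- repeated_measures_correlation(d, x, y, id)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_equal(res$df, 6 - 2 - 1)
})

test_that("rmcorr matches an independent least-squares decomposition", {
  set.seed(42)
  for (rep in 1:5) {
    d <- data.frame(id = rep(letters[1:3], each = 4),
                    x = rnorm(12))
    d$y <- 0.6 * d$x + rep(rnorm(3, sd = 2), each = 4) + rnorm(12, sd = 0.7)
    res <- repeated_measures_correlation(d, x, y, id)
    expect_equal(res$r, rmcorr_oracle(d$x, d$y, d$id), tolerance = 1e-8)
  }
})

test_that("rmcorr is invariant to person-specific constants and ~0 under the null", {
  set.seed(7)
  d <- data.frame(id = rep(letters[1:20], each = 30), x = rnorm(600))
  d$y <- 0.4 * d$x + rnorm(600)
  r0 <- repeated_measures_correlation(d, x, y, id)$r
  d2 <- d
  shift <- rnorm(20, sd = 50)
  d2$x <- d2$x + shift[match(d2$id, letters[1:20])]
  d2$y <- d2$y + rev(shift)[match(d2$id, letters[1:20])]
  expect_equal(repeated_measures_correlation(d2, x, y, id)$r, r0,
               tolerance = 1e-10)
  d$y2 <- rnorm(600) + shift[match(d$id, letters[1:20])]
  expect_lt(abs(repeated_measures_correlation(d, x, y2, id)$r), 0.1)
})

test_that("rmcorr rejects degenerate input", {
  d <- data.frame(id = rep(c("a", "b"), each = 3), x = rep(1, 6), y = rnorm(6))
  expect_error(repeated_measures_correlation(d, x, y, id),
               class = "emamot_undefined_correlation")
})

test_that("between-person Spearman matches direct rank computation", {
  co <- small_cohort()
  sp <- between_person_spearman(co)
  sc <- state_scores(co)
  sc <- sc[sc$valid, ]
  means <- aggregate(cbind(state_sum, happiness) ~ participant_id, sc, mean)
  rho_direct <- cor(rank(means$state_sum), rank(means$happiness))
  got <- sp$rho[sp$var1 == "motivation" & sp$var2 == "happiness"]
  expect_equal(got, rho_direct, tolerance = 1e-10)
  # monotone transform of person means gives rho = 1
  d5 <- data.frame(x = c(3, 1, 4, 2, 5))
  expect_equal(cor(rank(d5$x), rank(exp(d5$x))), 1)
  expect_true(all(abs(sp$rho) <= 1))
})

test_that("trait regression recovers an injected loading and perfect fits", {
  co <- small_cohort()
  tm <- trait_state_regression(co, "mean")
  # generator loading is negative; estimate must be too, with R^2 ~ half
  ap <- tm[tm$term == "apathy", ]
  expect_lt(ap$estimate, 0)
  expect_gt(attr(tm, "r.squared"), 0.2)
  expect_true(ap$conf.low < ap$estimate & ap$estimate < ap$conf.high)
  ts <- trait_state_regression(co, "sd")
  expect_true(is.finite(ts$estimate[ts$term == "apathy"]))
})

test_that("weekday ANOVA is zero for constant state and detects the uplift", {
  const <- scored_cohort(matrix(16L, nrow = 6, ncol = 29))
  wk <- weekday_analysis(const)
  expect_equal(wk$anova$statistic, 0)
  # generated cohorts carry a Thursday-Sunday uplift: first-part minus
  # second-part person means are negative on average
  wk2 <- weekday_analysis(small_cohort())
  expect_lt(wk2$paired$estimate, 0)
  expect_equal(wk2$anova$df1, 6)
})

test_that("summary ACF recovers the decay of a crafted AR series", {
  set.seed(3)
  n <- 40; T_occ <- 101; phi <- 0.6
  x <- matrix(0, n, T_occ)
  x[, 1] <- rnorm(n)
  for (t in 2:T_occ) x[, t] <- phi * x[, t - 1] + rnorm(n, 0, sqrt(1 - phi^2))
  # map to integer scores preserving order and approximate spacing
  score <- matrix(pmin(28L, pmax(4L, as.integer(round(16 + 4 * x)))), n, T_occ)
  co <- scored_cohort(score)
  ac <- state_autocorrelation(co, "summary_acf")
  # finite-series ACF is biased low; check ordering and rough level
  expect_equal(ac$summary$mean[1], phi, tolerance = 0.08)
  expect_true(all(diff(ac$summary$mean) < 0))
  # alternating series has negative lag-1
  alt <- scored_cohort(matrix(rep(c(10L, 22L), length.out = 29 * 6),
                              6, 29, byrow = TRUE))

  ac_alt <- state_autocorrelation(alt, "summary_acf")
  expect_lt(ac_alt$summary$mean[1], 0)
})

test_that("white-noise state has near-zero group ACF at all lags", {
  set.seed(8)
  score <- matrix(sample(10:22, 50 * 29, replace = TRUE), 50, 29)
  ac <- state_autocorrelation(scored_cohort(score), "summary_acf")
  expect_true(all(abs(ac$summary$mean) < 3 * ac$summary$sem + 0.06))
})

test_that("within-day model recovers inertia and its trait moderation", {
  co <- apply_validity_filter(generate_cohort(
    generator_config(n_participants = 250,
                     state = list(ar1_trait = -0.2)), seed = 99))
  wd <- state_autocorrelation(co, "within_day_model")
  expect_gt(wd$estimate[wd$term == "morning"], 0.15)
  expect_lt(wd$estimate[wd$term == "morning:apathy"], 0)
})
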