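test_that("IPW arithmetic matches hand calculations", {
  expect_equal(ipw_ate(c(1, 0), c(2, 1), c(0.5, 0.5)), 1, ignore_attr = TRUE)
  expect_equal(ipw_ate(c(1, 0), c(2, 1), c(0.5, 0.5), stabilized = FALSE), 1,
               ignore_attr = TRUE)
  # with constant propensity the stabilized form is the difference of
  # arm-wise means; the unstabilized form agrees when the constant equals
  # the treated fraction
  set.seed(2)
  T <- rbinom(40, 1, 0.5); T[1] <- 1; T[2] <- 0
  Y <- rnorm(40)
  diff_means <- mean(Y[T == 1]) - mean(Y[T == 0])
  expect_equal(ipw_ate(T, Y, rep(0.3, 40), warn = FALSE), diff_means,
               ignore_attr = TRUE)
  expect_equal(ipw_ate(T, Y, rep(mean(T), 40), stabilized = FALSE),
               diff_means, ignore_attr = TRUE)
})

test_that("degenerate and extreme propensities are reported", {
  expect_error(ipw_ate(c(1, 0), c(1, 2), c(1, 0.5)), "index 1")
  expect_error(ipw_ate(c(1, 0), c(1, 2), c(0.5, 0)), "index 2")
  expect_warning(ipw_ate(c(1, 0, 1), c(1, 2, 3), c(0.005, 0.5, 0.6)),
                 "positivity")
  est <- suppressWarnings(ipw_ate(c(1, 0, 1), c(1, 2, 3), c(0.005, 0.5, 0.6)))
  expect_equal(attr(est, "n_extreme"), 1)
})

test_that("a randomized design recovers the true effect", {
  # treatment assigned by a fair coin independent of covariates: weighting
  # with the known propensity 1/2 must recover the unit treatment effect
  d <- simulation_design(n = 10000, px = 2, pz = 2, sigma_e2 = 0,
                         gamma0 = 0, gamma_x = c(0, 0), gamma_z = c(0, 0),
                         beta_x = c(0.6, 0.6), beta_z = c(0.6, 0))
  ds <- generate_dataset(d, seed = 101)
  s <- ds$sample
  est <- ipw_ate(s$T, s$Y, rep(0.5, s$n), warn = FALSE)
  # Monte Carlo S.E. via the influence function of the stabilized estimator
  mu1 <- mean(s$Y[s$T == 1]); mu0 <- mean(s$Y[s$T == 0])
  infl <- s$T * (s$Y - mu1) / 0.5 - (1 - s$T) * (s$Y - mu0) / 0.5
  se <- sd(infl) / sqrt(s$n)
  expect_lt(abs(est - 1), 3 * se)
})

test_that("weighting by the true propensity identifies both arm means", {
  # confounded design with known pi: E(TY/pi) = E{Y(1)} and the analogue
  # for the control arm, so the weighted contrast recovers the true ATE
  d <- mild_design(n = 20000, sigma_e2 = 0)
  ds <- generate_dataset(d, seed = 202)
  s <- ds$sample; pi <- ds$truth$pi
  m1 <- mean(s$T * s$Y / pi)
  m0 <- mean((1 - s$T) * s$Y / (1 - pi))
  # E{Y(1)} = 1 and E{Y(0)} = 0 because the covariates are centered
  se1 <- sd(s$T * s$Y / pi) / sqrt(s$n)
  se0 <- sd((1 - s$T) * s$Y / (1 - pi)) / sqrt(s$n)
  expect_lt(abs(m1 - 1), 3 * se1)
  expect_lt(abs(m0 - 0), 3 * se0)
  est <- ipw_ate(s$T, s$Y, pi, warn = FALSE)
  expect_lt(abs(est - 1), 3 * (se1 + se0))
})

test_that("zero measurement error collapses the pipeline to the naive analysis", {
  d <- mild_design(n = 300)
  ds <- generate_dataset(d, seed = 33)
  naive <- simexsel_fit(ds$sample, correct = FALSE)
  z <- simexsel_fit(ds$sample, sigma_e = 0, K = 4, psi = short_psi, seed = 9)
  expect_equal(z$tau_hat, naive$tau_hat, tolerance = 1e-8)
  expect_equal(z$gamma_hat, naive$gamma_hat, tolerance = 1e-8)
})

test_that("the tau trajectory extrapolates consistently with its curve", {
  d <- mild_design(n = 250)
  ds <- generate_dataset(d, seed = 44)
  f <- simexsel_fit(ds$sample, sigma_e = 0.5, K = 8, psi = short_psi, seed = 10)
  refit <- fit_extrapolant(f$ate$psi, f$ate$tau_psi, "quadratic")
  expect_equal(f$tau_hat, refit$value_at_minus_one)
  expect_true(is.finite(f$tau_hat))
})

test_that("forced inclusion augments the selected model coherently", {
  d <- mild_design(n = 300, sigma_e2 = 0.4)
  ds <- generate_dataset(d, seed = 55)
  f <- simexsel_fit(ds$sample, sigma_e = 0.4, K = 8, psi = short_psi, seed = 12)
  # forcing an already-selected covariate changes nothing
  already <- f$active[1]
  same <- forced_inclusion_ate(ds$sample, f, already)
  expect_equal(same$tau_hat, f$tau_hat)
  # forcing excluded covariates grows the active set by exactly their number
  excluded <- setdiff(names(f$gamma_hat)[-1], f$active)
  forced <- forced_inclusion_ate(ds$sample, f, excluded[1:2])
  gf <- attr(forced, "gamma_forced")
  expect_equal(sum(abs(gf[-1]) > 1e-10), length(f$active) + 2)
  # re-entering coefficients come from the unpenalized corrected pilot
  expect_equal(gf[[excluded[1]]], f$gamma_tilde[[excluded[1]]])
  expect_error(forced_inclusion_ate(ds$sample, f, "bogus"), "unknown")
})

test_that("forcing a truly null covariate barely moves the estimate", {
  d <- mild_design(n = 400, sigma_e2 = 0.3)
  taus <- matrix(NA, 6, 2)
  for (r in 1:6) {
    ds <- generate_dataset(d, seed = 600 + r)
    f <- simexsel_fit(ds$sample, sigma_e = 0.3, K = 8, psi = short_psi,
                      seed = 700 + r)
    excluded <- setdiff(ds$sample$x_names[3:4], f$active)  # truly null Xs
    taus[r, 1] <- f$tau_hat
    taus[r, 2] <- if (length(excluded))
      forced_inclusion_ate(ds$sample, f, excluded[1])$tau_hat else f$tau_hat
  }
  # replicate-averaged difference is within Monte Carlo noise of zero
  dif <- taus[, 2] - taus[, 1]
  expect_lt(abs(mean(dif)), max(3 * sd(dif) / sqrt(nrow(taus)), 0.02))
})

test_that("bootstrap uncertainty behaves sanely", {
  d <- mild_design(n = 150, sigma_e2 = 0.4)
  ds <- generate_dataset(d, seed = 66)
  # degenerate outcome: the effect is exactly zero in every resample
  s0 <- observed_sample(ds$sample$T, rep(2, ds$sample$n), ds$sample$Xstar,
                        ds$sample$Z)
  f0 <- simexsel_fit(s0, sigma_e = 0.4, K = 3, psi = c(0, 1, 2), seed = 1)
  bs0 <- bootstrap_se(s0, f0, B = 50, seed = 2)
  expect_lt(bs0$se, 1e-10)
  expect_error(bootstrap_se(s0, f0, B = 10), "at least 50")
  # bootstrap size: 60 vs 200 replicates agree within Monte Carlo tolerance
  f <- simexsel_fit(ds$sample, sigma_e = 0.4, K = 3, psi = c(0, 1, 2), seed = 3)
  b1 <- bootstrap_se(ds$sample, f, B = 60, seed = 4)
  b2 <- bootstrap_se(ds$sample, f, B = 200, seed = 5)
  # sd of a bootstrap sd is roughly se / sqrt(2 (B - 1))
  tol <- 3 * b2$se * (1 / sqrt(2 * 59) + 1 / sqrt(2 * 199))
  expect_lt(abs(b1$se - b2$se), tol)
  expect_true(b1$ci[1] < f$tau_hat && f$tau_hat < b1$ci[2])
})

test_that("bootstrap S.E. tracks the sampling spread of the estimator", {
  d <- mild_design(n = 300, sigma_e2 = 0.4)
  taus <- numeric(40)
  for (r in 1:40) {
    ds <- generate_dataset(d, seed = 900 + r)
    taus[r] <- simexsel_fit(ds$sample, sigma_e = 0.4, K = 3, psi = c(0, 1, 2),
                            seed = 950 + r)$tau_hat
  }
  emp_se <- sd(taus)
  boot_se <- vapply(1:3, function(i) {
    ds <- generate_dataset(d, seed = 900 + i)
    f <- simexsel_fit(ds$sample, sigma_e = 0.4, K = 3, psi = c(0, 1, 2),
                      seed = 950 + i)
    bootstrap_se(ds$sample, f, B = 60, seed = 77 + i)$se
  }, numeric(1))
  expect_lt(mean(boot_se), 1.5 * emp_se)
  expect_gt(mean(boot_se), emp_se / 1.5)
})

test_that("an intercept-only selection proceeds with constant propensity", {
  # pure-noise pilots: selection empties the model, and the effect estimate
  # falls back to the (weighted) difference of arm means
  set.seed(88)
  n <- 200
  X <- matrix(rnorm(2 * n), n)
  T <- rbinom(n, 1, 0.5); T[1] <- 1; T[2] <- 0
  Y <- T + rnorm(n)
  s <- observed_sample(T, Y, X[, 1, drop = FALSE], X[, 2, drop = FALSE])
  expect_message(
    f <- simexsel_fit(s, sigma_e = 0.2, K = 4, psi = c(0, 1, 2), seed = 5),
    "intercept-only")
  expect_length(f$active, 0)
  expect_true(is.finite(f$tau_hat))
})
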