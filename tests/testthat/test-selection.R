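test_that("penalty derivative weights follow their closed forms", {
  expect_equal(penalty_weight(0, 0.5, "scad"), 0.5)        # u <= lambda branch
  expect_equal(penalty_weight(10, 0.5, "scad"), 0)         # u >= a * lambda
  expect_equal(penalty_weight(2, 1, "scad"), (3.7 - 2) / 2.7)
  expect_equal(penalty_weight(c(0, 1, 99), 0.3, "lasso"), rep(0.3, 3))
  # continuity across the SCAD knots
  u <- c(0.5 - 1e-9, 0.5 + 1e-9, 1.85 - 1e-9, 1.85 + 1e-9)
  w <- penalty_weight(u, 0.5, "scad")
  expect_equal(w[1], w[2], tolerance = 1e-6)
  expect_equal(w[3], w[4], tolerance = 1e-6)
  expect_error(penalty_weight(-1, 0.5), "non-negative")
  expect_error(penalty_weight(1, 0.5, "scad", a = 2), "exceed 2")
})

test_that("identity-weight minimization is the exact soft threshold", {
  gt <- c(0.5, 1.0, -0.2, 0.05)
  # lasso with threshold 0.1: intercept untouched, others shrunk toward 0
  g <- minimize_penalized_loss(gt, lambda = 0.1, n = 400, penalty = "lasso")
  expect_equal(unname(g), c(0.5, 0.9, -0.1, 0))
  # independent oracle: componentwise minimization over a fine grid
  brute <- vapply(2:4, function(j) {
    cand <- seq(-2, 2, by = 1e-4)
    cand[which.min(0.5 * (cand - gt[j])^2 + 0.1 * abs(cand))]
  }, numeric(1))
  expect_equal(unname(g[-1]), brute, tolerance = 1e-4)
  # vanishing penalty returns the pilot; overwhelming penalty zeroes all
  expect_equal(minimize_penalized_loss(gt, 1e-12, 400, "lasso"), gt,
               ignore_attr = TRUE)
  g0 <- minimize_penalized_loss(gt, 10, 400, "lasso")
  expect_equal(unname(g0), c(0.5, 0, 0, 0))
})

test_that("coordinate descent agrees with the closed form at identity weights", {
  set.seed(4)
  for (i in 1:20) {
    q <- sample(3:8, 1)
    gt <- rnorm(q)
    lam <- runif(1, 0.01, 1)
    pen <- sample(c("lasso", "scad"), 1)
    closed <- minimize_penalized_loss(gt, lam, 400, pen)
    cd <- minimize_penalized_loss(gt, lam, 400, pen, Vn = diag(q))
    expect_equal(cd, closed, tolerance = 1e-8)
  }
})

test_that("general-weight coordinate descent satisfies the KKT conditions", {
  set.seed(5)
  q <- 6
  A <- matrix(rnorm(q * q), q)
  Vn <- crossprod(A) / q + diag(q)  # well-conditioned positive definite
  gt <- rnorm(q)
  lam <- 0.3
  g <- minimize_penalized_loss(gt, lam, 400, "scad", Vn = Vn)
  w <- c(0, penalty_weight(abs(gt[-1]), lam, "scad"))
  r <- drop(Vn %*% (g - gt))
  for (j in seq_len(q)) {
    if (abs(g[j]) > 1e-10) {
      expect_lt(abs(r[j] + w[j] * sign(g[j])), 1e-6)
    } else {
      expect_lte(abs(r[j]), w[j] + 1e-8)
    }
  }
  expect_error(minimize_penalized_loss(gt, lam, 400, Vn = -diag(q)),
               "positive definite")
})

test_that("BIC scores count model size and lack of fit correctly", {
  gt <- c(0.5, 1.0, -0.2)
  n <- 400
  expect_equal(bic_score(gt, gt, n), 2 * log(n) * 3)  # perfect fit, 3 df
  shrunk <- c(0.5, 0, 0)
  expect_equal(bic_score(shrunk, gt, n), n * (1^2 + 0.2^2) + 2 * log(n) * 1)
  # removing a zero component can only reduce the df term
  expect_lt(bic_score(c(0.5, 1.0, 0), gt, n) - n * 0.2^2,
            bic_score(gt, gt, n))
})

test_that("BIC-tuned selection separates signal from noise pilots", {
  gt <- c(0.5, 1, -1, 0.01, -0.02)
  names(gt) <- c("(Intercept)", "X1", "X2", "Z1", "Z2")
  sel <- select_coefficients(gt, n = 400, penalty = "scad")
  expect_equal(unname(which(sel$active)), c(1, 2, 3))
  expect_equal(sel$gamma_hat[["Z1"]], 0)
  # the shrinkage path is monotone in df and the chosen lambda minimizes BIC
  expect_equal(sel$path$bic[sel$path$lambda == sel$lambda_star],
               min(sel$path$bic))
  # a grid of one tiny lambda keeps the full model
  sel_tiny <- select_coefficients(gt, n = 400, lambda = 1e-8)
  expect_equal(sum(sel_tiny$active), 5)
  expect_error(select_coefficients(gt, 400, lambda = numeric(0)), "empty")
})

test_that("selection is equivariant under component permutation", {
  gt <- c(0.2, 0.9, -0.03, 0.6, 0.01)
  names(gt) <- c("(Intercept)", paste0("V", 1:4))
  perm <- c(3, 1, 4, 2)
  gt2 <- c(gt[1], gt[-1][perm])
  s1 <- select_coefficients(gt, 400, penalty = "scad")
  s2 <- select_coefficients(gt2, 400, penalty = "scad")
  expect_equal(unname(s2$gamma_hat[-1]), unname(s1$gamma_hat[-1][perm]))
})

test_that("ties in BIC resolve to the sparser model", {
  # two pilots exactly at the threshold boundary produce equal-BIC candidates;
  # with an all-zero noise pilot the empty and near-empty models tie and the
  # larger lambda (empty) must win
  gt <- c(1, 0.4, 0)
  names(gt) <- c("(Intercept)", "A", "B")
  sel <- select_coefficients(gt, n = 50, penalty = "lasso",
                             lambda = c(0.5, 0.6))  # both zero everything
  expect_equal(sum(sel$active), 1)
  expect_equal(sel$lambda_star, 0.6)
})

test_that("forced covariates bypass the penalty", {
  gt <- c(0.5, 1, 0.05, -0.03)
  names(gt) <- c("(Intercept)", "X1", "X2", "Z1")
  sel <- select_coefficients(gt, 400, penalty = "scad", force_in = "X2")
  expect_true(sel$active[3])
  expect_equal(sel$gamma_hat[["X2"]], 0.05)   # unpenalized, so unshrunk
  expect_equal(sel$gamma_hat[["Z1"]], 0)
  expect_error(select_coefficients(gt, 400, force_in = "nope"), "unknown")
})

test_that("SCAD selection has the oracle behaviour on root-n pilots", {
  # pilots = truth + noise at the accuracy a root-n-consistent estimator
  # delivers at n = 400; zeros must be excluded essentially always and
  # signals never
  set.seed(77)
  truth <- c(1, 1, -1, 1, 0, 0, 0, 0)
  n <- 400
  excl <- fn <- numeric(200)
  shrink_signal <- numeric(200)
  for (r in 1:200) {
    gt <- truth + rnorm(8, sd = 0.05)
    sel <- select_coefficients(gt, n, penalty = "scad")
    zeros <- which(truth[-1] == 0)
    excl[r] <- mean(sel$gamma_hat[-1][zeros] == 0)
    fn[r] <- gamma_metrics(sel$gamma_hat, truth)[["n_false_negative"]]
    shrink_signal[r] <- max(abs(sel$gamma_hat[2:4] - gt[2:4]))
  }
  expect_gte(mean(excl == 1), 0.9)   # all true zeros excluded in >= 90% of runs
  expect_equal(mean(fn), 0)
  # SCAD leaves strong signals unpenalized (near-unbiasedness)
  expect_lt(median(shrink_signal), 1e-10)
})

test_that("selection never inflates the variance of active components", {
  # the one-step SCAD estimate of an active component equals the pilot when
  # the pilot is strong, so its spread cannot exceed the pilot's
  set.seed(78)
  truth <- c(0.5, 1, 0, 0)
  pilots <- hats <- matrix(NA, 100, 4)
  for (r in 1:100) {
    gt <- truth + rnorm(4, sd = 0.06)
    pilots[r, ] <- gt
    hats[r, ] <- select_coefficients(gt, 400, penalty = "scad")$gamma_hat
  }
  expect_lte(var(hats[, 2]), var(pilots[, 2]) + 1e-12)
  expect_lte(var(hats[, 3]), var(pilots[, 3]) + 1e-12)
})

test_that("the path export carries lambda, df, BIC and estimates", {
  gt <- c(0.5, 1, -0.2, 0.05)
  names(gt) <- c("(Intercept)", "a", "b", "c")
  sel <- select_coefficients(gt, 400, n_lambda = 10)
  tab <- selection_path_table(sel)
  expect_equal(nrow(tab), 10)
  expect_true(all(c("lambda", "df", "bic", "a") %in% names(tab)))
  expect_true(all(diff(tab$df) >= 0))  # lambda sorted decreasing -> df grows
})
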