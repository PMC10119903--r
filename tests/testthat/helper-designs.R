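# Shared fixtures: designs are built in code, at sizes chosen so that each
# test isolates one property (moderate signals give good overlap; the
# full-scale study design is exercised in the acceptance suite).

# small design with moderate coefficients and good propensity overlap
mild_design <- function(n = 400, sigma_e2 = 0.5, outcome = "model1_linear",
                        link = "logistic") {
  simulation_design(n = n, px = 4, pz = 4, outcome = outcome, link = link,
                    sigma_e2 = sigma_e2,
                    gamma0 = 0.3,
                    gamma_x = c(0.8, -0.8, 0, 0), gamma_z = c(0.8, -0.8, 0, 0),
                    beta_x = c(0.6, 0.6, 0, 0), beta_z = c(0.6, 0.6, 0, 0))
}

# design with aligned confounding (treatment and outcome coefficients share
# sign), so attenuation of the propensity coefficients translates into a
# visible bias of the uncorrected ATE estimate
confounded_design <- function(n = 400, sigma_e2 = 0.75) {
  simulation_design(n = n, px = 4, pz = 4, sigma_e2 = sigma_e2,
                    gamma0 = 0.2,
                    gamma_x = c(0.7, 0.7, 0, 0), gamma_z = c(0.7, 0.7, 0, 0),
                    beta_x = c(0.7, 0.7, 0, 0), beta_z = c(0.7, 0.7, 0, 0))
}

# quick SIMEX settings for unit tests
short_psi <- seq(0, 2, by = 0.5)

# random small observed sample (no structure; for interface-level tests)
random_sample <- function(n = 60, px = 2, pz = 2, seed = 42) {
  simexsel:::with_seed(seed, {
    X <- matrix(rnorm(n * px), n)
    Z <- matrix(rnorm(n * pz), n)
    T <- rbinom(n, 1, plogis(0.2 + 0.5 * X[, 1] - 0.5 * Z[, 1]))
    # guard: both arms present
    if (!any(T == 1)) T[1] <- 1
    if (!any(T == 0)) T[2] <- 0
    Y <- T + X[, 1] + rnorm(n)
    observed_sample(T, Y, X, Z)
  })
}

# numerical gradient of the Bernoulli log-likelihood (independent oracle for
# the score function)
numeric_score <- function(gamma, sample, link, h = 1e-6) {
  D <- cbind(1, sample$Xstar, sample$Z)
  ll <- function(g) {
    p <- link_prob(drop(D %*% g), link)
    sum(sample$T * log(p) + (1 - sample$T) * log(1 - p))
  }
  vapply(seq_along(gamma), function(j) {
    e <- numeric(length(gamma)); e[j] <- h
    (ll(gamma + e) - ll(gamma - e)) / (2 * h)
  }, numeric(1))
}
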