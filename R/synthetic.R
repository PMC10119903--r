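#' Define a synthetic simulation design
#'
#' Describes the multivariate-normal confounder design used throughout the
#' simulation studies: `px` error-prone and `pz` error-free covariates with
#' unit-variance AR(rho) within-block correlation and cross-covariances
#' `sigma_xz_base^(2 + |j - k|)`; a treatment model with intercept
#' `gamma0 = 1` and coefficient blocks
#' \eqn{\gamma_x = \gamma_z = (1_{d/2}^\top, -1_{d/2}^\top, 0^\top)^\top}
#' (`d = ceiling(p/2)` important covariates per block); outcomes from either
#' a linear model \eqn{Y = T + \beta_x^\top X + \beta_z^\top Z + \epsilon},
#' \eqn{\epsilon \sim N(0,1)} (true ATE exactly 1) or a logistic model
#' \eqn{\mathrm{logit}\, P(Y = 1 | T, X, Z) = T + \beta_x^\top X +
#' \beta_z^\top Z} with \eqn{\beta_x = (1_{d_x}^\top, 0^\top)^\top},
#' \eqn{\beta_z = (1_{d_z}^\top, 0^\top)^\top}; and classical additive
#' surrogate error \eqn{X^* = X + e}, \eqn{e \sim N(0, \sigma_e^2 I)}.
#'
#' All parameters are overridable; the defaults are the study design
#' (n = 400, px = pz = 15, sigma_e2 in {0.15, 0.5, 0.75}).
#'
#' @param n sample size.
#' @param px,pz numbers of error-prone and error-free covariates.
#' @param outcome `"model1_linear"` or `"model2_logistic"`.
#' @param link treatment-model link.
#' @param sigma_e2 common measurement-error variance on the diagonal of
#'   \eqn{\Sigma_e}.
#' @param gamma0,gamma_x,gamma_z treatment-model truth; defaults as above.
#' @param beta_x,beta_z outcome-model truth; defaults as above.
#' @param sigma_x2,sigma_z2,rho_x,rho_z,sigma_xz_base covariance parameters.
#' @return An object of class `simulation_design`.
#' @export
simulation_design <- function(n = 400, px = 15, pz = 15,
                              outcome = c("model1_linear", "model2_logistic"),
                              link = c("logistic", "probit", "cloglog"),
                              sigma_e2 = 0.15,
                              gamma0 = 1, gamma_x = NULL, gamma_z = NULL,
                              beta_x = NULL, beta_z = NULL,
                              sigma_x2 = 1, sigma_z2 = 1,
                              rho_x = 0.5, rho_z = 0.5, sigma_xz_base = 0.4) {
  outcome <- match.arg(outcome)
  link <- match.arg(link)
  dx <- ceiling(px / 2); dz <- ceiling(pz / 2)
  default_gamma <- function(p, d)
    c(rep(1, floor(d / 2)), rep(-1, ceiling(d / 2)), rep(0, p - d))
  default_beta <- function(p, d) c(rep(1, d), rep(0, p - d))
  gamma_x <- gamma_x %||% default_gamma(px, dx)
  gamma_z <- gamma_z %||% default_gamma(pz, dz)
  beta_x <- beta_x %||% default_beta(px, dx)
  beta_z <- beta_z %||% default_beta(pz, dz)
  stopifnot(length(gamma_x) == px, length(gamma_z) == pz,
            length(beta_x) == px, length(beta_z) == pz,
            sigma_e2 >= 0, n >= 2, px >= 1)
  structure(list(n = n, px = px, pz = pz, dx = dx, dz = dz,
                 outcome = outcome, link = link, sigma_e2 = sigma_e2,
                 gamma0 = gamma0, gamma_x = gamma_x, gamma_z = gamma_z,
                 beta_x = beta_x, beta_z = beta_z,
                 sigma_x2 = sigma_x2, sigma_z2 = sigma_z2,
                 rho_x = rho_x, rho_z = rho_z,
                 sigma_xz_base = sigma_xz_base),
            class = "simulation_design")
}

#' @export
print.simulation_design <- function(x, ...) {
  cat("Simulation design: n =", x$n, ", px =", x$px, ", pz =", x$pz,
      ",", x$outcome, "outcome,", x$link, "treatment link, sigma_e2 =",
      x$sigma_e2, "\n")
  invisible(x)
}

#' Covariate covariance matrix of a design
#'
#' Assembles \eqn{\Sigma_w} for the joint covariate vector (X, Z):
#' within-block entries \eqn{\sigma_x^2 \rho_x^{|j-k|}} and
#' \eqn{\sigma_z^2 \rho_z^{|j-k|}}, cross-block entries
#' `sigma_xz_base^(2 + |j - k|)` (the base raised to the power
#' `2 + |j - k|`; at the defaults the largest cross-covariance is
#' \eqn{0.4^2 = 0.16}). Positive definiteness is asserted.
#'
#' @param design a [simulation_design()].
#' @return A `(px + pz) x (px + pz)` positive definite matrix.
#' @export
build_sigma_w <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  ar <- function(p, s2, rho) s2 * outer(seq_len(p), seq_len(p),
                                        function(j, k) rho^abs(j - k))
  Sxx <- ar(design$px, design$sigma_x2, design$rho_x)
  Szz <- ar(design$pz, design$sigma_z2, design$rho_z)
  Sxz <- outer(seq_len(design$px), seq_len(design$pz),
               function(j, k) design$sigma_xz_base^(2 + abs(j - k)))
  Sw <- rbind(cbind(Sxx, Sxz), cbind(t(Sxz), Szz))
  ev <- eigen(Sw, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("design covariance matrix is not positive definite")
  Sw
}

#' Generate a synthetic observed sample
#'
#' Draws covariates \eqn{(X, Z) \sim N(0, \Sigma_w)}, the treatment from the
#' design's link and truth \eqn{\gamma}, the outcome from the chosen outcome
#' model, and surrogates \eqn{X^* = X + e} with
#' \eqn{e \sim N(0, \sigma_e^2 I)}.
#'
#' @param design a [simulation_design()].
#' @param seed optional integer seed; fixing it fixes all outputs bit-exactly
#'   without disturbing the caller's RNG stream.
#' @return List with `sample` (an [observed_sample()] built on the
#'   surrogates), `X` (the true error-prone covariates), and `truth`
#'   (list: `gamma`, `beta`, `pi` the true propensities, `design`).
#' @export
generate_dataset <- function(design, seed = NULL) {
  stopifnot(inherits(design, "simulation_design"))
  Sw <- build_sigma_w(design)
  gen <- function() {
    W <- rmvnorm_sqrt(design$n, Sw)
    X <- W[, seq_len(design$px), drop = FALSE]
    Z <- W[, design$px + seq_len(design$pz), drop = FALSE]
    eta_t <- design$gamma0 + drop(X %*% design$gamma_x + Z %*% design$gamma_z)
    pi <- link_prob(eta_t, design$link)
    T <- stats::rbinom(design$n, 1, pi)
    eta_y <- T + drop(X %*% design$beta_x + Z %*% design$beta_z)
    Y <- switch(design$outcome,
                model1_linear = eta_y + stats::rnorm(design$n),
                model2_logistic = stats::rbinom(design$n, 1, stats::plogis(eta_y)))
    Xstar <- X + matrix(stats::rnorm(design$n * design$px,
                                     sd = sqrt(design$sigma_e2)),
                        design$n, design$px)
    list(X = X, Z = Z, T = T, Y = Y, Xstar = Xstar, pi = pi)
  }
  d <- if (is.null(seed)) gen() else with_seed(seed, gen())
  sample <- observed_sample(d$T, d$Y, d$Xstar, d$Z)
  gamma <- c("(Intercept)" = design$gamma0,
             stats::setNames(design$gamma_x, sample$x_names),
             stats::setNames(design$gamma_z, sample$z_names))
  list(sample = sample, X = d$X,
       truth = list(gamma = gamma,
                    beta = c(design$beta_x, design$beta_z),
                    pi = d$pi, design = design))
}

#' True average treatment effect of a design
#'
#' Under the linear outcome model the ATE is exactly 1 (the coefficient of T;
#' all covariate terms cancel in expectation). Under the logistic outcome
#' model the ATE
#' \eqn{\tau_0 = E\{\mathrm{expit}(1 + \beta^\top W)\} -
#' E\{\mathrm{expit}(\beta^\top W)\}} has no closed form and is approximated
#' by Monte Carlo over `n_mc` covariate draws.
#'
#' @param design a [simulation_design()].
#' @param n_mc number of Monte Carlo draws for the logistic outcome model
#'   (at least 1000).
#' @param seed optional seed for the Monte Carlo draws.
#' @return The scalar true ATE.
#' @export
true_tau <- function(design, n_mc = 5000, seed = NULL) {
  stopifnot(inherits(design, "simulation_design"))
  if (design$outcome == "model1_linear") return(1)
  if (n_mc < 1000) stop("n_mc must be at least 1000 for the logistic outcome model")
  Sw <- build_sigma_w(design)
  b <- c(design$beta_x, design$beta_z)
  mc <- function() {
    eta <- drop(rmvnorm_sqrt(n_mc, Sw) %*% b)
    mean(stats::plogis(1 + eta) - stats::plogis(eta))
  }
  if (is.null(seed)) mc() else with_seed(seed, mc())
}

#' Write a synthetic dataset to CSV with a truth sidecar
#'
#' Writes columns `T`, `Y`, `X1..Xpx` (true covariates), `Xs1..Xspx`
#' (surrogates) and `Z1..Zpz`; the truth record is written alongside as JSON
#' when the jsonlite package is available.
#'
#' @param dataset a [generate_dataset()] result.
#' @param path output CSV path; the sidecar is written to `<path>.truth.json`.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(dataset, path) {
  s <- dataset$sample
  d <- data.frame(T = s$T, Y = s$Y)
  if (s$px) {
    Xt <- dataset$X; colnames(Xt) <- paste0("X", seq_len(s$px))
    Xs <- s$Xstar; colnames(Xs) <- paste0("Xs", seq_len(s$px))
    d <- cbind(d, Xt, Xs)
  }
  if (s$pz) {
    Zm <- s$Z; colnames(Zm) <- paste0("Z", seq_len(s$pz))
    d <- cbind(d, Zm)
  }
  utils::write.csv(d, path, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    tr <- dataset$truth
    jsonlite::write_json(list(gamma = unname(tr$gamma), beta = tr$beta,
                              design = unclass(tr$design)),
                         paste0(path, ".truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
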