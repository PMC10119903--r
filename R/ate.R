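#' Inverse-probability-weighted average treatment effect
#'
#' Computes the IPW estimate of the average treatment effect from fitted
#' propensity scores. The stabilized form (default) normalizes each arm by
#' its summed inverse weights,
#' \deqn{\hat\tau = \frac{\sum_i T_i Y_i/\hat\pi_i}{\sum_i T_i/\hat\pi_i}
#'  - \frac{\sum_i (1-T_i) Y_i/(1-\hat\pi_i)}{\sum_i (1-T_i)/(1-\hat\pi_i)},}
#' which is consistent and numerically stable under extreme weights; the
#' unstabilized form divides both weighted sums by n instead.
#'
#' @param treatment 0/1 treatment vector.
#' @param outcome numeric outcome vector.
#' @param pi_hat fitted propensity scores, strictly inside (0, 1).
#' @param stabilized use the ratio-of-weighted-sums form (default `TRUE`).
#' @param warn warn when propensities fall outside (0.01, 0.99), a practical
#'   positivity diagnostic.
#' @return The scalar ATE estimate, with attribute `"n_extreme"` counting
#'   propensities outside (0.01, 0.99).
#' @examples
#' ipw_ate(c(1, 0), c(2, 1), c(0.5, 0.5))  # 1
#' @export
ipw_ate <- function(treatment, outcome, pi_hat, stabilized = TRUE, warn = TRUE) {
  T <- as.numeric(treatment); Y <- as.numeric(outcome); p <- as.numeric(pi_hat)
  if (length(T) != length(Y) || length(T) != length(p))
    stop("treatment, outcome and pi_hat must have equal length")
  bad <- which(p <= 0 | p >= 1)
  if (length(bad))
    stop("propensity score at subject index ", bad[1],
         " is not strictly inside (0, 1)")
  n_extreme <- sum(p < 0.01 | p > 0.99)
  if (warn && n_extreme > 0)
    warning(n_extreme, " propensity score(s) outside (0.01, 0.99); ",
            "positivity may be practically violated")
  if (stabilized) {
    est <- sum(T * Y / p) / sum(T / p) -
      sum((1 - T) * Y / (1 - p)) / sum((1 - T) / (1 - p))
  } else {
    n <- length(T)
    est <- sum(T * Y / p) / n - sum((1 - T) * Y / (1 - p)) / n
  }
  attr(est, "n_extreme") <- n_extreme
  est
}

# propensities from a coefficient vector laid out as (intercept, X, Z)
#' @noRd
propensity <- function(gamma, sample, link, X = NULL) {
  link_prob(drop(design_matrix(sample, X) %*% gamma), link)
}

#' SIMEX correction of the ATE under a selected treatment model
#'
#' The treatment-effect analogue of the coefficient-level SIMEX: with the
#' selected coefficients held fixed (no refit), the fitted propensities are
#' recomputed on every pseudo-contaminated surrogate set
#' \eqn{X^*(k,\psi)} (the same draws used for the coefficient trajectory),
#' the stabilized IPW estimate \eqn{\hat\tau(k,\psi)} is averaged over k, and
#' the curve \eqn{\{(\psi, \hat\tau(\psi))\}} is extrapolated to
#' \eqn{\psi = -1}.
#'
#' @param sample an [observed_sample()].
#' @param selection a [select_coefficients()] result (or any object with a
#'   `gamma_hat` component); inactive coefficients are exactly zero, so the
#'   propensities depend only on the selected covariates.
#' @param grid the [simex_grid()] used for the coefficient step.
#' @param link treatment-model link.
#' @param family extrapolant family, see [fit_extrapolant()].
#' @param errors the pseudo-error array from the coefficient step; recomputed
#'   from the grid seed when omitted (identical draws by construction).
#' @param stabilized use the stabilized IPW form.
#' @return An object of class `ate_result`: list with `tau_hat`, `tau_psi`
#'   (per-level K-averages), `fit` (the extrapolant), `family`, `se`, `ci`,
#'   `p_value` (filled by [bootstrap_se()]), and `flags`.
#' @export
simex_ate <- function(sample, selection, grid, link = "logistic",
                      family = "quadratic", errors = NULL, stabilized = TRUE) {
  stopifnot(inherits(sample, "observed_sample"), inherits(grid, "simex_grid"))
  gamma_hat <- if (is.list(selection)) selection$gamma_hat else selection
  if (length(gamma_hat) != 1 + sample$p) stop("coefficient vector has the wrong length")
  intercept_only <- all(abs(gamma_hat[-1]) < 1e-10)
  if (intercept_only)
    message("selected model is intercept-only; proceeding with a constant propensity")
  errors <- errors %||% pseudo_errors(grid, sample$n)
  M <- length(grid$psi)
  tau_psi <- numeric(M)
  n_extreme <- 0L
  for (m in seq_len(M)) {
    ps <- grid$psi[m]
    s <- if (grid$scaling == "sqrt") sqrt(ps) else ps
    if (ps == 0 || all(grid$sigma_e == 0)) {
      est <- ipw_ate(sample$T, sample$Y, propensity(gamma_hat, sample, link),
                     stabilized, warn = FALSE)
      tau_psi[m] <- est
      n_extreme <- max(n_extreme, attr(est, "n_extreme"))
      next
    }
    tk <- numeric(grid$K)
    for (k in seq_len(grid$K)) {
      Xk <- sample$Xstar + s * errors[, , k]
      est <- ipw_ate(sample$T, sample$Y, propensity(gamma_hat, sample, link, Xk),
                     stabilized, warn = FALSE)
      tk[k] <- est
      n_extreme <- max(n_extreme, attr(est, "n_extreme"))
    }
    tau_psi[m] <- mean(tk)
  }
  fit <- fit_extrapolant(grid$psi, tau_psi, family)
  structure(list(tau_hat = fit$value_at_minus_one, tau_psi = tau_psi,
                 psi = grid$psi, fit = fit, family = fit$family,
                 se = NULL, ci = NULL, p_value = NULL,
                 flags = list(n_extreme_pi = n_extreme,
                              intercept_only = intercept_only)),
            class = "ate_result")
}

#' @export
print.ate_result <- function(x, ...) {
  cat("ATE estimate: tau_hat =", signif(x$tau_hat, 5), "\n")
  if (!is.null(x$se))
    cat("  bootstrap S.E. =", signif(x$se, 4),
        " 95% CI = [", signif(x$ci[1], 4), ",", signif(x$ci[2], 4),
        "]  p =", format.pval(x$p_value, digits = 3), "\n")
  if (x$flags$n_extreme_pi > 0)
    cat("  note:", x$flags$n_extreme_pi,
        "propensity score(s) outside (0.01, 0.99)\n")
  invisible(x)
}

#' Full five-step estimator of the average treatment effect
#'
#' Runs the complete pipeline on an observed sample:
#' 1. generate shared pseudo-errors for the SIMEX grid;
#' 2. refit the full treatment model on each pseudo-contaminated surrogate
#'    set and average over replicates;
#' 3. extrapolate each coefficient trajectory to \eqn{\psi = -1}, giving the
#'    measurement-error-corrected pilot \eqn{\tilde\gamma};
#' 4. select active confounders by BIC-tuned weighted-L1 shrinkage around
#'    \eqn{\tilde\gamma};
#' 5. recompute stabilized IPW estimates on the pseudo-contaminated
#'    surrogates under the selected model and extrapolate the effect curve to
#'    \eqn{\psi = -1}.
#'
#' `correct = FALSE` skips the SIMEX machinery entirely (the "naive" analysis
#' that treats the surrogates as true covariates); `select = FALSE` skips the
#' selection step (the "full model" analysis). Setting `boot > 0` adds a
#' nonparametric bootstrap standard error, normal CI, and p-value.
#'
#' @param sample an [observed_sample()].
#' @param sigma_e measurement-error covariance (matrix, or scalar variance
#'   applied to all error-prone covariates); ignored when `grid` is given.
#' @param link treatment-model link.
#' @param psi,K,seed,scaling SIMEX grid settings, see [simex_grid()].
#' @param grid optional prebuilt [simex_grid()].
#' @param extrapolation extrapolant family for steps 3 and 5.
#' @param penalty,a,Vn,n_lambda,force_in selection settings, see
#'   [select_coefficients()].
#' @param select run the selection step (default `TRUE`).
#' @param correct run the SIMEX correction (default `TRUE`).
#' @param refit refit the unpenalized model on the selected covariates before
#'   step 5 (default `FALSE`: the shrunken coefficients are used as is).
#' @param stabilized use the stabilized IPW form.
#' @param boot number of bootstrap replicates (0 = skip).
#' @param boot_seed seed for the bootstrap resampling.
#' @return An object of class `simexsel_fit`: list with `gamma_tilde` (pilot),
#'   `selection` (`NULL` when `select = FALSE`), `gamma_hat`, `active`
#'   covariate names, `trajectory` (`NULL` when `correct = FALSE`), `ate` (an
#'   `ate_result`), `tau_hat`, plus the configuration (`link`, `penalty`,
#'   `family`, `grid`, flags).
#' @export
simexsel_fit <- function(sample, sigma_e = NULL, link = "logistic",
                         psi = seq(0, 2, by = 0.25), K = 500, seed = NULL,
                         scaling = "sqrt", grid = NULL,
                         extrapolation = "quadratic",
                         penalty = "scad", a = 3.7, Vn = NULL, n_lambda = 50,
                         force_in = NULL, select = TRUE, correct = TRUE,
                         refit = FALSE, stabilized = TRUE,
                         boot = 0, boot_seed = NULL) {
  stopifnot(inherits(sample, "observed_sample"))
  if (correct) {
    if (is.null(grid)) {
      if (is.null(sigma_e)) stop("sigma_e (or a prebuilt grid) is required when correct = TRUE")
      if (is.null(dim(sigma_e)) && length(sigma_e) == 1)
        sigma_e <- diag(as.numeric(sigma_e), sample$px)
      grid <- simex_grid(sigma_e, psi = psi, K = K, seed = seed, scaling = scaling)
    }
    errors <- pseudo_errors(grid, sample$n)
    traj <- run_simex(sample, grid, link, errors = errors)
    gamma_tilde <- extrapolate_trajectory(traj, extrapolation)
    traj$errors <- NULL  # keep the returned object light; draws are seed-reproducible
  } else {
    errors <- NULL
    traj <- NULL
    gamma_tilde <- fit_treatment_model(sample, link)$coefficients
  }
  gt <- gamma_tilde
  attr(gt, "fits") <- NULL
  selection <- if (select)
    select_coefficients(gt, sample$n, penalty = penalty, a = a, Vn = Vn,
                        n_lambda = n_lambda, force_in = force_in)
  else NULL
  gamma_hat <- if (select) selection$gamma_hat else gt
  if (select && refit) {
    act <- selection$active
    sub <- refit_active(sample, link, act)
    gamma_hat[] <- 0
    gamma_hat[act] <- sub
  }
  if (correct) {
    ate <- simex_ate(sample, list(gamma_hat = gamma_hat), grid, link,
                     family = extrapolation, errors = errors,
                     stabilized = stabilized)
  } else {
    est <- ipw_ate(sample$T, sample$Y, propensity(gamma_hat, sample, link),
                   stabilized, warn = FALSE)
    ate <- structure(list(tau_hat = as.numeric(est), tau_psi = NULL, psi = NULL,
                          fit = NULL, family = NA_character_,
                          se = NULL, ci = NULL, p_value = NULL,
                          flags = list(n_extreme_pi = attr(est, "n_extreme"),
                                       intercept_only = all(abs(gamma_hat[-1]) < 1e-10))),
                     class = "ate_result")
  }
  out <- structure(list(gamma_tilde = gt, selection = selection,
                        gamma_hat = gamma_hat,
                        active = names(gamma_hat)[-1][abs(gamma_hat[-1]) > 1e-10],
                        trajectory = traj, ate = ate, tau_hat = ate$tau_hat,
                        link = link, penalty = if (select) penalty else NA_character_,
                        family = extrapolation, grid = grid,
                        select = select, correct = correct,
                        stabilized = stabilized, refit = refit),
                   class = "simexsel_fit")
  if (boot > 0) {
    bs <- bootstrap_se(sample, fit = out, B = boot, seed = boot_seed)
    out$ate$se <- bs$se; out$ate$ci <- bs$ci; out$ate$p_value <- bs$p_value
    out$boot <- bs
  }
  out
}

# unpenalized refit restricted to the active columns
#' @noRd
refit_active <- function(sample, link, active) {
  xa <- active[2:(1 + sample$px)]
  za <- if (sample$pz) active[(2 + sample$px):(1 + sample$p)] else logical()
  sub <- observed_sample(sample$T, sample$Y,
                         sample$Xstar[, xa, drop = FALSE],
                         sample$Z[, za, drop = FALSE])
  fit_treatment_model(sub, link)$coefficients
}

#' @export
print.simexsel_fit <- function(x, ...) {
  cat("SIMEX",
      if (x$select) paste0("+ ", x$penalty, " selection") else "(full model)",
      if (!x$correct) "[no measurement-error correction]", "\n")
  cat("Active covariates (", length(x$active), "): ",
      paste(x$active, collapse = ", "), "\n", sep = "")
  print(x$ate)
  invisible(x)
}

#' Nonparametric bootstrap uncertainty for the pipeline estimate
#'
#' Resamples subjects with replacement and re-runs the full pipeline on each
#' resample with fresh pseudo-error draws, giving a standard error (the
#' standard deviation of the bootstrap estimates), a normal-approximation 95%
#' confidence interval centered at the point estimate, and a two-sided
#' p-value for the null of no treatment effect.
#'
#' @param sample the original [observed_sample()].
#' @param fit a [simexsel_fit()] result whose configuration is replayed on
#'   each resample.
#' @param B number of bootstrap replicates (at least 50).
#' @param seed seed for resampling and the per-replicate pseudo-error draws.
#' @return List with `se`, `ci` (length 2), `p_value`, `taus` (the bootstrap
#'   estimates), and `n_failed`.
#' @export
bootstrap_se <- function(sample, fit, B = 200, seed = NULL) {
  stopifnot(inherits(sample, "observed_sample"), inherits(fit, "simexsel_fit"))
  if (B < 50) stop("B must be at least 50")
  seed <- seed %||% sample.int(.Machine$integer.max - 1L, 1L)
  taus <- with_seed(seed, {
    rep_seeds <- sample.int(.Machine$integer.max - 2L, B)
    vapply(seq_len(B), function(b) {
      idx <- sample.int(sample$n, sample$n, replace = TRUE)
      bs <- observed_sample(sample$T[idx], sample$Y[idx],
                            sample$Xstar[idx, , drop = FALSE],
                            sample$Z[idx, , drop = FALSE],
                            sample$x_names, sample$z_names)
      # both arms must survive the resample
      if (!any(bs$T == 1) || !any(bs$T == 0)) return(NA_real_)
      tryCatch(
        suppressMessages(simexsel_fit(
          bs,
          sigma_e = if (fit$correct) fit$grid$sigma_e else NULL,
          link = fit$link,
          psi = if (fit$correct) fit$grid$psi else seq(0, 2, 0.25),
          K = if (fit$correct) fit$grid$K else 1,
          seed = rep_seeds[b],
          scaling = if (fit$correct) fit$grid$scaling else "sqrt",
          extrapolation = fit$family,
          penalty = if (fit$select) fit$penalty else "scad",
          select = fit$select, correct = fit$correct,
          refit = fit$refit, stabilized = fit$stabilized))$tau_hat,
        error = function(e) NA_real_)
    }, numeric(1))
  })
  n_failed <- sum(is.na(taus))
  if (n_failed > 0.2 * B)
    stop("more than 20% of bootstrap replicates failed (", n_failed, "/", B, ")")
  se <- stats::sd(taus, na.rm = TRUE)
  ci <- fit$tau_hat + c(-1, 1) * stats::qnorm(0.975) * se
  p <- if (se > 0) 2 * stats::pnorm(-abs(fit$tau_hat) / se) else as.numeric(fit$tau_hat == 0)
  list(se = se, ci = ci, p_value = p, taus = taus, n_failed = n_failed)
}

#' Re-estimate the ATE with covariates forced into the selected model
#'
#' Augments the selected treatment model with covariates that must be
#' included for subject-matter reasons. Forced covariates that the selection
#' step had shrunk to zero re-enter with their unpenalized SIMEX-corrected
#' coefficient from the pilot \eqn{\tilde\gamma}; covariates already selected
#' are unchanged, so forcing them is a no-op. Step 5 is then re-run under the
#' augmented model.
#'
#' @param sample the [observed_sample()] the fit was computed on.
#' @param fit a [simexsel_fit()] result with `select = TRUE`.
#' @param forced character vector of covariate names to force in.
#' @return An `ate_result` for the augmented model, with the augmented
#'   coefficient vector attached as attribute `"gamma_forced"`.
#' @export
forced_inclusion_ate <- function(sample, fit, forced) {
  stopifnot(inherits(fit, "simexsel_fit"))
  if (is.null(fit$selection)) stop("fit has no selection step to augment")
  nm <- names(fit$gamma_hat)[-1]
  unknown <- setdiff(forced, nm)
  if (length(unknown)) stop("unknown covariate name(s): ", paste(unknown, collapse = ", "))
  gamma_f <- fit$gamma_hat
  add <- forced[abs(gamma_f[forced]) < 1e-10]
  gamma_f[add] <- fit$gamma_tilde[add]
  if (fit$correct) {
    out <- simex_ate(sample, list(gamma_hat = gamma_f), fit$grid, fit$link,
                     family = fit$family, stabilized = fit$stabilized)
  } else {
    est <- ipw_ate(sample$T, sample$Y, propensity(gamma_f, sample, fit$link),
                   fit$stabilized, warn = FALSE)
    out <- structure(list(tau_hat = as.numeric(est), tau_psi = NULL, psi = NULL,
                          fit = NULL, family = NA_character_,
                          se = NULL, ci = NULL, p_value = NULL,
                          flags = list(n_extreme_pi = attr(est, "n_extreme"),
                                       intercept_only = FALSE)),
                     class = "ate_result")
  }
  attr(out, "gamma_forced") <- gamma_f
  out
}
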