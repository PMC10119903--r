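#' Specify a SIMEX grid
#'
#' Defines the simulation-extrapolation layout: the pseudo-error levels
#' \eqn{\psi \in C} (with \eqn{\psi_1 = 0}), the number of pseudo-error
#' replicates K, the measurement-error covariance, and the seed from which
#' the pseudo-errors are generated. The pseudo-errors are a deterministic
#' function of (seed, subject, replicate) only, so the same draws are shared
#' across all \eqn{\psi} levels and reused by the treatment-effect step.
#'
#' @param sigma_e px x px positive semi-definite measurement-error covariance
#'   matrix (a scalar is promoted to a 1 x 1 matrix).
#' @param psi increasing vector of non-negative levels, first element 0.
#'   Default `seq(0, 2, by = 0.25)`.
#' @param K number of pseudo-error replicates per level (default 500).
#' @param seed integer seed for the pseudo-error draws; if `NULL`, one is
#'   drawn from the current RNG stream and stored so the grid stays
#'   reproducible.
#' @param scaling `"sqrt"` (default) adds `sqrt(psi) * e_ik` so the cumulative
#'   error variance is `(1 + psi) * sigma_e` and `psi = -1` corresponds to no
#'   error; `"linear"` adds `psi * e_ik` literally.
#' @return An object of class `simex_grid`.
#' @export
simex_grid <- function(sigma_e, psi = seq(0, 2, by = 0.25), K = 500,
                       seed = NULL, scaling = c("sqrt", "linear")) {
  scaling <- match.arg(scaling)
  if (is.null(dim(sigma_e))) sigma_e <- diag(as.numeric(sigma_e), length(sigma_e))
  sigma_e <- as.matrix(sigma_e)
  if (!is_psd(sigma_e)) stop("sigma_e must be symmetric positive semi-definite")
  if (length(psi) < 1 || psi[1] != 0) stop("psi must start at 0")
  if (any(diff(psi) <= 0)) stop("psi values must be strictly increasing")
  if (any(psi < 0)) stop("psi values must be non-negative")
  K <- as.integer(K)
  if (K < 1) stop("K must be >= 1")
  seed <- seed %||% sample.int(.Machine$integer.max - 1L, 1L)
  structure(list(sigma_e = sigma_e, psi = as.numeric(psi), K = K,
                 seed = as.integer(seed), scaling = scaling),
            class = "simex_grid")
}

#' @export
print.simex_grid <- function(x, ...) {
  cat("SIMEX grid: psi = {", paste(x$psi, collapse = ", "), "}, K =", x$K,
      ", px =", nrow(x$sigma_e), ", scaling =", x$scaling, "\n")
  invisible(x)
}

#' Generate the shared pseudo-error array
#'
#' Draws `e_ik ~ N(0, sigma_e)` for every subject i and replicate k, as an
#' `n x px x K` array, deterministically from the grid seed. These draws are
#' reused across every `psi` level and by the treatment-effect SIMEX step.
#'
#' @param grid a [simex_grid()].
#' @param n number of subjects.
#' @return An `n x px x K` numeric array.
#' @export
pseudo_errors <- function(grid, n) {
  stopifnot(inherits(grid, "simex_grid"))
  px <- nrow(grid$sigma_e)
  with_seed(grid$seed, {
    E <- array(0, c(n, px, grid$K))
    for (k in seq_len(grid$K)) E[, , k] <- rmvnorm_sqrt(n, grid$sigma_e)
    E
  })
}

#' Pseudo-contaminated surrogates for one (k, psi) cell
#'
#' Returns \eqn{X^*(k,\psi) = X^* + \sqrt{\psi}\, e_{ik}} (or
#' \eqn{X^* + \psi e_{ik}} under linear scaling).
#'
#' @param sample an [observed_sample()].
#' @param grid a [simex_grid()].
#' @param k replicate index in `1..K`.
#' @param psi a level from the grid.
#' @param errors optional pre-computed array from [pseudo_errors()]; computed
#'   from the grid seed when omitted.
#' @return An `n x px` matrix.
#' @export
generate_pseudo_data <- function(sample, grid, k, psi, errors = NULL) {
  stopifnot(inherits(sample, "observed_sample"), inherits(grid, "simex_grid"))
  if (k < 1 || k > grid$K) stop("k must be in 1..K")
  if (!any(abs(grid$psi - psi) < 1e-12)) stop("psi is not a grid level")
  errors <- errors %||% pseudo_errors(grid, sample$n)
  s <- if (grid$scaling == "sqrt") sqrt(psi) else psi
  sample$Xstar + s * errors[, , k]
}

#' Run the SIMEX simulation and estimation steps
#'
#' For each pseudo-error level \eqn{\psi} and replicate k, refits the full
#' treatment model on the pseudo-contaminated surrogates and averages the
#' coefficient estimates over k:
#' \eqn{\hat\gamma(\psi) = K^{-1} \sum_k \hat\gamma(k,\psi)}.
#' Non-converged (k, psi) fits are dropped from the average with a logged
#' count; if more than 10\% are dropped a warning is raised.
#'
#' At \eqn{\psi = 0} the pseudo-data equal the observed surrogates for every
#' k, so a single fit is performed.
#'
#' @inheritParams generate_pseudo_data
#' @param link treatment-model link.
#' @param errors optional pseudo-error array (computed from the grid seed when
#'   omitted); the returned trajectory carries it for reuse downstream.
#' @param keep_k keep the full k-indexed coefficient array.
#' @return An object of class `simex_trajectory`: list with `psi`, `gamma`
#'   (M x (1+p) matrix of K-averages), `n_dropped`, `errors`, `grid`, `link`,
#'   and optionally `gamma_k`.
#' @export
run_simex <- function(sample, grid, link = "logistic", errors = NULL,
                      keep_k = FALSE) {
  stopifnot(inherits(sample, "observed_sample"), inherits(grid, "simex_grid"))
  if (nrow(grid$sigma_e) != sample$px)
    stop("sigma_e dimension does not match the number of error-prone covariates")
  errors <- errors %||% pseudo_errors(grid, sample$n)
  M <- length(grid$psi)
  q <- 1 + sample$p
  G <- matrix(NA_real_, M, q)
  n_dropped <- integer(M)
  gamma_k <- if (keep_k) array(NA_real_, c(M, grid$K, q)) else NULL
  no_error <- all(grid$sigma_e == 0)
  for (m in seq_len(M)) {
    ps <- grid$psi[m]
    if (ps == 0 || no_error) {
      fit <- fit_treatment_model(sample, link)
      G[m, ] <- fit$coefficients
      if (keep_k) for (k in seq_len(grid$K)) gamma_k[m, k, ] <- fit$coefficients
      next
    }
    s <- if (grid$scaling == "sqrt") sqrt(ps) else ps
    acc <- matrix(NA_real_, grid$K, q)
    for (k in seq_len(grid$K)) {
      Xk <- sample$Xstar + s * errors[, , k]
      fit <- tryCatch(fit_treatment_model(sample, link, X = Xk),
                      error = function(e) NULL)
      if (!is.null(fit)) acc[k, ] <- fit$coefficients
    }
    ok <- stats::complete.cases(acc)
    n_dropped[m] <- sum(!ok)
    if (!any(ok)) stop("all ", grid$K, " fits failed at psi = ", ps)
    G[m, ] <- colMeans(acc[ok, , drop = FALSE])
    if (keep_k) gamma_k[m, , ] <- acc
  }
  if (sum(n_dropped) > 0.1 * M * grid$K)
    warning("more than 10% of (k, psi) fits were dropped for non-convergence")
  colnames(G) <- c("(Intercept)", sample$x_names, sample$z_names)
  structure(list(psi = grid$psi, gamma = G, n_dropped = n_dropped,
                 errors = errors, grid = grid, link = link,
                 gamma_k = gamma_k),
            class = "simex_trajectory")
}

#' @export
print.simex_trajectory <- function(x, ...) {
  cat("SIMEX trajectory over", length(x$psi), "psi levels, K =", x$grid$K, "\n")
  print(round(x$gamma, 4))
  invisible(x)
}

#' Export a trajectory as a tidy data frame
#'
#' @param traj a `simex_trajectory`.
#' @return data frame with columns `component`, `psi`, `estimate`.
#' @export
trajectory_table <- function(traj) {
  stopifnot(inherits(traj, "simex_trajectory"))
  data.frame(component = rep(colnames(traj$gamma), each = length(traj$psi)),
             psi = rep(traj$psi, ncol(traj$gamma)),
             estimate = as.vector(traj$gamma))
}

# exact fit of a + b/(c + psi) through three points; NULL when degenerate
#' @noRd
rational_three_point <- function(psi3, v3) {
  d12 <- v3[1] - v3[2]; d23 <- v3[2] - v3[3]
  if (abs(d23) < 1e-12 || abs(d12) < 1e-12) return(NULL)
  r <- d12 / d23
  den <- r * (psi3[3] - psi3[2]) - (psi3[2] - psi3[1])
  if (abs(den) < 1e-12) return(NULL)
  cc <- ((psi3[2] - psi3[1]) * psi3[3] - r * (psi3[3] - psi3[2]) * psi3[1]) / den
  b <- d12 * (cc + psi3[1]) * (cc + psi3[2]) / (psi3[2] - psi3[1])
  a <- v3[1] - b / (cc + psi3[1])
  c(a = a, b = b, c = cc)
}

#' Fit an extrapolant to a SIMEX coefficient trajectory
#'
#' Fits one of three working extrapolation families to the points
#' \eqn{\{(\psi, v(\psi))\}} and evaluates it at \eqn{\psi = -1}:
#' * `linear`: \eqn{a + b\psi}, exact ordinary least squares;
#' * `quadratic`: \eqn{a + b\psi + c\psi^2}, exact ordinary least squares;
#' * `rational_linear`: \eqn{a + b/(c + \psi)}, nonlinear least squares
#'   (Levenberg-Marquardt) initialized from the exact solution through three
#'   spread points.
#'
#' A rational-linear fit whose pole `-c` falls inside `[-1, max(psi)]` is
#' unusable for extrapolation; the fit falls back to quadratic with a warning.
#'
#' @param psi numeric vector of levels.
#' @param values numeric vector of trajectory values, same length.
#' @param family extrapolant family.
#' @return An object of class `extrapolation_fit`: list with `family`,
#'   `coefficients`, `value_at_minus_one`, `rss`, and `fallback` flag.
#' @export
fit_extrapolant <- function(psi, values,
                            family = c("quadratic", "linear", "rational_linear")) {
  family <- match.arg(family)
  if (length(psi) != length(values)) stop("psi and values must have equal length")
  npar <- switch(family, linear = 2L, quadratic = 3L, rational_linear = 3L)
  if (length(unique(psi)) < npar)
    stop("family '", family, "' needs at least ", npar, " distinct psi points")
  poly_fit <- function(deg) {
    Xp <- stats::poly(psi, degree = deg, raw = TRUE)
    f <- stats::lm.fit(cbind(1, Xp), values)
    co <- unname(f$coefficients)
    list(coefficients = co,
         value = sum(co * (-1)^(0:deg)),
         rss = sum(f$residuals^2))
  }
  fallback <- FALSE
  if (family == "rational_linear") {
    fit <- rational_fit(psi, values)
    if (is.null(fit)) {
      warning("rational-linear extrapolant unusable on [-1, max(psi)]; falling back to quadratic")
      fallback <- TRUE
      family <- "quadratic"
      fit <- poly_fit(2)
    }
  } else {
    fit <- poly_fit(switch(family, linear = 1L, quadratic = 2L))
  }
  structure(list(family = family, coefficients = fit$coefficients,
                 value_at_minus_one = fit$value, rss = fit$rss,
                 fallback = fallback),
            class = "extrapolation_fit")
}

# rational-linear fit machinery; returns NULL when the fit is degenerate or
# its pole lies in the extrapolation range
#' @noRd
rational_fit <- function(psi, values) {
  # near-constant trajectory: extrapolation is the constant
  if (stats::sd(values) < 1e-12 * max(1, abs(mean(values))) || stats::sd(values) == 0) {
    a <- mean(values)
    return(list(coefficients = c(a = a, b = 0, c = 2),
                value = a, rss = sum((values - a)^2)))
  }
  M <- length(psi)
  idx <- unique(round(c(1, (M + 1) / 2, M)))
  init <- rational_three_point(psi[idx], values[idx])
  if (is.null(init) || !all(is.finite(init)) || init["c"] + min(psi) <= 0)
    init <- c(a = mean(values), b = (values[1] - values[M]) * 2, c = 2)
  df <- data.frame(psi = psi, v = values)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ a + b / (cc + psi), data = df,
                      start = list(a = init[["a"]], b = init[["b"]], cc = init[["c"]]),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  co <- if (is.null(fit)) init else {
    cf <- stats::coef(fit); c(a = cf[["a"]], b = cf[["b"]], c = cf[["cc"]])
  }
  # pole -c inside [-1, max(psi)] (i.e. c in [-max(psi), 1]) breaks extrapolation
  if (!all(is.finite(co)) || (co[["c"]] >= -max(psi) - 1e-9 && co[["c"]] <= 1 + 1e-9))
    return(NULL)
  v <- co[["a"]] + co[["b"]] / (co[["c"]] - 1)
  pred <- co[["a"]] + co[["b"]] / (co[["c"]] + psi)
  list(coefficients = co, value = v, rss = sum((values - pred)^2))
}

#' @export
print.extrapolation_fit <- function(x, ...) {
  cat("Extrapolant (", x$family, if (x$fallback) ", fallback" else "",
      "): value at psi = -1 is ", signif(x$value_at_minus_one, 6), "\n", sep = "")
  invisible(x)
}

#' Extrapolate a SIMEX trajectory to psi = -1
#'
#' Applies [fit_extrapolant()] componentwise to each coefficient trajectory
#' and collects the values at \eqn{\psi = -1} into the SIMEX-corrected
#' coefficient vector \eqn{\tilde\gamma}.
#'
#' @param traj a `simex_trajectory` from [run_simex()].
#' @param family extrapolant family; see [fit_extrapolant()].
#' @return Named numeric vector \eqn{\tilde\gamma} with attribute `"fits"`
#'   holding the per-component `extrapolation_fit` objects.
#' @export
extrapolate_trajectory <- function(traj, family = "quadratic") {
  stopifnot(inherits(traj, "simex_trajectory"))
  fits <- lapply(seq_len(ncol(traj$gamma)), function(j)
    fit_extrapolant(traj$psi, traj$gamma[, j], family))
  out <- vapply(fits, function(f) f$value_at_minus_one, numeric(1))
  names(out) <- colnames(traj$gamma)
  attr(out, "fits") <- fits
  out
}
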