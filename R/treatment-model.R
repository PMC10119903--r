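#' Propensity model link functions
#'
#' Maps a linear predictor to a treatment probability under one of three
#' binary-regression links. Probabilities are clipped to the open interval
#' `(1e-10, 1 - 1e-10)` so that scores and inverse weights stay finite for
#' extreme linear predictors; at realistic predictor values the clipping is
#' inactive.
#'
#' @param eta numeric vector of linear predictor values.
#' @param link one of `"logistic"`, `"probit"`, `"cloglog"`.
#' @return Probabilities in (0, 1), same length as `eta`.
#' @examples
#' link_prob(0, "logistic")  # 0.5
#' link_prob(0, "cloglog")   # 1 - exp(-1)
#' @export
link_prob <- function(eta, link = c("logistic", "probit", "cloglog")) {
  link <- match.arg(link)
  if (any(!is.finite(eta))) stop("linear predictor must be finite")
  p <- switch(link,
    logistic = stats::plogis(eta),
    probit   = stats::pnorm(eta),
    cloglog  = 1 - exp(-exp(pmin(eta, 30)))
  )
  pmin(pmax(p, 1e-10), 1 - 1e-10)
}

# d pi / d eta for each link, clipped away from zero where it multiplies
# an inverse variance.
#' @noRd
link_mu_eta <- function(eta, link) {
  switch(link,
    logistic = {
      p <- stats::plogis(eta); p * (1 - p)
    },
    probit = stats::dnorm(eta),
    cloglog = exp(pmin(eta, 30) - exp(pmin(eta, 30)))
  )
}

#' Score function of the treatment model
#'
#' Gradient of the Bernoulli log-likelihood of the treatment indicator under
#' the chosen link, summed over subjects:
#' \eqn{\sum_i S_i(\gamma) = \sum_i d_i (g'(\eta_i)/\{\pi_i(1-\pi_i)\}) (T_i - \pi_i)}
#' with design row \eqn{d_i = (1, x_i, z_i)}. It vanishes at the maximum
#' likelihood solution.
#'
#' @param gamma coefficient vector of length `1 + p`, laid out as
#'   (intercept, X coefficients, Z coefficients).
#' @param sample an [observed_sample()].
#' @param link link function name.
#' @param X optional n x px matrix substituting for the surrogates (used to
#'   plug pseudo-contaminated covariates into the same score).
#' @return Numeric score vector of length `1 + p`.
#' @export
treatment_score <- function(gamma, sample, link = "logistic", X = NULL) {
  D <- design_matrix(sample, X)
  if (length(gamma) != ncol(D)) stop("gamma has length ", length(gamma),
                                     " but the model has ", ncol(D), " coefficients")
  eta <- drop(D %*% gamma)
  p <- link_prob(eta, link)
  w <- link_mu_eta(eta, link) / (p * (1 - p))
  drop(crossprod(D, w * (sample$T - p)))
}

# Bernoulli log-likelihood at clipped probabilities.
#' @noRd
treatment_loglik <- function(gamma, D, T, link) {
  p <- link_prob(drop(D %*% gamma), link)
  sum(T * log(p) + (1 - T) * log(1 - p))
}

#' Fit the treatment model by solving the score equation
#'
#' Solves \eqn{\sum_i S_i(\gamma) = 0} by Fisher scoring (Newton with the
#' expected information) from a zero start, with step-halving on the
#' log-likelihood, so the fit is deterministic given the inputs. Convergence
#' is declared when the supremum norm of the score drops below `tol`.
#'
#' Diverging coefficient paths (complete or quasi-complete separation) are
#' capped at `cap` in absolute value and flagged with a warning.
#'
#' @inheritParams treatment_score
#' @param tol convergence tolerance on the score supremum norm.
#' @param maxit maximum number of Fisher scoring iterations.
#' @param cap absolute bound on coefficients used to detect separation.
#' @return An object of class `treatment_fit`: list with `coefficients`
#'   (named), `converged`, `iterations`, `link`, and `separation` flag.
#'   On non-convergence an error is thrown carrying the last iterate in
#'   its `last` condition field.
#' @export
fit_treatment_model <- function(sample, link = c("logistic", "probit", "cloglog"),
                                X = NULL, tol = 1e-8, maxit = 100, cap = 30) {
  link <- match.arg(link)
  D <- design_matrix(sample, X)
  T <- sample$T
  q <- ncol(D)
  gamma <- numeric(q)
  ll <- treatment_loglik(gamma, D, T, link)
  converged <- FALSE
  separation <- FALSE
  it <- 0L
  for (it in seq_len(maxit)) {
    eta <- drop(D %*% gamma)
    p <- link_prob(eta, link)
    mu <- link_mu_eta(eta, link)
    v <- p * (1 - p)
    s <- drop(crossprod(D, (mu / v) * (T - p)))
    if (max(abs(s)) < tol) { converged <- TRUE; break }
    W <- pmax(mu^2 / v, 1e-10)
    H <- crossprod(D, D * W)
    step <- tryCatch(solve(H, s), error = function(e) NULL)
    if (is.null(step)) {
      cond <- structure(class = c("simexsel_singular_fit", "error", "condition"),
                        list(message = "singular information matrix; is the design full rank?",
                             call = sys.call(-1), last = gamma))
      stop(cond)
    }
    # step-halving: insist on non-decreasing log-likelihood
    h <- 1
    repeat {
      cand <- gamma + h * step
      llc <- treatment_loglik(cand, D, T, link)
      if (llc >= ll - 1e-12 || h < 1e-4) break
      h <- h / 2
    }
    gamma <- cand; ll <- llc
    if (max(abs(gamma)) > cap) {
      separation <- TRUE
      gamma <- pmin(pmax(gamma, -cap), cap)
    }
  }
  if (separation)
    warning("diverging coefficients detected (possible separation); estimate capped at |gamma| <= ", cap)
  if (!converged && !separation) {
    # re-check the score at the final iterate before declaring failure
    s <- treatment_score(gamma, sample, link, X)
    if (max(abs(s)) < sqrt(tol)) converged <- TRUE
  }
  if (!converged && !separation) {
    cond <- structure(class = c("simexsel_nonconvergence", "error", "condition"),
                      list(message = sprintf("treatment model fit did not converge in %d iterations", maxit),
                           call = sys.call(-1), last = gamma))
    stop(cond)
  }
  names(gamma) <- colnames(D)
  structure(list(coefficients = gamma, converged = converged,
                 iterations = it, link = link, separation = separation),
            class = "treatment_fit")
}

#' @export
print.treatment_fit <- function(x, ...) {
  cat("Treatment model (", x$link, "), ",
      if (x$converged) "converged" else "NOT converged",
      " in ", x$iterations, " iterations\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.treatment_fit <- function(object, ...) object$coefficients
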