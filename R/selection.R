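#' Penalty derivative weights
#'
#' First derivative \eqn{p'_\lambda(u)} of the LASSO and SCAD penalties,
#' evaluated at the magnitude of a pilot estimate. These derivatives are the
#' weights of the one-step weighted-L1 penalty
#' \eqn{p_\lambda(|\gamma_j|) = p'_\lambda(|\tilde\gamma_j|)\,|\gamma_j|}.
#'
#' LASSO: \eqn{p'_\lambda(u) = \lambda}. SCAD:
#' \eqn{p'_\lambda(u) = \lambda I(u \le \lambda) +
#' (a\lambda - u)_+ / (a - 1) \, I(u > \lambda)}, which is continuous in u and
#' vanishes for \eqn{u \ge a\lambda}, so large pilot coefficients are left
#' unpenalized (the near-unbiasedness behind the oracle property).
#'
#' @param u non-negative pilot magnitude(s).
#' @param lambda positive tuning parameter.
#' @param penalty `"scad"` (default) or `"lasso"`.
#' @param a SCAD shape parameter, must exceed 2; default 3.7.
#' @return Non-negative weight(s), same length as `u`.
#' @examples
#' penalty_weight(2, 1, "scad")  # (3.7 - 2) / 2.7
#' @export
penalty_weight <- function(u, lambda, penalty = c("scad", "lasso"), a = 3.7) {
  penalty <- match.arg(penalty)
  if (any(u < 0)) stop("u must be non-negative")
  if (lambda <= 0) stop("lambda must be positive")
  if (penalty == "lasso") return(rep(lambda, length(u)))
  if (a <= 2) stop("SCAD shape parameter a must exceed 2")
  ifelse(u <= lambda, lambda, pmax(a * lambda - u, 0) / (a - 1))
}

#' Soft-thresholding operator
#'
#' \eqn{S(x, t) = \mathrm{sign}(x)(|x| - t)_+}, the proximal map of the
#' absolute-value penalty.
#'
#' @param x numeric vector.
#' @param t non-negative threshold(s).
#' @export
soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' Minimize the penalized quadratic loss around a pilot estimate
#'
#' Solves
#' \deqn{\hat\gamma(\lambda) = \arg\min_\gamma \; \frac{n}{2}
#'   (\gamma - \tilde\gamma)^\top V_n (\gamma - \tilde\gamma)
#'   + n \sum_{j \ge 1} w_j |\gamma_j|, \qquad
#'   w_j = p'_\lambda(|\tilde\gamma_j|),}
#' where \eqn{\tilde\gamma} is the (SIMEX-corrected) pilot estimate and the
#' intercept (j = 0) is never penalized. The quadratic loss carries the
#' n-scaling of a log-likelihood curvature so that it is commensurate with
#' the `2 log(n) df` model-size term of the BIC used to tune \eqn{\lambda}.
#'
#' With `Vn = NULL` (the identity working weight) the solution is the exact
#' componentwise soft-threshold
#' \eqn{\hat\gamma_j = \mathrm{sign}(\tilde\gamma_j)
#' (|\tilde\gamma_j| - w_j)_+}; a general positive definite `Vn` is handled
#' by cyclic coordinate descent to tolerance `tol`.
#'
#' @param gamma_tilde named pilot coefficient vector (intercept first).
#' @param lambda positive tuning parameter.
#' @param n sample size behind the pilot estimate.
#' @param penalty,a see [penalty_weight()].
#' @param Vn optional positive definite weight matrix of dimension
#'   `length(gamma_tilde)`; `NULL` means identity.
#' @param penalty_factor multiplier on each non-intercept weight (length
#'   `length(gamma_tilde) - 1`); setting an entry to 0 forces that covariate
#'   into the model.
#' @param tol,maxit coordinate-descent control.
#' @return Coefficient vector \eqn{\hat\gamma(\lambda)}, same names as the
#'   pilot.
#' @export
minimize_penalized_loss <- function(gamma_tilde, lambda, n,
                                    penalty = "scad", a = 3.7, Vn = NULL,
                                    penalty_factor = NULL,
                                    tol = 1e-9, maxit = 10000) {
  if (any(!is.finite(gamma_tilde))) stop("pilot estimate must be finite")
  q <- length(gamma_tilde)
  w <- c(0, penalty_weight(abs(gamma_tilde[-1]), lambda, penalty, a))
  if (!is.null(penalty_factor)) {
    if (length(penalty_factor) != q - 1) stop("penalty_factor must have one entry per covariate")
    w[-1] <- w[-1] * penalty_factor
  }
  if (is.null(Vn)) return(soft_threshold(gamma_tilde, w))
  Vn <- as.matrix(Vn)
  if (!isTRUE(all.equal(dim(Vn), c(q, q))) || !is_psd(Vn) ||
      min(eigen(Vn, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("Vn must be positive definite with dimension matching the pilot")
  # cyclic coordinate descent on the (n-cancelled) objective
  g <- soft_threshold(gamma_tilde, w)  # warm start at the identity solution
  d <- diag(Vn)
  for (it in seq_len(maxit)) {
    delta <- 0
    r <- drop(Vn %*% (g - gamma_tilde))
    for (j in seq_len(q)) {
      rj <- r[j] - d[j] * (g[j] - gamma_tilde[j])  # partial residual
      new <- soft_threshold(gamma_tilde[j] - rj / d[j], w[j] / d[j])
      if (new != g[j]) {
        r <- r + Vn[, j] * (new - g[j])
        delta <- max(delta, abs(new - g[j]))
        g[j] <- new
      }
    }
    if (delta < tol) break
  }
  names(g) <- names(gamma_tilde)
  g
}

#' BIC score for a penalized fit
#'
#' \eqn{\mathrm{BIC}(\lambda) = n(\hat\gamma - \tilde\gamma)^\top V_n
#' (\hat\gamma - \tilde\gamma) + 2 \log(n)\, \mathrm{df}_\lambda}, where
#' \eqn{\mathrm{df}_\lambda} counts the non-zero components of
#' \eqn{\hat\gamma(\lambda)} (intercept included; entries below `1e-10` in
#' magnitude count as zero).
#'
#' @param gamma_hat penalized estimate.
#' @param gamma_tilde pilot estimate.
#' @param n sample size.
#' @param Vn optional positive definite weight matrix (`NULL` = identity).
#' @return Scalar BIC value.
#' @export
bic_score <- function(gamma_hat, gamma_tilde, n, Vn = NULL) {
  d <- gamma_hat - gamma_tilde
  quad <- if (is.null(Vn)) sum(d^2) else drop(crossprod(d, Vn %*% d))
  df <- sum(abs(gamma_hat) > 1e-10)
  n * quad + 2 * log(n) * df
}

#' Select active confounders by BIC-tuned weighted-L1 shrinkage
#'
#' Runs [minimize_penalized_loss()] over a grid of tuning parameters, scores
#' each solution by [bic_score()], and returns the minimizer. Ties in BIC are
#' broken toward the larger tuning parameter (the sparser model). The default
#' grid is `n_lambda` log-spaced values spanning
#' `[lambda_min_ratio * max|gamma_tilde[-1]|, max|gamma_tilde[-1]|]`, i.e.
#' from shrinking essentially nothing to shrinking every covariate.
#'
#' @inheritParams minimize_penalized_loss
#' @param lambda optional explicit grid; overrides the automatic one.
#' @param n_lambda,lambda_min_ratio automatic grid size and lower end.
#' @param force_in character vector of covariate names (or integer positions
#'   among the non-intercept components) that must stay in the model; their
#'   penalty weight is fixed at zero.
#' @return An object of class `selection_result`: list with `gamma_hat`
#'   (named), `active` (logical mask over all components; intercept always
#'   `TRUE`), `path` (data frame: `lambda`, `df`, `bic`), `lambda_star`,
#'   `penalty`, `a`, and the `estimates` matrix of the per-lambda solutions.
#' @export
select_coefficients <- function(gamma_tilde, n, penalty = c("scad", "lasso"),
                                a = 3.7, lambda = NULL, n_lambda = 50,
                                lambda_min_ratio = 1e-4, Vn = NULL,
                                force_in = NULL) {
  penalty <- match.arg(penalty)
  q <- length(gamma_tilde)
  if (q < 2) stop("pilot must contain an intercept and at least one covariate")
  nm <- names(gamma_tilde) %||% c("(Intercept)", paste0("V", seq_len(q - 1)))
  names(gamma_tilde) <- nm
  pf <- rep(1, q - 1)
  if (!is.null(force_in)) {
    idx <- if (is.character(force_in)) match(force_in, nm[-1]) else as.integer(force_in)
    if (anyNA(idx) || any(idx < 1 | idx > q - 1))
      stop("unknown force_in covariate(s): ",
           paste(force_in[is.na(idx) | idx < 1 | idx > q - 1], collapse = ", "))
    pf[idx] <- 0
  }
  if (is.null(lambda)) {
    mx <- max(abs(gamma_tilde[-1]))
    if (mx == 0) mx <- 1  # all-zero pilot: any grid selects the empty model
    lambda <- exp(seq(log(lambda_min_ratio * mx), log(mx), length.out = n_lambda))
  }
  if (!length(lambda)) stop("lambda grid is empty")
  lambda <- sort(lambda, decreasing = TRUE)  # sparser models first -> ties favor them
  est <- matrix(NA_real_, length(lambda), q, dimnames = list(NULL, nm))
  path <- data.frame(lambda = lambda, df = NA_integer_, bic = NA_real_)
  for (i in seq_along(lambda)) {
    g <- minimize_penalized_loss(gamma_tilde, lambda[i], n, penalty, a, Vn, pf)
    est[i, ] <- g
    path$df[i] <- sum(abs(g) > 1e-10)
    path$bic[i] <- bic_score(g, gamma_tilde, n, Vn)
  }
  best <- which.min(path$bic)
  gamma_hat <- est[best, ]
  structure(list(gamma_hat = gamma_hat,
                 active = abs(gamma_hat) > 1e-10 | seq_len(q) == 1L,
                 path = path, lambda_star = lambda[best],
                 penalty = penalty, a = a, estimates = est,
                 force_in = force_in),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  act <- names(x$gamma_hat)[x$active][-1]
  cat("Penalized selection (", x$penalty, "), lambda* = ",
      signif(x$lambda_star, 4), "\n", sep = "")
  cat("Active covariates (", length(act), "): ",
      paste(act, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Export a selection path as a data frame
#'
#' @param selection a `selection_result`.
#' @return data frame with `lambda`, `df`, `bic` and one column per component.
#' @export
selection_path_table <- function(selection) {
  stopifnot(inherits(selection, "selection_result"))
  cbind(selection$path, as.data.frame(selection$estimates))
}
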