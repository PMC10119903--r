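# Internal helpers shared across the package.

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a temporary RNG state.
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG stream so
#' that seeded internals (pseudo-error generation, Monte Carlo truths) do not
#' perturb user-level randomness.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Draw n rows from N(0, Sigma) using a Cholesky (or eigen) square root.
#'
#' `chol()` is used when Sigma is positive definite; positive semi-definite
#' matrices fall back to an eigendecomposition with negative eigenvalues
#' clipped at zero.
#' @noRd
rmvnorm_sqrt <- function(n, Sigma) {
  d <- nrow(Sigma)
  if (d == 0L) return(matrix(0, n, 0))
  R <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(R)) {
    es <- eigen(Sigma, symmetric = TRUE)
    R <- t(es$vectors %*% (sqrt(pmax(es$values, 0)) * t(es$vectors)))
  }
  matrix(stats::rnorm(n * d), n, d) %*% R
}

#' Symmetry + positive semi-definiteness check.
#' @noRd
is_psd <- function(S, tol = 1e-8) {
  if (!isSymmetric(unname(S), tol = 1e-8)) return(FALSE)
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  all(ev > -tol * max(1, abs(ev[1])))
}

#' Clip eigenvalues at zero to repair a nearly-PSD matrix.
#' @noRd
psd_repair <- function(S, warn = TRUE) {
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  if (min(es$values) < -1e-8 * max(1, abs(es$values[1]))) {
    if (warn) warning("matrix is not positive semi-definite; clipping negative eigenvalues at 0")
    S <- es$vectors %*% (pmax(es$values, 0) * t(es$vectors))
    S <- (S + t(S)) / 2
  }
  S
}
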