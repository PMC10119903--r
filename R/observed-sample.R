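#' Assemble an observed sample for treatment-effect estimation
#'
#' Bundles the per-subject data used throughout the package: a binary
#' treatment indicator, an outcome (continuous or binary), the observed
#' surrogates of the error-prone covariates, and the error-free covariates.
#'
#' @param treatment integer or logical vector of 0/1 treatment indicators.
#' @param outcome numeric outcome vector of the same length.
#' @param x_star numeric matrix (or data frame) of observed surrogates for the
#'   error-prone covariates, one row per subject. May have zero columns.
#' @param z numeric matrix (or data frame) of error-free covariates. May have
#'   zero columns; at least one covariate must be present overall.
#' @param x_names,z_names optional column names; defaults are taken from the
#'   matrices or generated as `X1..Xpx` / `Z1..Zpz`.
#'
#' @return An object of class `observed_sample`: a list with elements
#'   `T`, `Y`, `Xstar` (n x px), `Z` (n x pz), `n`, `px`, `pz`, `p`,
#'   `x_names`, `z_names`.
#'
#' @examples
#' s <- observed_sample(c(1, 0, 1, 0), rnorm(4),
#'                      matrix(rnorm(8), 4), matrix(rnorm(4), 4))
#' s$p
#' @export
observed_sample <- function(treatment, outcome, x_star = NULL, z = NULL,
                            x_names = NULL, z_names = NULL) {
  T <- as.numeric(treatment)
  Y <- as.numeric(outcome)
  n <- length(T)
  as_mat <- function(m, nr) {
    if (is.null(m)) return(matrix(0, nr, 0))
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  }
  Xstar <- as_mat(x_star, n)
  Z <- as_mat(z, n)
  if (length(Y) != n || nrow(Xstar) != n || nrow(Z) != n)
    stop("treatment, outcome and covariate matrices must have the same number of rows")
  if (anyNA(T) || anyNA(Y) || anyNA(Xstar) || anyNA(Z))
    stop("missing values are not supported")
  if (!all(T %in% c(0, 1))) stop("treatment must be coded 0/1")
  if (n < 2 || !any(T == 1) || !any(T == 0))
    stop("both treatment arms must be present (n >= 2)")
  px <- ncol(Xstar); pz <- ncol(Z)
  if (px + pz < 1) stop("at least one covariate is required")
  x_names <- x_names %||% colnames(Xstar) %||% if (px) paste0("X", seq_len(px)) else character()
  z_names <- z_names %||% colnames(Z) %||% if (pz) paste0("Z", seq_len(pz)) else character()
  colnames(Xstar) <- x_names
  colnames(Z) <- z_names
  structure(list(T = T, Y = Y, Xstar = Xstar, Z = Z,
                 n = n, px = px, pz = pz, p = px + pz,
                 x_names = x_names, z_names = z_names),
            class = "observed_sample")
}

#' Read an observed sample from CSV
#'
#' Expects columns `T` and `Y` plus covariate columns. Columns named in
#' `x_cols` (default: those starting with `"X"`) are treated as error-prone
#' surrogates; `z_cols` (default: those starting with `"Z"`) as error-free.
#'
#' @param path path to a CSV file.
#' @param x_cols,z_cols character vectors naming the surrogate and error-free
#'   covariate columns; by default inferred from the `X`/`Z` prefixes.
#' @return An [observed_sample()].
#' @export
read_sample_csv <- function(path, x_cols = NULL, z_cols = NULL) {
  d <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("T", "Y") %in% names(d)))
    stop("CSV must contain columns 'T' and 'Y'")
  other <- setdiff(names(d), c("T", "Y"))
  x_cols <- x_cols %||% grep("^X", other, value = TRUE)
  z_cols <- z_cols %||% grep("^Z", other, value = TRUE)
  missing <- setdiff(c(x_cols, z_cols), names(d))
  if (length(missing)) stop("columns not found: ", paste(missing, collapse = ", "))
  observed_sample(d$T, d$Y,
                  if (length(x_cols)) d[x_cols] else NULL,
                  if (length(z_cols)) d[z_cols] else NULL)
}

#' Standardize the covariates of a sample
#'
#' Centers each surrogate and error-free covariate column to mean 0 and
#' scales it to variance 1. Intended as preprocessing for real data; synthetic
#' designs generate standardized covariates already.
#'
#' @param sample an [observed_sample()].
#' @return A new `observed_sample` with standardized `Xstar` and `Z`; the
#'   centers and scales are attached as attributes `"center"` and `"scale"`.
#' @export
standardize_covariates <- function(sample) {
  stopifnot(inherits(sample, "observed_sample"))
  std <- function(m) {
    if (ncol(m) == 0) return(list(m = m, c = numeric(), s = numeric()))
    c0 <- colMeans(m)
    s0 <- apply(m, 2, stats::sd)
    if (any(s0 == 0)) stop("constant covariate column cannot be standardized")
    list(m = sweep(sweep(m, 2, c0), 2, s0, "/"), c = c0, s = s0)
  }
  x <- std(sample$Xstar); z <- std(sample$Z)
  out <- observed_sample(sample$T, sample$Y, x$m, z$m,
                         sample$x_names, sample$z_names)
  attr(out, "center") <- c(x$c, z$c)
  attr(out, "scale") <- c(x$s, z$s)
  out
}

#' @export
print.observed_sample <- function(x, ...) {
  cat("Observed sample: n =", x$n,
      "| treated =", sum(x$T == 1),
      "| error-prone covariates =", x$px,
      "| error-free covariates =", x$pz, "\n")
  invisible(x)
}

# Design matrix (intercept, X, Z) for the treatment model; X may be overridden
# by a pseudo-contaminated version of the surrogates.
#' @noRd
design_matrix <- function(sample, X = NULL) {
  X <- X %||% sample$Xstar
  D <- cbind(1, X, sample$Z)
  colnames(D) <- c("(Intercept)", sample$x_names, sample$z_names)
  D
}
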