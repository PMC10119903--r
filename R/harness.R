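#' Coefficient estimation and selection metrics
#'
#' Summarizes a coefficient estimate against the truth with the four
#' variable-selection metrics used in the simulation tables: the L1 and L2
#' losses \eqn{\sum_{k=0}^p |\hat\gamma_k - \gamma_k|} and
#' \eqn{\sum_{k=0}^p (\hat\gamma_k - \gamma_k)^2} (intercept included), the
#' number of selected covariates `#S` (non-zero non-intercept components of
#' the estimate), and the number of falsely excluded important covariates
#' `#FN` (truly non-zero components estimated as zero). Magnitudes below
#' `1e-10` count as zero.
#'
#' @param gamma_hat estimated coefficient vector (intercept first).
#' @param gamma_true true coefficient vector, same length.
#' @return Named numeric vector: `l1`, `l2`, `n_selected`,
#'   `n_false_negative`.
#' @examples
#' gamma_metrics(c(1, 0, 0), c(1, 1, 0))  # l1 = 1, #S = 0, #FN = 1
#' @export
gamma_metrics <- function(gamma_hat, gamma_true) {
  if (length(gamma_hat) != length(gamma_true))
    stop("estimate and truth must have equal length")
  nz_hat <- abs(gamma_hat) > 1e-10
  c(l1 = sum(abs(gamma_hat - gamma_true)),
    l2 = sum((gamma_hat - gamma_true)^2),
    n_selected = sum(nz_hat[-1]),
    n_false_negative = sum(gamma_true != 0 & !nz_hat))
}

# parse a benchmark method tag into its components
#' @noRd
parse_method <- function(method) {
  known <- c("scad", "lasso", "full",
             "naive_scad", "naive_lasso", "naive_full",
             "trueX_scad", "trueX_lasso", "trueX_full")
  if (!method %in% known)
    stop("unknown method '", method, "'; choose from: ", paste(known, collapse = ", "))
  parts <- strsplit(method, "_")[[1]]
  if (length(parts) == 1) parts <- c("proposed", parts)
  list(covariates = switch(parts[1], proposed = "simex", naive = "star", trueX = "true"),
       selection = parts[2])
}

#' Replicate-level simulation benchmark
#'
#' Repeats the full estimation pipeline on independently generated synthetic
#' datasets and aggregates the variable-selection metrics (L1/L2 loss, #S,
#' #FN) and the estimation metrics (Bias, S.E., RMSE, and optionally CR%, the
#' coverage of bootstrap confidence intervals) per method.
#'
#' Methods combine the covariate treatment with the selection step:
#' `"scad"`, `"lasso"`, `"full"` run the SIMEX-corrected pipeline (selection
#' by the named penalty, or no selection for `"full"`); `"naive_*"` variants
#' treat the surrogates as true covariates (no correction); `"trueX_*"`
#' variants use the error-free covariates (the benchmark an oracle would
#' run). Within a replicate all SIMEX-based methods share one coefficient
#' trajectory and one pseudo-error set, so the comparison is paired.
#'
#' Replicate seeds are drawn up front from the master seed, so results are
#' deterministic and invariant to the execution order of replicates.
#'
#' @param design a [simulation_design()].
#' @param methods character vector of method tags (see Details).
#' @param extrapolation one or more extrapolant families applied to the
#'   SIMEX-based methods.
#' @param reps number of simulation replicates (>= 2).
#' @param K,psi SIMEX grid settings for the benchmark runs.
#' @param seed master seed.
#' @param n_lambda tuning-grid size for the selection step.
#' @param compute_ci also compute bootstrap confidence intervals per
#'   replicate (B resamples each) and report coverage; off by default since
#'   it multiplies the cost by roughly B.
#' @param B bootstrap replicates per CI when `compute_ci = TRUE`.
#' @param tau0 true ATE; computed from the design when omitted (Monte Carlo
#'   with 5000 draws for the logistic outcome model).
#' @param verbose print per-replicate progress.
#' @return An object of class `benchmark_result`: list with `records` (one
#'   row per replicate x method x extrapolant) and `summary` (aggregated
#'   table), plus `tau0` and the call configuration.
#' @export
run_benchmark <- function(design,
                          methods = c("scad", "naive_scad", "full", "trueX_scad"),
                          extrapolation = "quadratic",
                          reps = 100, K = 50, psi = seq(0, 2, by = 0.25),
                          seed = 1, n_lambda = 50,
                          compute_ci = FALSE, B = 50,
                          tau0 = NULL, verbose = FALSE) {
  stopifnot(inherits(design, "simulation_design"), reps >= 2)
  specs <- lapply(methods, parse_method)
  names(specs) <- methods
  tau0 <- tau0 %||% true_tau(design, n_mc = 5000, seed = seed)
  seeds <- with_seed(seed, matrix(sample.int(.Machine$integer.max - 2L, reps * 2L),
                                  reps, 2))
  rec <- vector("list", reps)
  for (r in seq_len(reps)) {
    rows <- tryCatch(
      run_replicate(design, specs, extrapolation, K, psi,
                    data_seed = seeds[r, 1], grid_seed = seeds[r, 2],
                    n_lambda = n_lambda, compute_ci = compute_ci, B = B,
                    tau0 = tau0),
      error = function(e) {
        warning("replicate ", r, " failed: ", conditionMessage(e))
        NULL
      })
    if (!is.null(rows)) rows$rep <- r
    rec[[r]] <- rows
    if (verbose) cat("replicate", r, "of", reps, "done\n")
  }
  records <- do.call(rbind, rec)
  if (is.null(records)) stop("all replicates failed")
  for (m in methods) {
    got <- records[records$method == m, ]
    if (nrow(got) == 0) stop("all replicates failed for method cell '", m, "'")
  }
  summary <- aggregate_benchmark(records, tau0)
  structure(list(records = records, summary = summary, tau0 = tau0,
                 design = design, methods = methods,
                 extrapolation = extrapolation, reps = reps, K = K,
                 psi = psi, seed = seed),
            class = "benchmark_result")
}

#' @noRd
run_replicate <- function(design, specs, extrapolation, K, psi,
                          data_seed, grid_seed, n_lambda, compute_ci, B,
                          tau0) {
  ds <- generate_dataset(design, seed = data_seed)
  sample_star <- ds$sample
  sample_true <- observed_sample(sample_star$T, sample_star$Y, ds$X,
                                 sample_star$Z, sample_star$x_names,
                                 sample_star$z_names)
  gamma_true <- ds$truth$gamma
  need_simex <- any(vapply(specs, function(s) s$covariates == "simex", logical(1)))
  grid <- NULL; errors <- NULL; gtil <- list()
  if (need_simex) {
    grid <- simex_grid(diag(design$sigma_e2, design$px), psi = psi, K = K,
                       seed = grid_seed)
    errors <- pseudo_errors(grid, sample_star$n)
    traj <- run_simex(sample_star, grid, design$link, errors = errors)
    for (fam in extrapolation) {
      g <- extrapolate_trajectory(traj, fam)
      attr(g, "fits") <- NULL
      gtil[[fam]] <- g
    }
  }
  pilot_star <- pilot_true <- NULL
  rows <- list()
  for (m in names(specs)) {
    s <- specs[[m]]
    fams <- if (s$covariates == "simex") extrapolation else "none"
    for (fam in fams) {
      if (s$covariates == "simex") {
        pilot <- gtil[[fam]]
        smp <- sample_star
      } else if (s$covariates == "star") {
        pilot_star <- pilot_star %||% fit_treatment_model(sample_star, design$link)$coefficients
        pilot <- pilot_star
        smp <- sample_star
      } else {
        pilot_true <- pilot_true %||% fit_treatment_model(sample_true, design$link)$coefficients
        pilot <- pilot_true
        smp <- sample_true
      }
      if (s$selection == "full") {
        gamma_hat <- pilot
        sel <- NULL
      } else {
        sel <- select_coefficients(pilot, smp$n, penalty = s$selection,
                                   n_lambda = n_lambda)
        gamma_hat <- sel$gamma_hat
      }
      if (s$covariates == "simex") {
        ate <- suppressMessages(
          simex_ate(smp, list(gamma_hat = gamma_hat), grid, design$link,
                    family = fam, errors = errors))
        tau <- ate$tau_hat
      } else {
        tau <- as.numeric(ipw_ate(smp$T, smp$Y,
                                  propensity(gamma_hat, smp, design$link),
                                  warn = FALSE))
      }
      covered <- NA
      if (compute_ci) {
        stub <- structure(list(correct = s$covariates == "simex",
                               select = s$selection != "full",
                               penalty = if (s$selection != "full") s$selection else "scad",
                               grid = grid, family = if (fam == "none") "quadratic" else fam,
                               link = design$link, stabilized = TRUE,
                               refit = FALSE, tau_hat = tau),
                          class = "simexsel_fit")
        bs <- tryCatch(bootstrap_se(smp, stub, B = max(B, 50),
                                    seed = data_seed),
                       error = function(e) NULL)
        if (!is.null(bs)) covered <- tau0 >= bs$ci[1] && tau0 <= bs$ci[2]
      }
      met <- gamma_metrics(gamma_hat, gamma_true)
      rows[[length(rows) + 1]] <-
        data.frame(method = m, extrapolation = fam, tau_hat = tau,
                   l1 = met[["l1"]], l2 = met[["l2"]],
                   n_selected = met[["n_selected"]],
                   n_false_negative = met[["n_false_negative"]],
                   covered = covered)
    }
  }
  do.call(rbind, rows)
}

#' @noRd
aggregate_benchmark <- function(records, tau0) {
  key <- interaction(records$method, records$extrapolation, drop = TRUE)
  out <- do.call(rbind, lapply(split(records, key), function(g) {
    bias <- mean(g$tau_hat) - tau0
    se <- stats::sd(g$tau_hat)
    data.frame(method = g$method[1], extrapolation = g$extrapolation[1],
               reps = nrow(g),
               l1 = mean(g$l1), l2 = mean(g$l2),
               n_selected = mean(g$n_selected),
               n_false_negative = mean(g$n_false_negative),
               bias = bias, se = se, rmse = sqrt(bias^2 + se^2),
               cr = if (all(is.na(g$covered))) NA_real_
                    else 100 * mean(g$covered, na.rm = TRUE))
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("Benchmark:", x$reps, "replicates, K =", x$K,
      ", true ATE =", signif(x$tau0, 4), "\n")
  s <- x$summary
  num <- vapply(s, is.numeric, logical(1))
  s[num] <- lapply(s[num], function(v) round(v, 3))
  print(s)
  invisible(x)
}

#' @export
summary.benchmark_result <- function(object, ...) object$summary
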