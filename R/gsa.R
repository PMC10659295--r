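# Variance-based (Sobol') global sensitivity analysis.
#
# Indices are estimated from two independent sample matrices A and B and
# the column-substituted hybrids AB_j / BA_j. The default estimator is the
# correlation form (Glen & Isaacs): for standardized outputs,
# cor(y(A), y(BA_j)) estimates the first-order index S_j (the two designs
# share only coordinate j) and 1 - cor(y(A), y(AB_j)) estimates the total
# index T_j (they share everything but coordinate j); both directions are
# averaged. A Saltelli/Jansen estimator is available as a cross-check.

#' Estimate first-order and total Sobol' indices
#'
#' @param objective_fn vectorized function: an m x d matrix of points (one
#'   per row, including any dummy coordinate) to an m x n_out matrix of
#'   outcomes (or a vector for a single outcome).
#' @param n base sample count (the function is evaluated at (2 + 2 d) n
#'   points for the correlation estimator).
#' @param lower,upper sampling box (length-d numeric vectors).
#' @param seed RNG seed for the two independent uniform sample sets.
#' @param n_boot bootstrap resamples of the design rows (0 = none).
#' @param estimator \code{"glen_isaacs"} (correlation form, default) or
#'   \code{"saltelli"} (Saltelli first-order / Jansen total).
#' @param dummy_param optional index or name of a dummy coordinate that the
#'   model ignores (negative control); recorded for
#'   \code{\link{dummy_significance_test}}.
#' @return a list of class \code{vacf_gsa}: matrices \code{S} and \code{T}
#'   (d x n_out), bootstrap arrays \code{S_boot}, \code{T_boot}
#'   (d x n_out x n_boot), and metadata.
#' @export
sobol_indices <- function(objective_fn, n, lower, upper, seed = 1,
                          n_boot = 0, estimator = c("glen_isaacs", "saltelli"),
                          dummy_param = NULL) {
  estimator <- match.arg(estimator)
  d <- length(lower)
  stopifnot(length(upper) == d, n >= 8)
  set.seed(seed)
  A <- matrix(runif(n * d, rep(lower, each = n), rep(upper, each = n)), n, d)
  B <- matrix(runif(n * d, rep(lower, each = n), rep(upper, each = n)), n, d)
  as_mat <- function(y) {
    if (is.null(dim(y))) matrix(y, ncol = 1) else as.matrix(y)
  }
  yA <- as_mat(objective_fn(A))
  yB <- as_mat(objective_fn(B))
  n_out <- ncol(yA)
  yAB <- array(NA_real_, c(n, n_out, d))
  yBA <- array(NA_real_, c(n, n_out, d))
  for (j in seq_len(d)) {
    ABj <- A; ABj[, j] <- B[, j]
    yAB[, , j] <- as_mat(objective_fn(ABj))
    if (estimator == "glen_isaacs") {
      BAj <- B; BAj[, j] <- A[, j]
      yBA[, , j] <- as_mat(objective_fn(BAj))
    }
  }
  est <- function(idx) {
    S <- matrix(NA_real_, d, n_out)
    Tm <- matrix(NA_real_, d, n_out)
    for (o in seq_len(n_out)) {
      a <- yA[idx, o]; b <- yB[idx, o]
      for (j in seq_len(d)) {
        ab <- yAB[idx, o, j]
        if (estimator == "glen_isaacs") {
          ba <- yBA[idx, o, j]
          S[j, o] <- 0.5 * (cor_safe(a, ba) + cor_safe(b, ab))
          Tm[j, o] <- 1 - 0.5 * (cor_safe(a, ab) + cor_safe(b, ba))
        } else {
          V <- stats::var(c(a, b))
          S[j, o] <- mean(b * (ab - a)) / V
          Tm[j, o] <- mean((a - ab)^2) / (2 * V)
        }
      }
    }
    list(S = S, T = Tm)
  }
  full <- est(seq_len(n))
  out_names <- colnames(yA)
  dimnames(full$S) <- dimnames(full$T) <- list(NULL, out_names)
  S_boot <- T_boot <- NULL
  if (n_boot > 0) {
    S_boot <- array(NA_real_, c(d, n_out, n_boot))
    T_boot <- array(NA_real_, c(d, n_out, n_boot))
    for (bi in seq_len(n_boot)) {
      e <- est(sample.int(n, n, replace = TRUE))
      S_boot[, , bi] <- e$S
      T_boot[, , bi] <- e$T
    }
  }
  structure(list(S = full$S, T = full$T, S_boot = S_boot, T_boot = T_boot,
                 n = n, n_boot = n_boot, estimator = estimator,
                 dummy_param = dummy_param, seed = seed,
                 lower = lower, upper = upper),
            class = "vacf_gsa")
}

# Pearson correlation that returns 0 for degenerate (zero-variance) inputs.
cor_safe <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

#' Rank-sum significance of sensitivity indices against the dummy control
#'
#' For each (parameter, outcome) cell, compares the bootstrap distribution
#' of the index with the pooled bootstrap distribution of the dummy
#' parameter's indices (the negative control for true insensitivity) by a
#' two-sided Wilcoxon rank-sum test. Cells with p below \code{alpha} carry
#' a statistically significant sensitivity at the given sampling level.
#'
#' @param result a \code{vacf_gsa} with bootstrap distributions and a
#'   \code{dummy_param}.
#' @param which \code{"total"} (default) or \code{"first_order"}.
#' @param alpha significance level for flagging (default 0.05).
#' @return a list with matrices \code{p_values} and \code{significant}.
#' @export
dummy_significance_test <- function(result, which = c("total", "first_order"),
                                    alpha = 0.05) {
  which <- match.arg(which)
  if (is.null(result$S_boot)) {
    stop("run sobol_indices with n_boot > 0 first")
  }
  if (is.null(result$dummy_param)) {
    stop("the gsa result has no dummy_param recorded")
  }
  boot <- if (which == "total") result$T_boot else result$S_boot
  dj <- result$dummy_param
  if (is.character(dj)) dj <- match(dj, rownames(result$S))
  control <- as.numeric(boot[dj, , ])
  d <- dim(boot)[1]; n_out <- dim(boot)[2]
  p <- matrix(NA_real_, d, n_out, dimnames = dimnames(result$S))
  for (j in seq_len(d)) {
    for (o in seq_len(n_out)) {
      p[j, o] <- suppressWarnings(
        stats::wilcox.test(boot[j, o, ], control, exact = FALSE)$p.value)
    }
  }
  list(p_values = p, significant = p < alpha, alpha = alpha, which = which)
}

#' Model objective function for sensitivity analysis
#'
#' Returns a vectorized outcome function over the 8 model parameters plus an
#' appended 9th dummy coordinate: the five rectified-linear objectives plus
#' a dummy outcome equal to one chosen kinetic parameter (log10), giving the
#' positive control with total index 1 for that parameter and true
#' insensitivity elsewhere.
#'
#' @param cfg a \code{\link{model_config}}.
#' @param dummy_outcome_param name of the parameter copied into the dummy
#'   outcome (default \code{"K1"}).
#' @return function mapping an m x 9 matrix to an m x 6 outcome matrix.
#' @export
model_objective_fn <- function(cfg = model_config(),
                               dummy_outcome_param = "K1") {
  oi <- match(dummy_outcome_param, param_names())
  if (is.na(oi)) stop("unknown parameter: ", dummy_outcome_param)
  function(x) {
    x <- as.matrix(x)
    stopifnot(ncol(x) == 9)
    rep_df <- evaluate_criteria_batch(x[, 1:8, drop = FALSE], cfg = cfg)
    out <- cbind(as.matrix(rep_df[, paste0("O", 1:5)]), dummy = x[, oi])
    out
  }
}
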