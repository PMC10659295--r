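# Posterior interrogation: credible intervals, histograms, steady-state
# composition surveys, and replicate reproducibility tests.

#' Weighted quantile (inverse empirical CDF)
#'
#' The quantile at probability p is the smallest sample value whose
#' cumulative normalized weight reaches p. With equal weights this matches
#' \code{stats::quantile(type = 1)}, and it agrees exactly with brute-force
#' expansion of rational weights into replicated samples.
#'
#' @param x numeric values.
#' @param w non-negative weights (default equal).
#' @param probs probabilities in [0, 1].
#' @return numeric vector of quantiles.
#' @export
weighted_quantile <- function(x, w = NULL, probs = 0.5) {
  if (!length(x)) stop("empty sample")
  if (is.null(w)) w <- rep(1, length(x))
  stopifnot(length(w) == length(x), all(w >= 0), sum(w) > 0,
            all(probs >= 0 & probs <= 1))
  keep <- is.finite(x)
  x <- x[keep]; w <- w[keep]
  if (!length(x)) return(rep(NA_real_, length(probs)))
  o <- order(x)
  x <- x[o]
  cw <- cumsum(w[o]) / sum(w)
  vapply(probs, function(p) {
    if (p <= 0) return(x[1L])
    x[which(cw >= p - 1e-12)[1L]]
  }, numeric(1))
}

#' Per-parameter credible intervals of a population
#'
#' Weighted equal-tailed quantile intervals in log10 space.
#'
#' @param population an ABC population (or any list with \code{theta} matrix
#'   and \code{weights}).
#' @param level credible level (default 0.95).
#' @param weighted use the importance weights (default TRUE); FALSE treats
#'   particles as an unweighted sample.
#' @return a matrix with one row per parameter and columns \code{lower},
#'   \code{median}, \code{upper}.
#' @export
credible_intervals <- function(population, level = 0.95, weighted = TRUE) {
  theta <- population$theta
  if (is.null(theta) || !nrow(theta)) stop("empty population")
  w <- if (weighted) population$weights else rep(1, nrow(theta))
  a <- (1 - level) / 2
  out <- t(apply(theta, 2L, weighted_quantile, w = w,
                 probs = c(a, 0.5, 1 - a)))
  colnames(out) <- c("lower", "median", "upper")
  out
}

#' Survey steady-state membrane composition across a population
#'
#' Recomputes the pre-perturbation steady state for every particle and
#' summarizes how the machinery is partitioned there: the free-HOPS fraction
#' H/(H+C) and ratio H/C (both reported), the fraction of SNAREs locked in
#' HOPS:trans-SNARE super-complexes 4C/(S + 4(T+C+Y)), and the total
#' membrane Sec17 to total membrane HOPS ratio (X+Y)/(H+C).
#'
#' @param population an ABC population.
#' @param cfg a \code{\link{model_config}}.
#' @param level credible level for the interval summaries (default 0.95).
#' @param weighted use importance weights in the summaries (default TRUE).
#' @return a list with \code{per_particle} (data.frame), \code{summary}
#'   (matrix metric x (lower, median, upper)), \code{n_failed} (particles
#'   excluded for failed steady-state recomputation), \code{n_nonfinite}
#'   (per-metric non-finite values excluded from summaries).
#' @export
steady_state_survey <- function(population, cfg = model_config(),
                                level = 0.95, weighted = TRUE) {
  theta <- population$theta
  n <- nrow(theta)
  w <- if (weighted) population$weights else rep(1, n)
  rows <- lapply(seq_len(n), function(i) {
    ss <- find_steady_state(theta[i, ], cfg = cfg)
    if (!ss$solver_ok) return(NULL)
    st <- ss$state
    tot <- snare_total(st)
    data.frame(
      free_hops_fraction = st[["H"]] / (st[["H"]] + st[["C"]]),
      free_hops_ratio = st[["H"]] / st[["C"]],
      snare_supercomplex_fraction = if (tot > 0) 4 * st[["C"]] / tot else 0,
      snare_free_fraction = if (tot > 0) st[["S"]] / tot else 0,
      snare_trans_fraction = if (tot > 0) 4 * st[["T"]] / tot else 0,
      snare_sec17_fraction = if (tot > 0) 4 * st[["Y"]] / tot else 0,
      sec17_to_hops = (st[["X"]] + st[["Y"]]) / (st[["H"]] + st[["C"]]),
      weight = w[i])
  })
  ok <- !vapply(rows, is.null, logical(1))
  per <- do.call(rbind, rows[ok])
  if (is.null(per) || !nrow(per)) stop("no particle produced a steady state")
  a <- (1 - level) / 2
  metrics <- setdiff(names(per), "weight")
  summ <- t(vapply(metrics, function(m) {
    weighted_quantile(per[[m]], per$weight, probs = c(a, 0.5, 1 - a))
  }, numeric(3)))
  colnames(summ) <- c("lower", "median", "upper")
  nonfin <- vapply(metrics, function(m) sum(!is.finite(per[[m]])), integer(1))
  list(per_particle = per, summary = summ,
       n_failed = sum(!ok), n_nonfinite = nonfin)
}

# Deterministic weight-flattening: read m equally spaced quantiles off the
# weighted marginal, turning a weighted sample into an unweighted one.
flatten_weights <- function(x, w, m = length(x)) {
  weighted_quantile(x, w, probs = (seq_len(m) - 0.5) / m)
}

#' Replicate reproducibility: two-sample KS tests on paired marginals
#'
#' The replicate-reproducibility check for two independent ABC runs:
#' per parameter, a two-sample Kolmogorov-Smirnov test on the two final
#' marginal distributions. Weighted populations are first flattened into
#' equal-weight samples via their weighted quantile functions.
#'
#' @param population_a,population_b final populations over the same
#'   parameterization.
#' @param alpha significance level (default 0.05).
#' @param weighted flatten by importance weight (default TRUE).
#' @return a data.frame with one row per parameter: \code{statistic} (KS D),
#'   \code{p_value}, \code{reject}.
#' @export
replicate_ks_test <- function(population_a, population_b, alpha = 0.05,
                              weighted = TRUE) {
  ta <- population_a$theta; tb <- population_b$theta
  if (ncol(ta) != ncol(tb) ||
      !identical(colnames(ta), colnames(tb))) {
    stop("populations have mismatched parameterizations")
  }
  wa <- if (weighted) population_a$weights else rep(1, nrow(ta))
  wb <- if (weighted) population_b$weights else rep(1, nrow(tb))
  res <- lapply(seq_len(ncol(ta)), function(j) {
    xa <- flatten_weights(ta[, j], wa)
    xb <- flatten_weights(tb[, j], wb)
    kt <- suppressWarnings(stats::ks.test(xa, xb, exact = FALSE))
    data.frame(parameter = colnames(ta)[j],
               statistic = unname(kt$statistic),
               p_value = kt$p.value,
               reject = kt$p.value < alpha)
  })
  do.call(rbind, res)
}

#' Weighted 2D histogram of two parameters
#'
#' @param population an ABC population.
#' @param param_x,param_y parameter names (among \code{param_names()}).
#' @param bins number of bins per axis (default 50).
#' @param lower,upper axis limits; default the prior box bounds for the two
#'   parameters.
#' @return a list with \code{x_breaks}, \code{y_breaks}, \code{x_mids},
#'   \code{y_mids}, and \code{density} (bins x bins matrix of normalized
#'   weights summing to 1).
#' @export
histogram2d <- function(population, param_x, param_y, bins = 50,
                        lower = NULL, upper = NULL) {
  theta <- population$theta
  nm <- colnames(theta)
  if (!(param_x %in% nm) || !(param_y %in% nm)) {
    stop("unknown parameter name(s): ", param_x, ", ", param_y)
  }
  box <- prior_box()
  if (is.null(lower)) lower <- c(box$lower[[param_x]], box$lower[[param_y]])
  if (is.null(upper)) upper <- c(box$upper[[param_x]], box$upper[[param_y]])
  xb <- seq(lower[1], upper[1], length.out = bins + 1L)
  yb <- seq(lower[2], upper[2], length.out = bins + 1L)
  ix <- findInterval(theta[, param_x], xb, rightmost.closed = TRUE,
                     all.inside = TRUE)
  iy <- findInterval(theta[, param_y], yb, rightmost.closed = TRUE,
                     all.inside = TRUE)
  dens <- matrix(0, bins, bins)
  w <- population$weights / sum(population$weights)
  for (i in seq_along(ix)) {
    dens[ix[i], iy[i]] <- dens[ix[i], iy[i]] + w[i]
  }
  list(x_breaks = xb, y_breaks = yb,
       x_mids = (xb[-1L] + xb[-length(xb)]) / 2,
       y_mids = (yb[-1L] + yb[-length(yb)]) / 2,
       density = dens)
}
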