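# The five satisficing criteria, ReLU objectives and summary statistic.
#
# Qualitative phenotypes of guard-cell vacuoles are encoded as inequality
# constraints on simulation outcomes:
#   CR1  stable pre-perturbation steady state: max |d/dt| <= 1e-8
#   CR2  PI3P depletion induces >= 10x fusion:  I_base / I_depl   <= 0.1
#   CR3  trigger activation induces >= 10x fusion: I_base / I_trig <= 0.1
#   CR4  depletion-driven fusion >= 10x trigger-driven: I_trig / I_depl <= 0.1
#   CR5  spontaneous fusion rare: steady-state Y <= 1e-6
# where I_* are cumulative fusion activities over the common window.
# Each criterion is scored by a rectified linear objective that is zero at
# or below threshold and grows linearly above it; the summary statistic is
# the sum of the five objectives, so zero means all criteria are met.

#' Criterion thresholds
#' @return named numeric vector of the five acceptance thresholds.
#' @export
criteria_thresholds <- function() {
  c(CR1 = 1e-8, CR2 = 0.1, CR3 = 0.1, CR4 = 0.1, CR5 = 1e-6)
}

#' Rectified linear objective
#'
#' \code{max(0, (cr - th)/th)}: zero for any outcome meeting the threshold,
#' growing linearly with relative exceedance otherwise. Non-finite criterion
#' values map to \code{Inf} (failure), never to acceptance.
#'
#' @param cr measured criterion value (finite, \code{NaN} or \code{Inf}).
#' @param th positive threshold.
#' @return non-negative objective value.
#' @examples
#' relu_objective(0.1, 0.1)  # 0: meets threshold
#' relu_objective(0.2, 0.1)  # 1: twice the threshold
#' @export
relu_objective <- function(cr, th) {
  if (!is.numeric(th) || any(th <= 0) || anyNA(th)) {
    stop("threshold must be positive")
  }
  out <- pmax(0, (cr - th) / th)
  out[!is.finite(cr) | is.nan(cr)] <- Inf
  out
}

# Ratio with the zero-denominator convention used by CR2-CR4: a zero
# denominator means no fusion was induced, which must read as failure, so
# the ratio is +Inf (including the 0/0 case).
safe_ratio <- function(num, den) {
  if (is.na(num) || is.na(den)) return(NaN)
  if (den == 0) return(Inf)
  num / den
}

#' Evaluate the five satisficing criteria for one parameter set
#'
#' Relaxes to the pre-perturbation steady state once, runs the three
#' scenarios from it over the common window, and scores the five criteria.
#' This path is deterministic: repeated evaluation of the same parameters
#' and configuration is bit-identical.
#'
#' @param params a \code{\link{vacf_params}} set (log10 scale).
#' @param cfg a \code{\link{model_config}}.
#' @param dense keep dense scenario trajectories (slower; default FALSE).
#' @return a list of class \code{vacf_criteria} with fields
#'   \code{cr_values}, \code{thresholds}, \code{objectives},
#'   \code{summary_statistic}, \code{pass}, \code{all_pass},
#'   \code{fusion_integrals} and \code{steady_state}.
#' @export
evaluate_criteria <- function(params, cfg = model_config(), dense = FALSE) {
  validate_params(params)
  steady <- find_steady_state(params, cfg = cfg)
  scen <- lapply(scenario_names(), run_scenario, params = params, cfg = cfg,
                 steady = steady, dense = dense)
  names(scen) <- scenario_names()
  ii <- vapply(scen, `[[`, numeric(1), "fusion_integral")
  cr <- c(CR1 = steady$max_abs_deriv,
          CR2 = safe_ratio(ii[["baseline"]], ii[["pi3p_depletion"]]),
          CR3 = safe_ratio(ii[["baseline"]], ii[["trigger_activation"]]),
          CR4 = safe_ratio(ii[["trigger_activation"]], ii[["pi3p_depletion"]]),
          CR5 = unname(steady$state[["Y"]]))
  th <- criteria_thresholds()
  obj <- stats::setNames(relu_objective(cr, th), paste0("O", 1:5))
  pass <- stats::setNames(obj == 0, names(cr))
  res <- list(cr_values = cr, thresholds = th, objectives = obj,
              summary_statistic = sum(obj),
              pass = pass, all_pass = all(pass),
              fusion_integrals = ii, steady_state = steady$state)
  structure(res, class = "vacf_criteria")
}

#' Evaluate criteria for a batch of parameter sets
#'
#' Per-set evaluation is pure (no shared state), so results are independent
#' of ordering or partitioning of the batch.
#'
#' @param theta an n x 8 matrix of log10 parameter sets (columns
#'   \code{param_names()}) or a single set.
#' @param cfg a \code{\link{model_config}}.
#' @return a data.frame with one row per set: the eight parameters, CR1-CR5,
#'   O1-O5, \code{summary_statistic}, pass flags and \code{all_pass}.
#' @export
evaluate_criteria_batch <- function(theta, cfg = model_config()) {
  m <- as_param_matrix(theta)
  rows <- lapply(seq_len(nrow(m)), function(i) {
    r <- evaluate_criteria(m[i, ], cfg = cfg)
    c(m[i, ], r$cr_values, r$objectives,
      summary_statistic = r$summary_statistic,
      stats::setNames(as.numeric(r$pass), paste0("pass_", names(r$pass))),
      all_pass = as.numeric(r$all_pass))
  })
  out <- as.data.frame(do.call(rbind, rows))
  out
}

#' @export
print.vacf_criteria <- function(x, ...) {
  cat("Satisficing criteria report\n")
  for (i in 1:5) {
    cat(sprintf("  %s = %-12.4g (threshold %-8.2g) O%d = %-10.4g %s\n",
                names(x$cr_values)[i], x$cr_values[[i]], x$thresholds[[i]],
                i, x$objectives[[i]], if (x$pass[[i]]) "pass" else "FAIL"))
  }
  cat(sprintf("  summary statistic = %.6g (%s)\n", x$summary_statistic,
              if (x$all_pass) "all criteria met" else "not satisficing"))
  invisible(x)
}
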