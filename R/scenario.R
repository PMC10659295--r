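# Perturbation scenarios and cumulative fusion activity.

scenario_names <- function() c("baseline", "pi3p_depletion", "trigger_activation")

scenario_to_flags <- function(scenario) {
  switch(scenario,
         baseline = scenario_flags(),
         pi3p_depletion = scenario_flags(pi3p_present = FALSE),
         trigger_activation = scenario_flags(signal_active = TRUE),
         stop("unknown scenario: ", scenario))
}

#' Run one perturbation scenario
#'
#' Relaxes the unperturbed cell (PI3P on, signal off) to its steady state,
#' then flips the scenario's Boolean perturbation at t = 0 and integrates
#' over the common window [0, window_T]: \code{baseline} leaves the flags
#' unchanged, \code{pi3p_depletion} removes PI3P (the wortmannin analogue),
#' \code{trigger_activation} switches the fusion-licensing signal on (the
#' fusicoccin analogue). Cumulative fusion activity is the integral of the
#' fusion-competent species Y over the window, accumulated by the solver
#' itself as an auxiliary state (so it carries solver-level accuracy).
#'
#' @param params a \code{\link{vacf_params}} set.
#' @param scenario one of \code{"baseline"}, \code{"pi3p_depletion"},
#'   \code{"trigger_activation"}.
#' @param cfg a \code{\link{model_config}}.
#' @param steady optional precomputed result of
#'   \code{\link{find_steady_state}} (reused across scenarios).
#' @param dense if \code{TRUE} (default) the trajectory is reported on
#'   \code{cfg$n_out} output times; if \code{FALSE} only the endpoints are
#'   kept (cheapest path for large screens).
#' @return a list of class \code{vacf_scenario} with fields \code{scenario},
#'   \code{steady_state}, \code{steady_state_ok}, \code{max_abs_deriv},
#'   \code{times}, \code{states} (matrix with columns H,T,S,Y,C,X),
#'   \code{fusion_flux} (= Y), and \code{fusion_integral}.
#' @export
run_scenario <- function(params, scenario = "baseline", cfg = model_config(),
                         steady = NULL, dense = TRUE) {
  scenario <- match.arg(scenario, scenario_names())
  if (is.null(steady)) steady <- find_steady_state(params, cfg = cfg)
  flags <- scenario_to_flags(scenario)
  times <- if (dense) {
    seq(0, cfg$window_T, length.out = max(2L, cfg$n_out))
  } else {
    c(0, cfg$window_T)
  }
  y0 <- c(steady$state, FI = 0)
  out <- if (steady$solver_ok) {
    integrate_window(y0, times, params, flags, cfg)
  } else {
    NULL
  }
  if (is.null(out)) {
    res <- list(scenario = scenario, steady_state = steady$state,
                steady_state_ok = FALSE,
                max_abs_deriv = steady$max_abs_deriv,
                times = numeric(0), states = NULL, fusion_flux = numeric(0),
                fusion_integral = NA_real_)
    return(structure(res, class = "vacf_scenario"))
  }
  states <- out[, 2:7, drop = FALSE]
  colnames(states) <- state_names()
  res <- list(scenario = scenario, steady_state = steady$state,
              steady_state_ok = steady$converged,
              max_abs_deriv = steady$max_abs_deriv,
              times = out[, 1L], states = states,
              fusion_flux = states[, "Y"],
              fusion_integral = unname(out[nrow(out), "FI"]))
  structure(res, class = "vacf_scenario")
}

#' Cumulative fusion activity of a stored trajectory
#'
#' Trapezoidal integral of the fusion flux Y over a trajectory, for use on
#' exported/dense trajectories. (Scenario runs also accumulate the integral
#' inside the solver; the two agree to quadrature error on a dense grid.)
#'
#' @param times monotone non-decreasing time grid.
#' @param y fusion flux at those times (or a \code{vacf_scenario} object in
#'   place of \code{times}).
#' @return non-negative scalar integral.
#' @export
fusion_integral <- function(times, y = NULL) {
  if (inherits(times, "vacf_scenario")) {
    y <- times$fusion_flux
    times <- times$times
  }
  if (length(times) < 2 || length(times) != length(y)) {
    stop("need at least two (time, flux) pairs")
  }
  if (is.unsorted(times)) stop("time grid must be monotone")
  pracma::trapz(times, y)
}

#' Export a scenario trajectory as CSV
#'
#' Writes time, the six species, and the fusion flux, one row per output time.
#' @param res a \code{vacf_scenario}.
#' @param path file path.
#' @export
write_trajectory_csv <- function(res, path) {
  stopifnot(inherits(res, "vacf_scenario"))
  df <- data.frame(time = res$times, res$states,
                   fusion_flux = res$fusion_flux, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
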