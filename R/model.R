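# ODE right-hand side and steady-state relaxation.
#
# The model tracks six membrane species in dimensionless concentration
# units (the HOPS recruitment/turnover scale): H (HOPS), T (trans-SNARE
# complexes), S (free SNAREs), Y (Sec17-bound trans-SNARE, the
# fusion-competent species), C (HOPS:trans-SNARE super-complexes) and X
# (membrane Sec17). Four SNAREs enter each complex, so
# S + 4 (T + C + Y) is conserved. Fusion proceeds at rate Y (the fusion
# rate constant is the time scale), and fused complexes return their
# SNAREs to the free pool.

state_names <- function() c("H", "T", "S", "Y", "C", "X")

#' Evaluate the model right-hand side
#'
#' Pure-R, term-by-term evaluation of the six coupled ODEs. The compiled
#' derivative used by the solver implements the same algebra; the two are
#' cross-checked in the test suite.
#'
#' @param state named numeric vector (H, T, S, Y, C, X), non-negative.
#' @param params a \code{\link{vacf_params}} set (log10 scale).
#' @param flags a \code{\link{scenario_flags}} object.
#' @return named numeric vector of time derivatives for the six species.
#' @examples
#' rhs(c(H = 0, T = 0, S = 1, Y = 0, C = 0, X = 0), vacf_params())
#' @export
rhs <- function(state, params, flags = scenario_flags()) {
  if (length(state) < 6 || anyNA(state) || any(!is.finite(state[1:6]))) {
    stop("state must be 6 finite numeric values")
  }
  validate_params(params)
  K <- linear_rates(params)
  H <- state[[1]]; T_ <- state[[2]]; S <- state[[3]]
  Y <- state[[4]]; C <- state[[5]]; X <- state[[6]]
  pi3p <- as.numeric(flags$pi3p_present)
  sig <- as.numeric(flags$signal_active)
  hc <- as.numeric(flags$hops_cytosol_present)
  xc <- as.numeric(flags$sec17_cytosol_present)
  S4 <- max(S, 0)^4
  c(H = K[["K1"]] * pi3p * hc + K[["K4"]] * C - K[["K5"]] * H * T_ -
        K[["K3"]] * H * S4 - K[["K1"]] * H,
    T = K[["K4"]] * C - K[["K5"]] * H * T_ - K[["K9"]] * X * T_,
    S = 4 * Y - 4 * K[["K3"]] * H * S4,
    Y = K[["K9"]] * X * T_ + K[["K8"]] * X * C * sig - Y,
    C = K[["K3"]] * H * S4 + K[["K5"]] * H * T_ - K[["K4"]] * C -
        K[["K8"]] * X * C * sig,
    X = K[["K6"]] * xc - K[["K7"]] * X - K[["K8"]] * X * C * sig -
        K[["K9"]] * X * T_)
}

# Compiled right-hand side (same algebra as rhs(), in C); returns 7 values,
# the 7th being the cumulative-fusion auxiliary dY/dt = Y.
rhs_compiled <- function(state, params, flags = scenario_flags()) {
  p <- solver_parms(params, flags)
  d <- .Call(C_fusion_rhs, as.numeric(state), as.numeric(p))
  stats::setNames(d, c(state_names(), "FI"))
}

#' Conserved SNARE total of a state
#'
#' @param state state vector or trajectory matrix with columns H,T,S,Y,C,X.
#' @return S + 4 (T + C + Y).
#' @export
snare_total <- function(state) {
  if (is.matrix(state)) {
    state[, "S"] + 4 * (state[, "T"] + state[, "C"] + state[, "Y"])
  } else {
    state[["S"]] + 4 * (state[["T"]] + state[["C"]] + state[["Y"]])
  }
}

# One stiff integration over explicit output times. Returns the deSolve
# matrix, or NULL on solver failure. The 7th state accumulates the fusion
# integral.
integrate_window <- function(y0, times, params, flags, cfg) {
  p <- solver_parms(params, flags)
  # capture.output: DLSODA prints step-size-collapse diagnostics straight to
  # the console on the (expected) pathological corners of the prior box
  tmp <- capture.output(
    out <- try(suppressWarnings(
      deSolve::lsoda(y = y0, times = times, func = "fusion_deriv",
                     parms = p, dllname = "vacfusion",
                     initfunc = "fusion_init",
                     rtol = cfg$rtol, atol = cfg$atol, maxsteps = 20000)
    ), silent = TRUE)
  )
  if (inherits(out, "try-error")) return(NULL)
  if (anyNA(out) || any(!is.finite(out))) return(NULL)
  # lsoda returns early (with a warning) if it could not reach the end
  if (nrow(out) < length(times)) return(NULL)
  out
}

new_state <- function(cfg) {
  c(H = 0, T = 0, S = cfg$s_total_init, Y = 0, C = 0, X = 0, FI = 0)
}

#' Relax the system to its pre-perturbation steady state
#'
#' Starting from an empty membrane plus a free-SNARE pool of size
#' \code{cfg$s_total_init}, integrates the unperturbed system (PI3P present,
#' signal off) over geometrically doubling windows until the largest species
#' derivative drops to \code{cfg$deriv_tol} or the horizon
#' \code{cfg$relax_t_max} is exhausted. Steady-state detection follows the
#' trajectory, so slow transients and failures are reported rather than
#' hidden: the caller decides pass/fail from \code{max_abs_deriv}.
#'
#' @param params a \code{\link{vacf_params}} set.
#' @param flags flags for the relaxation (default: unperturbed cell).
#' @param cfg a \code{\link{model_config}}.
#' @return a list with \code{state} (named 6-vector), \code{max_abs_deriv},
#'   \code{converged}, \code{t_end}, and \code{solver_ok}.
#' @export
find_steady_state <- function(params, flags = scenario_flags(),
                              cfg = model_config()) {
  n_win <- ceiling(log2(cfg$relax_t_max / cfg$relax_t0)) + 1L
  ends <- pmin(cfg$relax_t0 * 2^(seq_len(n_win) - 1L), cfg$relax_t_max)
  ends <- unique(ends)
  y <- new_state(cfg)
  t_prev <- 0
  maxd <- Inf
  solver_ok <- TRUE
  for (te in ends) {
    out <- integrate_window(y, c(t_prev, te), params, flags, cfg)
    if (is.null(out)) {
      solver_ok <- FALSE
      break
    }
    y <- out[nrow(out), -1L]
    t_prev <- te
    maxd <- max(abs(rhs_compiled(y[1:6], params, flags)[1:6]))
    if (maxd <= cfg$deriv_tol) break
  }
  state <- stats::setNames(as.numeric(y[1:6]), state_names())
  list(state = state, max_abs_deriv = maxd,
       converged = is.finite(maxd) && maxd <= cfg$deriv_tol,
       t_end = t_prev, solver_ok = solver_ok)
}
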