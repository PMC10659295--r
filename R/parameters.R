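# Parameter sets, scenario flags and run configuration.

#' Names of the eight dimensionless model parameters
#'
#' The model is parameterized by eight dimensionless rate constants, stored
#' and sampled as log10 values: K1 (HOPS recruitment and turnover), K3
#' (SNARE chaperoning), K4 (super-complex dissociation), alpha = K5/K4
#' (HOPS/trans-SNARE reassociation relative to dissociation), K6 (Sec17
#' recruitment), K7 (Sec17 turnover), beta = K8/K9 (signal-gated HOPS
#' displacement relative to spontaneous Sec17 association), and K9 (Sec17
#' association with bare trans-SNARE complexes). The fusion rate constant
#' K10 is the time scale and is identically 1.
#'
#' @export
param_names <- function() {
  c("K1", "K3", "K4", "alpha", "K6", "K7", "beta", "K9")
}

#' Prior box for the dimensionless parameters (log10)
#'
#' Every parameter is allowed four orders of magnitude above and below the
#' fusion rate reference of 1, i.e. log10 values in [-4, 4].
#'
#' @return a list with numeric vectors \code{lower} and \code{upper}.
#' @export
prior_box <- function() {
  nm <- param_names()
  list(lower = stats::setNames(rep(-4, 8), nm),
       upper = stats::setNames(rep(4, 8), nm))
}

#' Construct a parameter set (log10 scale)
#'
#' @param K1,K3,K4,alpha,K6,K7,beta,K9 log10 values of the dimensionless
#'   constants. Defaults of 0 give all rate constants equal to the fusion
#'   rate.
#' @return a named numeric vector of class \code{vacf_params}.
#' @export
vacf_params <- function(K1 = 0, K3 = 0, K4 = 0, alpha = 0,
                        K6 = 0, K7 = 0, beta = 0, K9 = 0) {
  theta <- c(K1 = K1, K3 = K3, K4 = K4, alpha = alpha,
             K6 = K6, K7 = K7, beta = beta, K9 = K9)
  validate_params(theta)
  structure(theta, class = "vacf_params")
}

validate_params <- function(theta) {
  if (length(theta) != 8 || !is.numeric(theta) || anyNA(theta) ||
      any(!is.finite(theta))) {
    stop("parameter set must be 8 finite numeric log10 values")
  }
  invisible(theta)
}

#' Is a parameter set inside the prior box?
#' @param theta log10 parameter vector or matrix (one row per set).
#' @return logical vector.
#' @export
in_prior_box <- function(theta) {
  box <- prior_box()
  if (is.matrix(theta)) {
    apply(theta, 1L, function(r) all(r >= box$lower & r <= box$upper))
  } else {
    all(theta >= box$lower & theta <= box$upper)
  }
}

# Linear-scale rate constants K1,K3,K4,K5,K6,K7,K8,K9 from a log10 set.
# K5 = alpha * K4 and K8 = beta * K9 are derived on demand.
linear_rates <- function(theta) {
  k <- 10^unclass(theta)
  c(K1 = unname(k[1]), K3 = unname(k[2]), K4 = unname(k[3]),
    K5 = unname(k[4] * k[3]), K6 = unname(k[5]), K7 = unname(k[6]),
    K8 = unname(k[7] * k[8]), K9 = unname(k[8]))
}

#' Non-dimensionalize dimensional rate constants
#'
#' Reduces the nine dimensional rate constants k1..k10 to the eight
#' dimensionless groups using the concentration scale k1/k2 and time scale
#' 1/k10: K1 = k2/k10, K3 = k3*k1^4/(k10*k2^4), K4 = k4/k10,
#' K5 = k1*k5/(k2*k10), K6 = k6/k10, K7 = k7/k10, K8 = k1*k8/(k2*k10),
#' K9 = k1*k9/(k2*k10). K5 and K8 are returned through the ratios
#' alpha = K5/K4 and beta = K8/K9.
#'
#' @param k named numeric vector with entries k1..k10, all strictly positive.
#' @return a \code{\link{vacf_params}} object (log10 scale).
#' @examples
#' nondimensionalize(stats::setNames(rep(1, 10), paste0("k", 1:10)))
#' @export
nondimensionalize <- function(k) {
  need <- paste0("k", 1:10)
  if (!all(need %in% names(k))) {
    stop("k must contain named entries k1..k10")
  }
  k <- k[need]
  if (any(!is.finite(k)) || any(k <= 0)) {
    stop("all rate constants must be finite and strictly positive")
  }
  K1 <- k[["k2"]] / k[["k10"]]
  K3 <- k[["k3"]] * k[["k1"]]^4 / (k[["k10"]] * k[["k2"]]^4)
  K4 <- k[["k4"]] / k[["k10"]]
  K5 <- k[["k1"]] * k[["k5"]] / (k[["k2"]] * k[["k10"]])
  K6 <- k[["k6"]] / k[["k10"]]
  K7 <- k[["k7"]] / k[["k10"]]
  K8 <- k[["k1"]] * k[["k8"]] / (k[["k2"]] * k[["k10"]])
  K9 <- k[["k1"]] * k[["k9"]] / (k[["k2"]] * k[["k10"]])
  vacf_params(K1 = log10(K1), K3 = log10(K3), K4 = log10(K4),
              alpha = log10(K5 / K4), K6 = log10(K6), K7 = log10(K7),
              beta = log10(K8 / K9), K9 = log10(K9))
}

#' Boolean scenario flags
#'
#' The model gates four processes on Boolean presence variables: the
#' membrane lipid PI3P (required for HOPS recruitment), the upstream
#' biological signal that licenses Sec17 to displace HOPS, and the
#' cytosolic HOPS and Sec17 pools. Defaults reproduce the unperturbed
#' cell: PI3P present, no signal, both cytosolic pools available.
#'
#' @param pi3p_present,signal_active,hops_cytosol_present,sec17_cytosol_present
#'   logical scalars.
#' @return a list of class \code{vacf_flags}.
#' @export
scenario_flags <- function(pi3p_present = TRUE, signal_active = FALSE,
                           hops_cytosol_present = TRUE,
                           sec17_cytosol_present = TRUE) {
  fl <- list(pi3p_present = isTRUE(pi3p_present),
             signal_active = isTRUE(signal_active),
             hops_cytosol_present = isTRUE(hops_cytosol_present),
             sec17_cytosol_present = isTRUE(sec17_cytosol_present))
  structure(fl, class = "vacf_flags")
}

#' Simulation configuration
#'
#' @param s_total_init initial free-SNARE pool (dimensionless); the conserved
#'   SNARE total of every run.
#' @param relax_t_max maximum relaxation time when searching for the
#'   pre-perturbation steady state.
#' @param relax_t0 first relaxation window end; windows double up to
#'   \code{relax_t_max}.
#' @param deriv_tol steady-state criterion: max over species of |d/dt| must
#'   fall at or below this value.
#' @param window_T post-perturbation integration horizon, identical for all
#'   scenarios so cumulative fusion activities are comparable.
#' @param rtol,atol solver relative/absolute tolerances (stiff integrator).
#' @param n_out number of output times for dense scenario trajectories.
#' @return a list of class \code{vacf_config}.
#' @export
model_config <- function(s_total_init = 1, relax_t_max = 1e6, relax_t0 = 1,
                         deriv_tol = 1e-8, window_T = 100,
                         rtol = 1e-8, atol = 1e-12, n_out = 101) {
  cfg <- list(s_total_init = s_total_init, relax_t_max = relax_t_max,
              relax_t0 = relax_t0, deriv_tol = deriv_tol,
              window_T = window_T, rtol = rtol, atol = atol, n_out = n_out)
  if (any(!vapply(cfg, function(v) is.numeric(v) && length(v) == 1 &&
                    is.finite(v) && v >= 0, logical(1)))) {
    stop("all configuration fields must be non-negative finite scalars")
  }
  if (any(unlist(cfg[c("relax_t_max", "relax_t0", "deriv_tol", "window_T",
                       "rtol", "atol", "n_out")]) <= 0)) {
    stop("all configuration fields except s_total_init must be positive")
  }
  structure(cfg, class = "vacf_config")
}

# 12-element parameter vector handed to the compiled derivative:
# linear rates followed by the Boolean gates as 0/1.
solver_parms <- function(theta, flags) {
  c(linear_rates(theta),
    pi3p = as.numeric(flags$pi3p_present),
    sig = as.numeric(flags$signal_active),
    hc = as.numeric(flags$hops_cytosol_present),
    xc = as.numeric(flags$sec17_cytosol_present))
}

#' Read / write parameter sets as CSV
#'
#' Parameter tables use one row per set with the log10 columns
#' \code{K1, K3, K4, alpha, K6, K7, beta, K9}.
#'
#' @param theta a parameter matrix (or single set) to write.
#' @param path file path.
#' @return \code{read_params_csv} returns a numeric matrix with the eight
#'   named columns; \code{write_params_csv} returns \code{path} invisibly.
#' @export
write_params_csv <- function(theta, path) {
  m <- as_param_matrix(theta)
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_params_csv
#' @export
read_params_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  nm <- param_names()
  if (!all(nm %in% names(df))) {
    stop("parameter CSV must contain columns ", paste(nm, collapse = ", "))
  }
  as.matrix(df[, nm, drop = FALSE])
}

# Coerce a single set or matrix to an n x 8 matrix with canonical columns.
as_param_matrix <- function(theta) {
  if (is.matrix(theta)) {
    stopifnot(ncol(theta) == 8)
    colnames(theta) <- param_names()
    theta
  } else {
    matrix(unclass(theta), 1L, 8L, dimnames = list(NULL, param_names()))
  }
}
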