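# Shared helpers for the suite.

# All-K-equal parameter set on the linear scale value 10^x.
flat_params <- function(x = 0) {
  vacf_params(K1 = x, K3 = x, K4 = x, alpha = x, K6 = x, K7 = x,
              beta = x, K9 = x)
}

# Small random log10 parameter sets inside the prior box.
random_params <- function(n, seed = 42) {
  set.seed(seed)
  m <- matrix(runif(n * 8, -4, 4), n, 8)
  colnames(m) <- param_names()
  m
}

# Independent right-hand-side oracle: stoichiometry matrix times the rate
# vector, assembled reaction by reaction (a different decomposition from the
# per-species implementation in the package).
rhs_oracle <- function(state, params, flags = scenario_flags()) {
  k <- 10^unclass(params)
  K <- c(K1 = k[["K1"]], K3 = k[["K3"]], K4 = k[["K4"]],
         K5 = k[["alpha"]] * k[["K4"]], K6 = k[["K6"]], K7 = k[["K7"]],
         K8 = k[["beta"]] * k[["K9"]], K9 = k[["K9"]])
  H <- state[[1]]; T_ <- state[[2]]; S <- state[[3]]
  Y <- state[[4]]; C <- state[[5]]; X <- state[[6]]
  # reactions: recruit_H, turnover_H, chaperone, dissoc, reassoc,
  # recruit_X, turnover_X, displace, assoc, fusion
  rates <- c(
    K[["K1"]] * as.numeric(flags$pi3p_present) *
      as.numeric(flags$hops_cytosol_present),
    K[["K1"]] * H,
    K[["K3"]] * H * max(S, 0)^4,
    K[["K4"]] * C,
    K[["K5"]] * H * T_,
    K[["K6"]] * as.numeric(flags$sec17_cytosol_present),
    K[["K7"]] * X,
    K[["K8"]] * X * C * as.numeric(flags$signal_active),
    K[["K9"]] * X * T_,
    Y)
  #          recH turH chap dis reas recX turX disp assoc fus
  stoich <- rbind(
    H = c(1, -1, -1, 1, -1, 0, 0, 0, 0, 0),
    T = c(0, 0, 0, 1, -1, 0, 0, 0, -1, 0),
    S = c(0, 0, -4, 0, 0, 0, 0, 0, 0, 4),
    Y = c(0, 0, 0, 0, 0, 0, 0, 1, 1, -1),
    C = c(0, 0, 1, -1, 1, 0, 0, -1, 0, 0),
    X = c(0, 0, 0, 0, 0, 1, -1, -1, -1, 0))
  drop(stoich %*% rates)
}

# Quick, coarse configuration for tests that only need qualitative behavior.
quick_cfg <- function(...) {
  model_config(rtol = 1e-8, atol = 1e-12, ...)
}
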