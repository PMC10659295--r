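# Model core: right-hand side, parameter transforms, steady states.

test_that("rhs at an empty membrane keeps only the recruitment terms", {
  th <- random_params(1, seed = 7)[1, ]
  d <- rhs(c(H = 0, T = 0, S = 0, Y = 0, C = 0, X = 0), th,
           scenario_flags(signal_active = TRUE))
  K <- 10^th
  expect_equal(unname(d["H"]), unname(K[["K1"]]))
  expect_equal(unname(d["X"]), unname(K[["K6"]]))
  expect_equal(unname(d[c("T", "S", "Y", "C")]), rep(0, 4))
})

test_that("rhs matches a hand-substituted case", {
  # H = 1, S = 1, all constants 1, PI3P on, signal off
  d <- rhs(c(H = 1, T = 0, S = 1, Y = 0, C = 0, X = 0), flat_params(0))
  expect_equal(unname(d), c(-1, 0, -4, 0, 1, 1))
})

test_that("rhs conserves the SNARE total algebraically", {
  th <- random_params(20, seed = 1)
  set.seed(2)
  for (i in seq_len(nrow(th))) {
    st <- runif(6, 0, 3)
    names(st) <- c("H", "T", "S", "Y", "C", "X")
    fl <- scenario_flags(pi3p_present = i %% 2 == 0,
                         signal_active = i %% 3 == 0)
    d <- rhs(st, th[i, ], fl)
    scale <- max(abs(d), 1)
    expect_lt(abs(d[["S"]] + 4 * (d[["T"]] + d[["C"]] + d[["Y"]])),
              1e-12 * scale)
  }
})

test_that("R and compiled right-hand sides agree to near machine precision", {
  th <- random_params(25, seed = 3)
  set.seed(4)
  for (i in seq_len(nrow(th))) {
    st <- runif(6, 0, 2)
    fl <- scenario_flags(signal_active = i %% 2 == 0)
    a <- rhs(stats::setNames(st, c("H", "T", "S", "Y", "C", "X")), th[i, ], fl)
    b <- vacfusion:::rhs_compiled(st, th[i, ], fl)[1:6]
    expect_equal(unname(a), unname(b), tolerance = 1e-12)
  }
})

test_that("rhs agrees with an independent stoichiometry-based oracle", {
  th <- random_params(25, seed = 5)
  set.seed(6)
  for (i in seq_len(nrow(th))) {
    st <- stats::setNames(runif(6, 0, 2), c("H", "T", "S", "Y", "C", "X"))
    fl <- scenario_flags(signal_active = i %% 2 == 0,
                         pi3p_present = i %% 5 != 0)
    a <- rhs(st, th[i, ], fl)
    b <- rhs_oracle(st, th[i, ], fl)
    expect_equal(unname(a), unname(b), tolerance = 1e-12)
  }
})

test_that("rhs rejects non-finite input", {
  expect_error(rhs(c(1, NA, 0, 0, 0, 0), flat_params()), "finite")
  expect_error(rhs(c(1, Inf, 0, 0, 0, 0), flat_params()), "finite")
})

test_that("nondimensionalization reproduces the defining ratios", {
  k1 <- stats::setNames(rep(1, 10), paste0("k", 1:10))
  th <- nondimensionalize(k1)
  expect_equal(unname(unclass(th)), rep(0, 8))

  # doubling the fusion rate halves every dimensionless constant
  k2 <- k1; k2[["k10"]] <- 2
  th2 <- nondimensionalize(k2)
  lin1 <- 10^unclass(th)[c("K1", "K3", "K4", "K6", "K7", "K9")]
  lin2 <- 10^unclass(th2)[c("K1", "K3", "K4", "K6", "K7", "K9")]
  expect_equal(unname(lin2), unname(lin1) / 2)
  # the ratios alpha and beta are unchanged
  expect_equal(th2[["alpha"]], th[["alpha"]])
  expect_equal(th2[["beta"]], th[["beta"]])

  # the chaperoning group scales as (k1/k2)^4
  k3 <- k1; k3[["k1"]] <- 2
  expect_equal(10^nondimensionalize(k3)[["K3"]], 16)

  expect_error(nondimensionalize(replace(k1, 3, -1)), "positive")
})

test_that("steady state with no SNARE pool is pure HOPS balance", {
  th <- flat_params(0)
  cfg <- quick_cfg(s_total_init = 0)
  ss <- find_steady_state(th, cfg = cfg)
  expect_true(ss$converged)
  expect_equal(unname(ss$state[["H"]]), 1, tolerance = 1e-6)
  expect_equal(unname(ss$state[c("T", "S", "Y", "C")]),
               rep(0, 4), tolerance = 1e-9)

  # with all recruitment gates off everything decays to zero
  ss0 <- find_steady_state(th, cfg = cfg,
                           flags = scenario_flags(pi3p_present = FALSE,
                                                  sec17_cytosol_present = FALSE))
  expect_true(ss0$converged)
  expect_equal(max(ss0$state), 0, tolerance = 1e-9)
})

test_that("solver trajectories conserve the SNARE total and stay non-negative", {
  th <- random_params(12, seed = 9)
  cfg <- quick_cfg()
  for (i in seq_len(nrow(th))) {
    ss <- find_steady_state(th[i, ], cfg = cfg)
    if (!ss$solver_ok) next
    tot0 <- cfg$s_total_init
    expect_lt(abs(snare_total(ss$state) - tot0),
              10 * (cfg$atol + cfg$rtol * tot0))
    expect_true(all(ss$state >= -10 * cfg$atol))
  }
})

test_that("solver matches the closed-form HOPS relaxation limit", {
  cfg <- quick_cfg()
  cfg$s_total_init <- 0
  for (logK1 in c(-1, 0, 2)) {
    th <- vacf_params(K1 = logK1)
    res <- run_scenario(th, "baseline", cfg = cfg,
                        steady = list(state = c(H = 0.25, T = 0, S = 0,
                                                Y = 0, C = 0, X = 0),
                                      solver_ok = TRUE, converged = TRUE,
                                      max_abs_deriv = NA))
    exact <- hops_relaxation_exact(res$times, 10^logK1, H0 = 0.25)
    expect_equal(unname(res$states[, "H"]), unname(exact), tolerance = 1e-7)
  }
})

test_that("steady-state relaxation reports solver failure instead of raising", {
  # a pathological stiff corner: relaxation must return a flagged result
  th <- c(K1 = 4, K3 = 4, K4 = -4, alpha = 4, K6 = 4, K7 = -4,
          beta = 4, K9 = 4)
  ss <- find_steady_state(th, cfg = quick_cfg())
  expect_true(is.list(ss))
  expect_false(ss$converged && ss$max_abs_deriv > quick_cfg()$deriv_tol)
})

test_that("parameter CSV round-trips", {
  th <- random_params(5, seed = 10)
  f <- tempfile(fileext = ".csv")
  write_params_csv(th, f)
  back <- read_params_csv(f)
  expect_equal(unname(back), unname(th), tolerance = 1e-12)
  expect_identical(colnames(back), param_names())
})
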