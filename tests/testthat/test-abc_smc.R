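# ABC-SMC machinery on cheap toy problems.

# 1-parameter toy: statistic = ReLU(|theta| - 0.1)/0.1, prior U(-4, 4);
# the exact acceptance region at statistic zero is [-0.1, 0.1].
toy_eval <- function(th) relu_objective(abs(th[[1]]), 0.1)

toy_cfg <- function(n = 200, seed = 1, ...) {
  abc_config(n_particles = n, lower = c(theta = -4), upper = c(theta = 4),
             seed = seed, ...)
}

test_that("initial population has uniform weights and percentile epsilon", {
  cfg <- toy_cfg(n = 400, seed = 5)
  pop <- initialize_population(cfg, toy_eval)
  expect_equal(pop$weights, rep(1 / 400, 400))
  expect_equal(pop$epsilon,
               unname(quantile(pop$statistics, 0.99, names = FALSE)))
  # determinism given identical settings
  pop2 <- initialize_population(cfg, toy_eval)
  expect_identical(pop$theta, pop2$theta)
  # a different seed produces a different (shifted) population
  pop3 <- initialize_population(toy_cfg(n = 400, seed = 6), toy_eval)
  expect_false(identical(pop$theta, pop3$theta))
})

test_that("evaluation failures are recorded as infinite statistics", {
  cfg <- toy_cfg(n = 50, seed = 7)
  bad_eval <- function(th) if (th[[1]] > 0) stop("boom") else toy_eval(th)
  pop <- initialize_population(cfg, bad_eval)
  expect_true(all(is.infinite(pop$statistics[pop$theta[, 1] > 0])))
})

test_that("kernel proposals are bounded by D = 0.25 * range and uniform", {
  cfg <- toy_cfg(n = 100, seed = 8)
  pop <- initialize_population(cfg, toy_eval)
  D <- 0.25 * diff(range(pop$theta[, 1]))
  set.seed(9)
  props <- replicate(1e4, perturb_particle(0, pop, cfg)[[1]])
  expect_true(all(abs(props) <= D + 1e-12))
  # empirical distribution is uniform on [-D, D]
  ks <- stats::ks.test(props, "punif", -D, D)
  expect_gt(ks$p.value, 0.01)
})

test_that("a degenerate population yields unchanged proposals", {
  cfg <- toy_cfg(n = 10, seed = 10)
  pop <- initialize_population(cfg, toy_eval)
  pop$theta[] <- 1.5
  expect_warning(D <- vacfusion:::kernel_halfwidths(pop, cfg), "degenerate")
  set.seed(11)
  suppressWarnings(
    expect_identical(perturb_particle(1.5, pop, cfg)[[1]], 1.5))
})

test_that("the toy posterior is confined to the analytic acceptance region", {
  cfg <- toy_cfg(n = 200, seed = 12)
  run <- run_abc(cfg, toy_eval)
  expect_true(run$converged)
  fin <- final_population(run)
  zero <- fin$statistics <= cfg$zero_tol
  expect_gte(mean(zero), cfg$stop_zero_fraction)
  expect_true(all(abs(fin$theta[zero, 1]) <= 0.1))
  # no particle escapes the prior box, in any generation
  for (p in run$populations) {
    expect_true(all(p$theta >= -4 & p$theta <= 4))
    expect_equal(sum(p$weights), 1, tolerance = 1e-12)
  }
})

test_that("the rejection constant shrinks by exactly 10% per generation", {
  run <- run_abc(toy_cfg(n = 100, seed = 13), toy_eval)
  eps <- run$epsilons
  expect_gt(length(eps), 2)
  ratios <- eps[-1] / eps[-length(eps)]
  expect_equal(ratios, rep(0.9, length(ratios)), tolerance = 1e-12)
})

test_that("zero-statistic fraction reaches the stopping rule and re-evaluates", {
  cfg <- toy_cfg(n = 150, seed = 14)
  run <- run_abc(cfg, toy_eval)
  fin <- final_population(run)
  re <- apply(fin$theta, 1L, toy_eval)
  expect_gte(mean(re <= cfg$zero_tol), cfg$stop_zero_fraction)
})

test_that("an unachievable schedule aborts with diagnostics", {
  # statistic can never reach zero inside the box -> epsilon underruns it
  cfg <- toy_cfg(n = 30, seed = 15, proposal_budget = 3000,
                 max_generations = 1000)
  hopeless <- function(th) 5 + relu_objective(abs(th[[1]]), 0.1)
  expect_error(run_abc(cfg, hopeless), "aborted")
})

test_that("abc runs are reproducible for a fixed seed", {
  cfg <- toy_cfg(n = 80, seed = 16)
  a <- run_abc(cfg, toy_eval)
  b <- run_abc(cfg, toy_eval)
  expect_identical(final_population(a)$theta, final_population(b)$theta)
  expect_identical(a$epsilons, b$epsilons)
})

test_that("config validation rejects out-of-range settings", {
  expect_error(abc_config(epsilon_decay = 1.1))
  expect_error(abc_config(stop_zero_fraction = 0))
  expect_error(abc_config(n_particles = 1))
  expect_error(abc_config(lower = c(0, 0), upper = c(1, -1)))
})

test_that("populations export as CSV", {
  cfg <- toy_cfg(n = 20, seed = 17)
  pop <- initialize_population(cfg, toy_eval)
  f <- tempfile(fileext = ".csv")
  write_population_csv(pop, f)
  df <- utils::read.csv(f, check.names = FALSE)
  expect_equal(nrow(df), 20)
  expect_true(all(c("theta", "weight", "statistic") %in% names(df)))
  expect_equal(sum(df$weight), 1)
})
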