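# Posterior summaries: quantiles, intervals, surveys, KS tests, histograms.

fake_population <- function(theta, weights = NULL) {
  n <- nrow(theta)
  if (is.null(weights)) weights <- rep(1 / n, n)
  list(theta = theta, weights = weights / sum(weights),
       statistics = rep(0, n), epsilon = 0)
}

test_that("weighted quantiles match brute-force weight expansion", {
  set.seed(41)
  for (rep in 1:10) {
    x <- round(rnorm(12), 2)
    counts <- sample(1:5, 12, replace = TRUE)
    w <- counts / sum(counts)
    expanded <- rep(x, counts)
    probs <- c(0.025, 0.25, 0.5, 0.9, 0.975)
    expect_equal(weighted_quantile(x, w, probs),
                 unname(quantile(expanded, probs, type = 1)))
  }
})

test_that("near-total coverage reproduces the sample range", {
  pop <- fake_population(matrix(c(-1, 0, 1), ncol = 1,
                                dimnames = list(NULL, "K1")))
  ci <- credible_intervals(pop, level = 1 - 1e-9)
  expect_equal(unname(ci["K1", "lower"]), -1)
  expect_equal(unname(ci["K1", "upper"]), 1)
  expect_error(credible_intervals(fake_population(
    matrix(numeric(0), 0, 1))), "empty")
})

test_that("credible intervals are ordered and respect weights", {
  set.seed(42)
  theta <- matrix(rnorm(500), ncol = 1, dimnames = list(NULL, "K1"))
  w <- runif(500)
  pop <- fake_population(theta, w)
  ci <- credible_intervals(pop)
  expect_true(ci[1, "lower"] <= ci[1, "median"])
  expect_true(ci[1, "median"] <= ci[1, "upper"])
  # upweighting the right tail moves the upper quantile up
  w2 <- w + 5 * (theta[, 1] > 1)
  ci2 <- credible_intervals(fake_population(theta, w2))
  expect_gte(ci2[1, "upper"], ci[1, "upper"])
})

test_that("steady-state survey fractions partition the conserved total", {
  th <- all_pass_fixtures()[1:4, ]
  pop <- fake_population(th)
  sv <- steady_state_survey(pop, cfg = model_config())
  per <- sv$per_particle
  expect_equal(per$snare_supercomplex_fraction + per$snare_free_fraction +
                 per$snare_trans_fraction + per$snare_sec17_fraction,
               rep(1, nrow(per)), tolerance = 1e-6)
  expect_true(all(per$snare_supercomplex_fraction >= 0 &
                    per$snare_supercomplex_fraction <= 1))
  expect_true(all(per$free_hops_fraction >= 0 & per$free_hops_fraction <= 1))
  expect_true(all(per$sec17_to_hops >= 0))
  expect_identical(sv$n_failed, 0L)
})

test_that("a state without super-complexes gives a zero super-complex fraction", {
  # K3 and alpha at the floor: effectively no chaperoning or reassociation
  th <- vacf_params(K3 = -4, alpha = -4, K4 = 4)
  ss <- find_steady_state(th, cfg = model_config())
  tot <- snare_total(ss$state)
  expect_lt(4 * ss$state[["C"]] / tot, 1e-4)
})

test_that("KS reproducibility test is calibrated at the extremes", {
  theta <- matrix(rnorm(300), ncol = 2,
                  dimnames = list(NULL, c("K1", "K3")))
  popA <- fake_population(theta)
  # identical populations: maximal p, no rejection
  res <- replicate_ks_test(popA, popA)
  expect_true(all(res$p_value == 1))
  expect_false(any(res$reject))
  # disjoint point masses: rejection at any alpha
  popB <- fake_population(theta + 100)
  res2 <- replicate_ks_test(popA, popB)
  expect_true(all(res2$p_value < 1e-10))
  expect_true(all(res2$reject))
  popC <- fake_population(matrix(rnorm(300), ncol = 2,
                                 dimnames = list(NULL, c("K1", "bad"))))
  expect_error(replicate_ks_test(popA, popC), "mismatched")
})

test_that("2D histograms are normalized and marginalize consistently", {
  set.seed(43)
  theta <- matrix(runif(400 * 8, -4, 4), ncol = 8,
                  dimnames = list(NULL, param_names()))
  w <- runif(400)
  pop <- fake_population(theta, w)
  h <- histogram2d(pop, "K1", "K6", bins = 20)
  expect_equal(sum(h$density), 1, tolerance = 1e-12)
  # marginalizing over K6 reproduces the weighted 1D histogram of K1
  marg <- rowSums(h$density)
  ix <- findInterval(theta[, "K1"], h$x_breaks, rightmost.closed = TRUE,
                     all.inside = TRUE)
  ref <- vapply(1:20, function(b) sum(pop$weights[ix == b]), numeric(1))
  expect_equal(marg, ref, tolerance = 1e-12)
  # single particle: all mass in one cell
  h1 <- histogram2d(fake_population(theta[1, , drop = FALSE]), "K1", "K6")
  expect_equal(max(h1$density), 1)
  expect_equal(sum(h1$density > 0), 1L)
  expect_error(histogram2d(pop, "K1", "nope"), "unknown")
})
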