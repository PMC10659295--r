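# Approximate Bayesian computation with sequential Monte Carlo.
#
# Particles are log10 parameter vectors under a uniform prior on a box.
# Each generation resamples source particles by importance weight, perturbs
# them with a per-coordinate uniform kernel of half-width D_j = f * Delta_j
# (Delta_j = range of coordinate j in the current population, f = 0.25 by
# default), and accepts proposals whose summary statistic falls at or below
# a rejection constant that shrinks by 10% per generation from the 99th
# percentile of the initial statistics. Weights follow the SMC importance
# formula: with a uniform prior, w_i is proportional to
# 1 / sum_j w_j^{t-1} K(theta_i | theta_j^{t-1}) inside the box.
# The run stops when at least 99% of particles have a summary statistic of
# (numerically) zero, i.e. satisfy all criteria.

#' ABC-SMC configuration
#'
#' @param n_particles particles per population (full-scale default 5000).
#' @param kernel_halfwidth_fraction kernel half-width as a fraction of the
#'   per-coordinate population range (default 0.25).
#' @param epsilon_decay multiplicative shrinkage of the rejection constant
#'   per generation (default 0.9).
#' @param initial_epsilon_percentile percentile of the initial statistics
#'   used as the starting rejection constant (default 99).
#' @param stop_zero_fraction stop once this fraction of particles has a zero
#'   statistic (default 0.99).
#' @param lower,upper prior box (log10), default the 8-parameter [-4,4] box.
#' @param seed RNG seed for the whole run.
#' @param proposal_budget maximum attempted perturbations per generation
#'   before aborting (default 1e6).
#' @param max_generations hard cap on generations (default 1000).
#' @param zero_tol statistics at or below this count as zero (default 1e-12).
#' @return a list of class \code{vacf_abc_config}.
#' @export
abc_config <- function(n_particles = 5000, kernel_halfwidth_fraction = 0.25,
                       epsilon_decay = 0.9, initial_epsilon_percentile = 99,
                       stop_zero_fraction = 0.99,
                       lower = prior_box()$lower, upper = prior_box()$upper,
                       seed = 1, proposal_budget = 1e6,
                       max_generations = 1000, zero_tol = 1e-12) {
  stopifnot(n_particles >= 2,
            kernel_halfwidth_fraction > 0,
            epsilon_decay > 0, epsilon_decay < 1,
            initial_epsilon_percentile > 0,
            initial_epsilon_percentile <= 100,
            stop_zero_fraction > 0, stop_zero_fraction <= 1,
            length(lower) == length(upper), all(upper > lower))
  structure(list(n_particles = as.integer(n_particles),
                 kernel_halfwidth_fraction = kernel_halfwidth_fraction,
                 epsilon_decay = epsilon_decay,
                 initial_epsilon_percentile = initial_epsilon_percentile,
                 stop_zero_fraction = stop_zero_fraction,
                 lower = lower, upper = upper, seed = seed,
                 proposal_budget = proposal_budget,
                 max_generations = max_generations, zero_tol = zero_tol),
            class = "vacf_abc_config")
}

new_population <- function(t, theta, weights, stats, epsilon, cfg,
                           acceptance_rate = NA_real_,
                           n_out_of_box = 0L) {
  list(t = t, theta = theta, weights = weights / sum(weights),
       statistics = stats, epsilon = epsilon,
       zero_fraction = mean(stats <= cfg$zero_tol),
       acceptance_rate = acceptance_rate, n_out_of_box = n_out_of_box)
}

#' Initialize an ABC-SMC population
#'
#' Draws \code{n_particles} points by uniform Sobol' sampling of the prior
#' box (randomized across seeds by a Cranley-Patterson shift so independent
#' replicates differ), evaluates the summary statistic for each, assigns
#' uniform weights 1/N, and sets the initial rejection constant to the
#' configured percentile of the statistics. Evaluation failures are recorded
#' as +Inf statistics.
#'
#' @param cfg an \code{\link{abc_config}}.
#' @param evaluator function: parameter vector -> summary statistic.
#' @return a population list (generation 0).
#' @export
initialize_population <- function(cfg, evaluator) {
  d <- length(cfg$lower)
  set.seed(cfg$seed)
  shift <- runif(d)
  theta <- sobol_sample(cfg$n_particles, d, lower = cfg$lower,
                        upper = cfg$upper, shift = shift)
  if (!is.null(names(cfg$lower))) colnames(theta) <- names(cfg$lower)
  stats <- apply(theta, 1L, function(th) {
    s <- try(evaluator(th), silent = TRUE)
    if (inherits(s, "try-error") || !is.numeric(s) || is.na(s)) Inf else s
  })
  eps0 <- as.numeric(quantile(stats, cfg$initial_epsilon_percentile / 100,
                              na.rm = TRUE, names = FALSE))
  if (!is.finite(eps0)) {
    # more than (100 - percentile)% evaluation failures: fall back to the
    # largest finite statistic so the schedule can still shrink
    finite <- stats[is.finite(stats)]
    if (!length(finite)) stop("no particle produced a finite statistic")
    eps0 <- max(finite)
  }
  new_population(0L, theta, rep(1 / cfg$n_particles, cfg$n_particles),
                 stats, eps0, cfg)
}

# Per-coordinate kernel half-widths D_j = f * Delta_j from a population.
kernel_halfwidths <- function(population, cfg) {
  rng <- apply(population$theta, 2L, range)
  D <- cfg$kernel_halfwidth_fraction * (rng[2L, ] - rng[1L, ])
  if (any(D == 0)) {
    warning("degenerate kernel: zero range in some coordinate(s)")
  }
  D
}

#' Perturb a particle with the uniform kernel
#'
#' Each coordinate moves uniformly within +/- D_j of its current value,
#' D_j = \code{kernel_halfwidth_fraction} times the coordinate's range in
#' the current population. A zero range leaves the coordinate unchanged.
#' Proposals may land outside the prior box; there the prior (and hence the
#' particle weight) is zero, and \code{\link{run_abc}} redraws them.
#'
#' @param theta particle to perturb (log10 vector).
#' @param population current population (supplies the ranges).
#' @param cfg an \code{\link{abc_config}}.
#' @return proposal vector of the same length.
#' @export
perturb_particle <- function(theta, population, cfg) {
  D <- kernel_halfwidths(population, cfg)
  theta + runif(length(theta), -D, D)
}

# Uniform-kernel density of moving from each row of `from` to `to`.
kernel_density <- function(to, from, D) {
  dens <- rep(1, nrow(from))
  for (k in seq_along(D)) {
    diffk <- abs(from[, k] - to[k])
    if (D[k] > 0) {
      dens <- dens * ifelse(diffk <= D[k] + 1e-15, 1 / (2 * D[k]), 0)
    } else {
      dens <- dens * ifelse(diffk == 0, 1, 0)
    }
  }
  dens
}

#' Run the ABC-SMC sampler
#'
#' @param cfg an \code{\link{abc_config}}.
#' @param evaluator function: parameter vector -> summary statistic
#'   (defaults to the model criteria evaluator under \code{model_cfg}).
#' @param model_cfg a \code{\link{model_config}} used by the default
#'   evaluator.
#' @param memoize cache statistic evaluations by parameter value
#'   (default TRUE; the evaluator is the dominant cost).
#' @param verbose print one line per generation.
#' @return a list of class \code{vacf_abc}: \code{populations} (all
#'   generations, the last being the plausible-domain sample),
#'   \code{converged} (stopping rule reached), \code{epsilons}, \code{cfg}.
#' @export
run_abc <- function(cfg = abc_config(), evaluator = NULL,
                    model_cfg = model_config(), memoize = TRUE,
                    verbose = FALSE) {
  if (is.null(evaluator)) {
    evaluator <- function(th) {
      evaluate_criteria(th, cfg = model_cfg)$summary_statistic
    }
  }
  if (memoize) {
    cache <- new.env(parent = emptyenv(), hash = TRUE)
    base_eval <- evaluator
    evaluator <- function(th) {
      key <- paste(sprintf("%.17g", th), collapse = "|")
      hit <- cache[[key]]
      if (!is.null(hit)) return(hit)
      val <- base_eval(th)
      cache[[key]] <- val
      val
    }
  }
  pop <- initialize_population(cfg, evaluator)
  pops <- list(pop)
  eps <- pop$epsilon
  N <- cfg$n_particles
  d <- length(cfg$lower)
  t <- 0L
  while (pop$zero_fraction < cfg$stop_zero_fraction &&
         t < cfg$max_generations) {
    t <- t + 1L
    eps <- cfg$epsilon_decay * eps
    D <- suppressWarnings(kernel_halfwidths(pop, cfg))
    theta_new <- matrix(NA_real_, N, d, dimnames = dimnames(pop$theta))
    stats_new <- numeric(N)
    filled <- 0L
    attempts <- 0L
    oob <- 0L
    while (filled < N) {
      if (attempts >= cfg$proposal_budget) {
        stop(sprintf(paste0(
          "ABC-SMC aborted in generation %d: %d proposals exhausted with ",
          "%d/%d particles accepted (epsilon = %.3g). The rejection ",
          "schedule is too aggressive for this evaluator."),
          t, attempts, filled, N, eps))
      }
      src <- sample.int(N, 1L, prob = pop$weights)
      prop <- pop$theta[src, ] + runif(d, -D, D)
      attempts <- attempts + 1L
      if (any(prop < cfg$lower) || any(prop > cfg$upper)) {
        oob <- oob + 1L
        next
      }
      s <- evaluator(prop)
      if (is.na(s)) s <- Inf
      if (s <= eps) {
        filled <- filled + 1L
        theta_new[filled, ] <- prop
        stats_new[filled] <- s
      }
    }
    # importance weights (uniform prior inside the box)
    denom <- vapply(seq_len(N), function(i) {
      sum(pop$weights * kernel_density(theta_new[i, ], pop$theta, D))
    }, numeric(1))
    w <- 1 / denom
    pop <- new_population(t, theta_new, w, stats_new, eps, cfg,
                          acceptance_rate = N / attempts,
                          n_out_of_box = oob)
    pops[[length(pops) + 1L]] <- pop
    if (verbose) {
      message(sprintf(
        "generation %3d: epsilon = %.4g, acceptance = %.3f, zero = %.3f",
        t, eps, pop$acceptance_rate, pop$zero_fraction))
    }
  }
  structure(list(populations = pops,
                 converged = pop$zero_fraction >= cfg$stop_zero_fraction,
                 epsilons = vapply(pops, `[[`, numeric(1), "epsilon"),
                 cfg = cfg),
            class = "vacf_abc")
}

#' Final (plausible-domain) population of an ABC run
#' @param run a \code{vacf_abc} object.
#' @return the last population.
#' @export
final_population <- function(run) {
  run$populations[[length(run$populations)]]
}

#' @export
print.vacf_abc <- function(x, ...) {
  fin <- final_population(x)
  cat(sprintf(paste0(
    "ABC-SMC run: %d particles, %d generations, %s\n",
    "  final epsilon = %.4g, zero-statistic fraction = %.3f\n"),
    length(fin$weights), length(x$populations) - 1L,
    if (x$converged) "converged" else "generation cap reached",
    fin$epsilon, fin$zero_fraction))
  invisible(x)
}

#' Export an ABC population as CSV
#'
#' One row per particle: the log10 parameters, importance weight and summary
#' statistic.
#'
#' @param population an ABC population.
#' @param path file path.
#' @export
write_population_csv <- function(population, path) {
  df <- data.frame(population$theta, weight = population$weights,
                   statistic = population$statistics, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
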