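# Quasi-random screening of the prior box for satisficing fractions.

#' Wilson score interval for a binomial fraction
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param level confidence level (default 0.95).
#' @return numeric vector \code{c(lower, upper)}.
#' @export
wilson_interval <- function(x, n, level = 0.95) {
  stopifnot(n >= 1, x >= 0, x <= n)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, center - half), upper = min(1, center + half))
}

#' Screen the prior box for satisficing parameter sets
#'
#' Draws \code{n} parameter sets by uniform Sobol' sampling of the log10
#' prior box, evaluates the five criteria for each, and summarizes
#' per-criterion and joint pass fractions with Wilson 95\% intervals.
#' Per-set evaluation is pure, so fractions are invariant to partitioning
#' the sequence into sub-screens.
#'
#' @param n number of parameter sets.
#' @param cfg a \code{\link{model_config}}.
#' @param lower,upper log10 box bounds (default the [-4, 4] prior box).
#' @param shift optional Cranley-Patterson shift (see
#'   \code{\link{sobol_sample}}); \code{NULL} gives the deterministic raw
#'   sequence.
#' @param keep_reports keep the full per-set report data.frame (default TRUE).
#' @param progress print progress every \code{progress} sets (0 = silent).
#' @return a list of class \code{vacf_screen}: \code{n_sampled},
#'   \code{fractions} (named CR1..CR5, joint), \code{counts}, \code{wilson}
#'   (2 x 6 matrix), \code{cfg}, \code{sampler} metadata, and optionally
#'   \code{reports}.
#' @export
screen_parameters <- function(n, cfg = model_config(),
                              lower = prior_box()$lower,
                              upper = prior_box()$upper,
                              shift = NULL, keep_reports = TRUE,
                              progress = 0) {
  stopifnot(n >= 1)
  theta <- sobol_sample(n, 8, lower = lower, upper = upper, shift = shift)
  colnames(theta) <- param_names()
  chunks <- split(seq_len(n), ceiling(seq_len(n) / 1024))
  reports <- vector("list", length(chunks))
  for (i in seq_along(chunks)) {
    reports[[i]] <- evaluate_criteria_batch(theta[chunks[[i]], , drop = FALSE],
                                            cfg = cfg)
    if (progress > 0 && (max(chunks[[i]]) %% progress == 0 || i == length(chunks))) {
      message(sprintf("screen: %d / %d parameter sets evaluated",
                      max(chunks[[i]]), n))
    }
  }
  reports <- do.call(rbind, reports)
  pass_cols <- paste0("pass_", names(criteria_thresholds()))
  counts <- c(colSums(reports[, pass_cols, drop = FALSE]),
              joint = sum(reports$all_pass))
  names(counts) <- c(names(criteria_thresholds()), "joint")
  fractions <- counts / n
  wil <- vapply(counts, wilson_interval, numeric(2), n = n)
  out <- list(n_sampled = n, fractions = fractions, counts = counts,
              wilson = wil, cfg = cfg,
              sampler = list(type = "sobol", scramble = FALSE,
                             skip = 0L, shift = shift,
                             lower = lower, upper = upper))
  if (keep_reports) out$reports <- reports
  structure(out, class = "vacf_screen")
}

#' @export
print.vacf_screen <- function(x, ...) {
  cat(sprintf("Satisficing screen: n = %d Sobol' parameter sets\n",
              x$n_sampled))
  for (nm in names(x$fractions)) {
    cat(sprintf("  %-5s pass %7.3f%%  (Wilson 95%%: %.3f%% - %.3f%%)\n",
                nm, 100 * x$fractions[[nm]],
                100 * x$wilson["lower", nm], 100 * x$wilson["upper", nm]))
  }
  invisible(x)
}

#' Export a screen summary as JSON
#'
#' Writes the fractions, counts, Wilson intervals, sampler settings and
#' configuration (everything except the per-set reports) to a JSON file.
#'
#' @param x a \code{vacf_screen}.
#' @param path file path.
#' @export
write_screen_json <- function(x, path) {
  stopifnot(inherits(x, "vacf_screen"))
  out <- list(n_sampled = x$n_sampled,
              fractions = as.list(x$fractions),
              counts = as.list(x$counts),
              wilson_lower = as.list(x$wilson["lower", ]),
              wilson_upper = as.list(x$wilson["upper", ]),
              sampler = x$sampler[c("type", "scramble", "skip")],
              cfg = unclass(x$cfg))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
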