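# Quasi-random (Sobol') sequence generation.
#
# No installed package provides Sobol' sequences, so the generator is
# implemented here: the standard Gray-code construction with Joe-Kuo
# direction numbers (new-joe-kuo-6), matching the unscrambled default of
# common quasi-random libraries. Dimensions up to 10 are supported, which
# covers the 8 kinetic parameters plus a dummy coordinate with headroom.

# Joe-Kuo direction-number table: degree s, coefficient bits a, initial m's.
.sobol_dirtab <- list(
  list(s = 1L, a = 0L, m = c(1L)),
  list(s = 2L, a = 1L, m = c(1L, 3L)),
  list(s = 3L, a = 1L, m = c(1L, 3L, 1L)),
  list(s = 3L, a = 2L, m = c(1L, 1L, 1L)),
  list(s = 4L, a = 1L, m = c(1L, 1L, 3L, 3L)),
  list(s = 4L, a = 4L, m = c(1L, 3L, 5L, 13L)),
  list(s = 5L, a = 2L, m = c(1L, 1L, 5L, 5L, 17L)),
  list(s = 5L, a = 4L, m = c(1L, 1L, 5L, 5L, 5L)),
  list(s = 5L, a = 7L, m = c(1L, 1L, 7L, 11L, 19L))
)

.sobol_maxbit <- 30L

# Direction integers v[1..maxbit] for one dimension (dim 1 = van der Corput).
.sobol_directions <- function(dim) {
  mb <- .sobol_maxbit
  if (dim == 1L) {
    return(bitwShiftL(1L, mb - seq_len(mb)))
  }
  e <- .sobol_dirtab[[dim - 1L]]
  s <- e$s
  m <- integer(mb)
  m[seq_len(s)] <- e$m
  if (mb > s) {
    for (k in (s + 1L):mb) {
      val <- bitwXor(m[k - s], bitwShiftL(m[k - s], s))
      if (s > 1L) {
        for (j in seq_len(s - 1L)) {
          # coefficient a_j is bit (s - 1 - j) of e$a (most significant first)
          if (bitwAnd(bitwShiftR(e$a, s - 1L - j), 1L) == 1L) {
            val <- bitwXor(val, bitwShiftL(m[k - j], j))
          }
        }
      }
      m[k] <- val
    }
  }
  bitwShiftL(m, mb - seq_len(mb))
}

#' Generate a Sobol' low-discrepancy sample
#'
#' Gray-code Sobol' sequence (unscrambled, no points skipped, so the first
#' point is the lower corner of the box), mapped affinely into a rectangular
#' box. With default settings the sequence is fully deterministic; a
#' Cranley-Patterson random shift (mod 1) can be applied to obtain seeded,
#' independent low-discrepancy replicates.
#'
#' @param n number of points (>= 1).
#' @param dims dimension (1 to 10).
#' @param lower,upper box bounds; scalars are recycled across dimensions.
#' @param shift optional numeric vector of length \code{dims} in [0,1):
#'   Cranley-Patterson rotation applied before mapping into the box, or
#'   \code{NULL} (default) for the raw sequence.
#' @return an \code{n x dims} numeric matrix of points inside the box.
#' @examples
#' sobol_sample(8, 2)                       # unit square
#' sobol_sample(8, 8, lower = -4, upper = 4) # log10 prior box
#' @export
sobol_sample <- function(n, dims, lower = 0, upper = 1, shift = NULL) {
  stopifnot(n >= 1, dims >= 1)
  if (dims > 10L) {
    stop("sobol_sample: at most 10 dimensions are supported")
  }
  if (n > 2^.sobol_maxbit) {
    stop("sobol_sample: n exceeds generator capacity")
  }
  lower <- rep_len(lower, dims)
  upper <- rep_len(upper, dims)
  if (any(upper < lower)) stop("sobol_sample: upper < lower")
  v <- vapply(seq_len(dims), .sobol_directions, integer(.sobol_maxbit))
  x <- integer(dims)
  out <- matrix(0L, n, dims)
  for (i in seq_len(n)) {
    out[i, ] <- x
    # rightmost zero bit of (i - 1), 1-based
    c <- 1L
    val <- i - 1L
    while (bitwAnd(val, 1L) == 1L) {
      val <- bitwShiftR(val, 1L)
      c <- c + 1L
    }
    x <- bitwXor(x, v[c, ])
  }
  u <- out / 2^.sobol_maxbit
  if (!is.null(shift)) {
    stopifnot(length(shift) == dims, all(shift >= 0), all(shift < 1))
    u <- (u + matrix(shift, n, dims, byrow = TRUE)) %% 1
  }
  sweep(sweep(u, 2L, upper - lower, "*"), 2L, lower, "+")
}
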