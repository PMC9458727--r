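# Primitive polynomials and initial direction numbers for the first 48
# dimensions of the Sobol' sequence, from the published Joe & Kuo (2008)
# direction-number tables (new-joe-kuo-6 ordering).  48 dimensions cover a
# Saltelli design over all 21 cascade weights (2 x 21 = 42).
.SOBOL_POLY <- c(
  1L, 3L, 7L, 11L, 13L, 19L, 25L, 37L, 41L, 47L, 55L, 59L, 61L, 67L, 91L,
  97L, 103L, 109L, 115L, 131L, 137L, 143L, 145L, 157L, 167L, 171L, 185L,
  191L, 193L, 203L, 211L, 213L, 229L, 239L, 241L, 247L, 253L, 285L, 299L,
  301L, 333L, 351L, 355L, 357L, 361L, 369L, 391L, 397L)

.SOBOL_MINIT <- list(
  c(1L), c(1L), c(1L, 3L), c(1L, 3L, 1L), c(1L, 1L, 1L), c(1L, 1L, 3L, 3L),
  c(1L, 3L, 5L, 13L), c(1L, 1L, 5L, 5L, 17L), c(1L, 1L, 5L, 5L, 5L),
  c(1L, 1L, 7L, 11L, 19L), c(1L, 1L, 5L, 1L, 1L), c(1L, 1L, 1L, 3L, 11L),
  c(1L, 3L, 5L, 5L, 31L), c(1L, 3L, 3L, 9L, 7L, 49L),
  c(1L, 1L, 1L, 15L, 21L, 21L), c(1L, 3L, 1L, 13L, 27L, 49L),
  c(1L, 1L, 1L, 15L, 7L, 5L), c(1L, 3L, 1L, 15L, 13L, 25L),
  c(1L, 1L, 5L, 5L, 19L, 61L), c(1L, 3L, 7L, 11L, 23L, 15L, 103L),
  c(1L, 3L, 7L, 13L, 13L, 15L, 69L), c(1L, 1L, 3L, 13L, 7L, 35L, 63L),
  c(1L, 3L, 5L, 9L, 1L, 25L, 53L), c(1L, 3L, 1L, 13L, 9L, 35L, 107L),
  c(1L, 3L, 1L, 5L, 27L, 61L, 31L), c(1L, 1L, 5L, 11L, 19L, 41L, 61L),
  c(1L, 3L, 5L, 3L, 3L, 13L, 69L), c(1L, 1L, 7L, 13L, 1L, 19L, 1L),
  c(1L, 3L, 7L, 5L, 13L, 19L, 59L), c(1L, 1L, 3L, 9L, 25L, 29L, 41L),
  c(1L, 3L, 5L, 13L, 23L, 1L, 55L), c(1L, 3L, 7L, 3L, 13L, 59L, 17L),
  c(1L, 3L, 1L, 3L, 5L, 53L, 69L), c(1L, 1L, 5L, 5L, 23L, 33L, 13L),
  c(1L, 1L, 7L, 7L, 1L, 61L, 123L), c(1L, 1L, 7L, 9L, 13L, 61L, 49L),
  c(1L, 3L, 3L, 5L, 3L, 55L, 33L), c(1L, 3L, 1L, 15L, 31L, 13L, 49L, 245L),
  c(1L, 3L, 5L, 15L, 31L, 59L, 63L, 97L),
  c(1L, 3L, 1L, 11L, 11L, 11L, 77L, 249L),
  c(1L, 3L, 1L, 11L, 27L, 43L, 71L, 9L),
  c(1L, 1L, 7L, 15L, 21L, 11L, 81L, 45L),
  c(1L, 3L, 7L, 3L, 25L, 31L, 65L, 79L),
  c(1L, 3L, 1L, 1L, 19L, 11L, 3L, 205L),
  c(1L, 1L, 5L, 9L, 19L, 21L, 29L, 157L),
  c(1L, 3L, 7L, 11L, 1L, 33L, 89L, 185L),
  c(1L, 3L, 3L, 3L, 15L, 9L, 79L, 71L),
  c(1L, 3L, 7L, 11L, 15L, 39L, 119L, 27L))

#' Sobol' low-discrepancy points
#'
#' Generates `n` quasi-random points in the unit hypercube of dimension
#' `d` (up to 48) by the Gray-code Sobol' construction.  When `seed` is
#' given, a per-dimension random digital shift (XOR mask) is applied,
#' giving a randomized sequence that is reproducible for a given seed;
#' without a seed the plain (unshifted) sequence is returned, whose first
#' point is the origin.
#'
#' @param n number of points (powers of two give the best balance).
#' @param d dimension, at most 48.
#' @param seed optional integer seed for the digital shift.
#' @return an `n` x `d` matrix of points in `[0, 1)`.
#' @export
sobol_points <- function(n, d, seed = NULL) {
  if (d < 1 || d > length(.SOBOL_POLY))
    stop("dimension must be between 1 and ", length(.SOBOL_POLY))
  if (n < 1) stop("n must be positive")
  shift <- integer(d)
  if (!is.null(seed)) {
    old <- .save_rng()
    on.exit(.restore_rng(old))
    set.seed(seed)
    # 31 random bits per dimension
    shift <- as.integer(floor(runif(d) * 2^31))
  }
  .sobol_points_cpp(as.integer(n), .SOBOL_MINIT[seq_len(d)],
                    .SOBOL_POLY[seq_len(d)], shift)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
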