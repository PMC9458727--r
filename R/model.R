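#' Polynomial basis library for the cascade equations
#'
#' Enumerates the monomial terms available to one equation of the cascade.
#' In `"single"` mode (the amyloid equation) terms are powers `x^l`,
#' `l = 0..m`, of the equation's own variable.  In `"pair"` mode (the
#' downstream equations) terms are monomials `x^l1 * y^l2` in the own
#' variable `x` and the upstream variable `y` with total degree
#' `l1 + l2 <= m`.  Ordering is canonical and positionally stable:
#' constant, pure own powers ascending, pure upstream powers ascending,
#' then cross terms by total degree (own exponent descending within a
#' degree).  For `m = 2`, `"pair"` this yields exactly the printed model
#' order `1, x, x^2, y, y^2, x*y`.
#'
#' @param m non-negative integer polynomial degree.
#' @param mode `"single"` or `"pair"`.
#' @return an object of class `library_spec`: list with `degree`, `mode`,
#'   and `exponents` (an integer matrix, one row per term, columns `own`
#'   and `upstream`; the upstream column is absent in single mode).
#' @examples
#' build_library(2, "pair")$exponents
#' @export
build_library <- function(m, mode = c("pair", "single")) {
  mode <- match.arg(mode)
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 0 || m != floor(m))
    stop("degree m must be a non-negative integer")
  m <- as.integer(m)
  if (mode == "single") {
    exps <- matrix(0:m, ncol = 1, dimnames = list(NULL, "own"))
  } else {
    own <- integer(0); up <- integer(0)
    # constant, pure own powers, pure upstream powers
    own <- c(own, 0L, seq_len(m)); up <- c(up, 0L, rep(0L, m))
    own <- c(own, rep(0L, m)); up <- c(up, seq_len(m))
    # cross terms, by total degree then own exponent descending
    if (m >= 2) {
      for (d in 2:m) {
        for (l1 in seq.int(d - 1L, 1L)) {
          own <- c(own, l1); up <- c(up, d - l1)
        }
      }
    }
    exps <- cbind(own = own, upstream = up)
  }
  expected <- if (mode == "single") m + 1L else (m + 1L) * (m + 2L) / 2L
  stopifnot(nrow(exps) == expected)
  structure(list(degree = m, mode = mode, exponents = exps),
            class = "library_spec")
}

#' Labels for library terms
#'
#' @param spec a `library_spec`.
#' @param own,upstream variable names used in the labels.
#' @return character vector of human-readable term labels.
#' @export
library_term_labels <- function(spec, own = "x", upstream = "y") {
  ex <- spec$exponents
  lab <- function(v, e) {
    if (e == 0) "" else if (e == 1) v else paste0(v, "^", e)
  }
  apply(ex, 1, function(r) {
    s <- lab(own, r[["own"]])
    if (ncol(ex) > 1) {
      s2 <- lab(upstream, r[["upstream"]])
      s <- paste0(s, if (nzchar(s) && nzchar(s2)) "*" else "", s2)
    }
    if (!nzchar(s)) "1" else s
  })
}

#' Cascade right-hand side
#'
#' Derivatives of the four biomarkers with respect to DPS.  The dependency
#' structure encodes the amyloid cascade: the amyloid equation involves A
#' only; tau depends on (A, tau); neurodegeneration on (tau, N); cognition
#' on (N, C).
#'
#' @param state numeric 4-vector `(A, T, N, C)`.
#' @param params a [cascade_params] object.
#' @return numeric 4-vector of derivatives.
#' @export
cascade_rhs <- function(state, params) {
  stopifnot(is_cascade_params(params))
  if (length(state) != 4L || !all(is.finite(state)))
    stop("state must be a finite 4-vector")
  w <- params$w
  A <- state[1]; T <- state[2]; N <- state[3]; C <- state[4]
  c(A = w[["w_A0"]] + w[["w_A1"]] * A + w[["w_A2"]] * A^2,
    T = w[["w_T0"]] + w[["w_T1"]] * T + w[["w_T2"]] * T^2 +
        w[["w_T3"]] * A + w[["w_T4"]] * A^2 + w[["w_T5"]] * A * T,
    N = w[["w_N0"]] + w[["w_N1"]] * N + w[["w_N2"]] * N^2 +
        w[["w_N3"]] * T + w[["w_N4"]] * T^2 + w[["w_N5"]] * T * N,
    C = w[["w_C0"]] + w[["w_C1"]] * C + w[["w_C2"]] * C^2 +
        w[["w_C3"]] * N + w[["w_C4"]] * N^2 + w[["w_C5"]] * N * C)
}

#' Solve the cascade over the DPS axis
#'
#' Integrates the four-equation system from `s = -10` with initial state
#' `(y0, 0, 0, 0)` using an adaptive Dormand-Prince 5(4) scheme
#' (relative tolerance 1e-8, absolute 1e-10 by default).  Integration
#' aborts with an error if any state magnitude exceeds the blow-up guard,
#' which matters when sensitivity analysis perturbs the weights.
#'
#' @param params a [cascade_params] object.
#' @param s_eval increasing DPS grid in `[-10, 20]` at which the solution
#'   is returned.
#' @param rtol,atol solver tolerances.
#' @param guard blow-up guard on state magnitude.
#' @return an object of class `cascade_trajectory`: list with `s` (the
#'   grid) and `values` (length(s) x 4 matrix, columns A, T, N, C).
#' @examples
#' tr <- solve_model(reference_params("lmci_ad"), seq(-10, 20, by = 0.1))
#' tail(tr$values[, "A"], 1)  # logistic plateau near w_A1/|w_A2|
#' @export
solve_model <- function(params, s_eval = seq(S_MIN, S_MAX, by = 0.1),
                        rtol = 1e-8, atol = 1e-10, guard = 1e3) {
  stopifnot(is_cascade_params(params))
  s_eval <- as.numeric(s_eval)
  if (any(!is.finite(s_eval)) || is.unsorted(s_eval, strictly = TRUE))
    stop("s_eval must be strictly increasing and finite")
  if (s_eval[1] < S_MIN - 1e-9 || s_eval[length(s_eval)] > S_MAX + 1e-9)
    stop("s_eval must lie within [-10, 20]")
  vals <- .solve_cascade_cpp(params$w, params$y0, s_eval,
                             s0 = S_MIN, rtol = rtol, atol = atol,
                             guard = guard)
  structure(list(s = s_eval, values = vals, params = params),
            class = "cascade_trajectory")
}

#' @export
print.cascade_trajectory <- function(x, ...) {
  cat(sprintf("cascade trajectory on %d DPS points in [%.3g, %.3g]\n",
              length(x$s), x$s[1], x$s[length(x$s)]))
  invisible(x)
}

# cache of dense solves keyed by parameter hash, so repeated evaluate_f
# calls with the same params reuse one integration
.f_cache <- new.env(parent = emptyenv())

.params_key <- function(params, rtol, atol) {
  paste(c(format(params$w, digits = 17), format(params$y0, digits = 17),
          rtol, atol), collapse = "|")
}

.dense_solution <- function(params, rtol = 1e-8, atol = 1e-10,
                            clamp = FALSE) {
  key <- .params_key(params, rtol, atol)
  hit <- .f_cache[[key]]
  if (!is.null(hit)) return(hit)
  s <- seq(S_MIN, S_MAX, length.out = 1201L)
  vals <- .solve_cascade_cpp(params$w, params$y0, s, s0 = S_MIN,
                             rtol = rtol, atol = atol, guard = 1e3,
                             clamp = clamp)
  tr <- structure(list(s = s, values = vals, params = params),
                  class = "cascade_trajectory")
  if (length(ls(.f_cache)) > 64L) rm(list = ls(.f_cache), envir = .f_cache)
  assign(key, tr, envir = .f_cache)
  tr
}

#' Evaluate one biomarker of the model solution
#'
#' `f_k(s; w)`: the solved trajectory of biomarker `k` at DPS values `s`.
#' A dense solve on 1201 grid points is cached per parameter set and
#' evaluated by monotone linear interpolation, so repeated calls are cheap
#' and the function is a pure function of `(k, s, params)`.
#'
#' @param k biomarker id: `"A"`, `"T"`, `"N"` or `"C"`.
#' @param s DPS value(s) in `[-10, 20]`.
#' @param params a [cascade_params] object.
#' @param rtol,atol solver tolerances for the underlying dense solve.
#' @return numeric vector of model values, same length as `s`.
#' @export
evaluate_f <- function(k, s, params, rtol = 1e-8, atol = 1e-10) {
  k <- match.arg(k, BIOMARKERS)
  s <- as.numeric(s)
  if (any(!is.finite(s)) || any(s < S_MIN - 1e-9) || any(s > S_MAX + 1e-9))
    stop("s outside the DPS domain [-10, 20]")
  tr <- .dense_solution(params, rtol, atol)
  approx(tr$s, tr$values[, k], xout = pmin(pmax(s, S_MIN), S_MAX))$y
}

# model values for all four biomarkers at per-observation s; used by the
# calibration and personalization fits.  Solves once at the union of the
# requested points -- no interpolation error.  With clamp = TRUE a
# blow-up does not raise: unreached outputs saturate at the guard value,
# which keeps least-squares residuals finite and steers the optimizer
# away from exploding weight regions.
.f_all_at <- function(s, params, rtol = 1e-8, atol = 1e-10, clamp = FALSE) {
  su <- sort(unique(s))
  vals <- .solve_cascade_cpp(params$w, params$y0, su, s0 = S_MIN,
                             rtol = rtol, atol = atol, guard = 1e3,
                             clamp = clamp)
  idx <- match(s, su)
  vals[idx, , drop = FALSE]
}
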