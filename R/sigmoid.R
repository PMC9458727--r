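#' Four-parameter sigmoid
#'
#' `g(s) = a / (1 + exp(-b (s - c))) + d`: the empirical baseline shape for
#' a biomarker trajectory over DPS.  `a` is the magnitude scale, `b` the
#' slope coefficient (its sign encodes direction), `c` the horizontal
#' position in DPS units and `d` the vertical offset.  Evaluation is
#' numerically stable for large `|b (s - c)|`.
#'
#' @param s DPS value(s).
#' @param theta numeric vector `c(a, b, c, d)` (named or positional).
#' @return numeric vector of sigmoid values.
#' @export
sigmoid_eval <- function(s, theta) {
  th <- .check_theta(theta)
  x <- th[2] * (s - th[3])
  # stable logistic: never exponentiate a large positive argument
  p <- ifelse(x >= 0, 1 / (1 + exp(-x)), exp(x) / (1 + exp(x)))
  unname(th[1] * p + th[4])
}

#' Analytic derivative of the four-parameter sigmoid
#'
#' `dg/ds = a b p (1 - p)` with `p` the logistic factor; supplies the
#' derivative vector of the sparse-discovery regression without finite
#' differences.
#'
#' @inheritParams sigmoid_eval
#' @return numeric vector of derivative values.
#' @export
sigmoid_derivative <- function(s, theta) {
  th <- .check_theta(theta)
  x <- th[2] * (s - th[3])
  p <- ifelse(x >= 0, 1 / (1 + exp(-x)), exp(x) / (1 + exp(x)))
  unname(th[1] * th[2] * p * (1 - p))
}

.check_theta <- function(theta) {
  if (length(theta) != 4L || !all(is.finite(theta)))
    stop("theta must be four finite values (a, b, c, d)")
  th <- as.numeric(theta)
  names(th) <- c("a", "b", "c", "d")
  th
}

#' Fit a four-parameter sigmoid to (s, value) points
#'
#' Weighted nonlinear least squares by Levenberg-Marquardt with five
#' deterministic data-driven starts (the objective is multimodal): `a` at
#' the signed data range, `d` at the matching extreme, `c` at the median
#' `s`, and slope `b` in `{0.5, 2}` for each orientation plus a flat
#' start.  The lowest-RSS converged start wins.
#'
#' @param s,value numeric vectors of equal length (>= 4 points).
#' @param weights optional non-negative observation weights.
#' @return an object of class `sigmoid_fit`: list with `theta`, `rss`,
#'   `converged`, `degenerate` (TRUE when the response is constant) and
#'   `n`.
#' @export
fit_sigmoid <- function(s, value, weights = NULL) {
  s <- as.numeric(s); value <- as.numeric(value)
  if (is.null(weights)) weights <- rep(1, length(s))
  ok <- is.finite(s) & is.finite(value)
  s <- s[ok]; value <- value[ok]; weights <- weights[ok]
  if (length(s) < 4L)
    stop("at least 4 points are required to fit a 4-parameter sigmoid")
  if (length(unique(s)) < 2L) stop("s values must not all be identical")
  sw <- sqrt(weights)

  rng <- diff(range(value))
  if (rng == 0) {
    th <- c(a = 0, b = 1, c = median(s), d = value[1])
    return(structure(list(theta = th, rss = 0, converged = TRUE,
                          degenerate = TRUE, n = length(s)),
                     class = "sigmoid_fit"))
  }
  # orientation from the overall trend
  up <- value[which.max(s)] >= value[which.min(s)]
  starts <- list()
  for (b0 in c(0.5, 2)) {
    starts[[length(starts) + 1L]] <-
      if (up) c(rng,  b0, median(s), min(value))
      else    c(rng, -b0, median(s), min(value))
  }
  for (b0 in c(0.5, 2)) {
    starts[[length(starts) + 1L]] <-
      if (up) c(-rng, -b0, median(s), max(value))
      else    c(-rng,  b0, median(s), max(value))
  }
  starts[[length(starts) + 1L]] <- c(rng, 0.1, median(s), mean(value) - rng / 2)

  resid_fn <- function(th) sw * (value - sigmoid_eval(s, th))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    conv <- fit$info %in% 1:4
    if (is.null(best) || rss < best$rss)
      best <- list(theta = setNames(as.numeric(fit$par),
                                    c("a", "b", "c", "d")),
                   rss = rss, converged = conv)
  }
  if (is.null(best))
    return(structure(list(theta = c(a = rng, b = 1, c = median(s),
                                    d = min(value)),
                          rss = Inf, converged = FALSE, degenerate = FALSE,
                          n = length(s)),
                     class = "sigmoid_fit"))
  structure(c(best, list(degenerate = FALSE, n = length(s))),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf(
    "sigmoid fit: a=%.4g b=%.4g c=%.4g d=%.4g  (RSS %.3g, %s, n=%d)\n",
    x$theta[1], x$theta[2], x$theta[3], x$theta[4], x$rss,
    if (x$converged) "converged" else "NOT converged", x$n))
  invisible(x)
}

#' Sigmoid denoising of one subject's biomarker series
#'
#' Replaces a subject's observed values of one biomarker by the values of
#' a per-subject sigmoid fitted against the subject's DPS.  With fewer
#' than 4 usable visits, or when the fit fails, the raw values are
#' returned with `fallback = TRUE`.
#'
#' @param s DPS values of the subject's visits.
#' @param value observed biomarker values at those visits.
#' @return list with `fitted` (denoised values), `fallback` flag and the
#'   underlying `fit` (NULL on fallback).
#' @export
denoise_subject <- function(s, value) {
  ok <- is.finite(s) & is.finite(value)
  if (sum(ok) < 4L)
    return(list(fitted = value, fallback = TRUE, fit = NULL))
  fit <- tryCatch(fit_sigmoid(s[ok], value[ok]), error = function(e) NULL)
  if (is.null(fit) || !fit$converged)
    return(list(fitted = value, fallback = TRUE, fit = fit))
  out <- value
  out[ok] <- sigmoid_eval(s[ok], fit$theta)
  list(fitted = out, fallback = FALSE, fit = fit)
}

#' Sigmoid baseline prediction of the last visit
#'
#' The empirical competitor to the personalized cascade model: fits the
#' four-parameter sigmoid to the first `M - 1` points of a single
#' biomarker and predicts the held-out last point, scored with the same
#' prediction-accuracy formula as the model ([prediction_accuracy()]).
#' Unlike the cascade model this uses the current biomarker's history
#' only.
#'
#' @param s DPS values of all `M >= 5` visits (increasing).
#' @param value observed (typically denoised) biomarker values.
#' @return list with `prediction`, `actual`, `pa` (percent) and `fit`.
#' @export
sigmoid_predict_last <- function(s, value) {
  ok <- is.finite(s) & is.finite(value)
  s <- s[ok]; value <- value[ok]
  M <- length(s)
  if (M < 5L)
    stop("at least 5 visits are required (4 to fit, 1 held out)")
  fit <- fit_sigmoid(s[-M], value[-M])
  pred <- sigmoid_eval(s[M], fit$theta)
  list(prediction = pred, actual = value[M],
       pa = prediction_accuracy(value[M], pred), fit = fit)
}
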