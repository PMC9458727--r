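#' Cascade model parameters
#'
#' Bundles the 21 polynomial weights of the four-equation biomarker cascade
#' with the initial amyloid level `y0` imposed at the left end of the DPS
#' domain (s = -10), where tau, neurodegeneration and cognition all start
#' at zero.  Weight names follow the `w_<eq><index>` convention: equation
#' letter in `A`, `T`, `N`, `C`, index 0..2 for the amyloid equation
#' (constant, linear, quadratic) and 0..5 for the downstream equations
#' (constant, own, own squared, upstream, upstream squared, cross).
#'
#' @param w numeric vector of 21 weights; if named, names must be a
#'   permutation of the canonical `w_A0 ... w_C5` set, otherwise canonical
#'   order is assumed.
#' @param y0 positive initial amyloid value at s = -10 ("a small positive
#'   value" that seeds the cascade).
#' @return an object of class `cascade_params`.
#' @examples
#' p <- reference_params("lmci_ad")
#' p$w[["w_A1"]]
#' @export
cascade_params <- function(w, y0) {
  if (length(w) != 21L)
    stop("exactly 21 weights required (3 amyloid + 6 each tau/neuro/cognition)")
  if (!is.null(names(w))) {
    if (!setequal(names(w), W_NAMES))
      stop("weight names must be exactly the canonical set w_A0 ... w_C5")
    w <- w[W_NAMES]
  } else {
    names(w) <- W_NAMES
  }
  w <- as.numeric(w)
  names(w) <- W_NAMES
  if (!all(is.finite(w))) stop("all weights must be finite")
  if (!is.numeric(y0) || length(y0) != 1L || !is.finite(y0) || y0 <= 0)
    stop("y0 must be a single positive finite value")
  structure(list(w = w, y0 = as.numeric(y0)), class = "cascade_params")
}

#' @export
print.cascade_params <- function(x, ...) {
  cat("Biomarker cascade parameters (21 weights + y0)\n")
  for (eq in BIOMARKERS) {
    idx <- grep(paste0("^w_", eq), names(x$w))
    cat(sprintf("  %s: %s\n", eq,
                paste(sprintf("%s=%.4g", names(x$w)[idx], x$w[idx]),
                      collapse = " ")))
  }
  cat(sprintf("  y0 = %g\n", x$y0))
  invisible(x)
}

#' @export
format.cascade_params <- function(x, ...) {
  paste0("cascade_params(y0=", format(x$y0), ")")
}

is_cascade_params <- function(x) inherits(x, "cascade_params")

#' Bundled calibrated population parameter sets
#'
#' Returns one of the two published population parameter columns calibrated
#' on the ADNI-1 cohort: `"full_cohort"` (CN + LMCI + AD subjects) or
#' `"lmci_ad"` (LMCI and AD groups only, refit with the DPS warps held
#' fixed).  These ship as plain-text fixtures and are used as reference
#' models for sensitivity analysis and as ground truth for the synthetic
#' cohort generator.
#'
#' @param which `"full_cohort"` or `"lmci_ad"`.
#' @return a [cascade_params] object.
#' @export
reference_params <- function(which = c("full_cohort", "lmci_ad")) {
  which <- match.arg(which)
  path <- system.file("extdata",
                      paste0("params_", which, ".json"),
                      package = "adcascade")
  if (!nzchar(path)) stop("bundled parameter fixture not found")
  read_params(path)
}

#' Write cascade parameters to a JSON key-value file
#'
#' Flat JSON with the canonical weight names plus `y0`; round-trips exactly
#' through [read_params()].
#'
#' @param params a [cascade_params] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(is_cascade_params(params))
  x <- c(as.list(params$w), list(y0 = params$y0))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read cascade parameters from a JSON key-value file
#'
#' @param path file written by [write_params()] (or hand-authored with the
#'   canonical key names `w_A0 ... w_C5`, `y0`).
#' @return a [cascade_params] object.
#' @export
read_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  missing <- setdiff(c(W_NAMES, "y0"), names(x))
  if (length(missing))
    stop("parameter file is missing keys: ", paste(missing, collapse = ", "))
  cascade_params(unlist(x[W_NAMES]), y0 = as.numeric(x[["y0"]]))
}
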