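#' Parameter ranges for global sensitivity analysis
#'
#' Builds per-weight sampling boxes at `(1 - frac)` to `(1 + frac)` of the
#' calibrated values (bounds reordered so lower <= upper for negative
#' weights).  Weights valued exactly zero have degenerate boxes and are
#' marked fixed: they are excluded from sampling and all their indices are
#' reported as 0.
#'
#' @param w a [cascade_params] object.
#' @param frac half-width as a fraction of each value (default 0.1, i.e.
#'   90--110%).
#' @return an object of class `param_ranges`: list with `lower`, `upper`
#'   (named, length 21), `free` (names of sampled weights), `fixed`, and
#'   `params`.
#' @export
make_ranges <- function(w, frac = 0.1) {
  stopifnot(is_cascade_params(w))
  lo <- pmin(w$w * (1 - frac), w$w * (1 + frac))
  hi <- pmax(w$w * (1 - frac), w$w * (1 + frac))
  fixed <- names(w$w)[w$w == 0]
  free <- setdiff(names(w$w), fixed)
  structure(list(lower = lo, upper = hi, free = free, fixed = fixed,
                 params = w, frac = frac),
            class = "param_ranges")
}

# Saltelli pick-freeze estimation core over an arbitrary model function.
# model_fn maps an n x d matrix of inputs (one row per evaluation) to a
# numeric vector (single output) or matrix (one column per output).
# Returns per-output first/total order indices, closed second-order
# indices, and bootstrap standard errors.
.saltelli <- function(lower, upper, model_fn, N, seed, second_order = TRUE,
                      n_boot = 100L) {
  d <- length(lower)
  if (N < 2 || bitwAnd(N, N - 1L) != 0)
    stop("base sample size N must be a power of two")
  U <- sobol_points(N, 2L * d, seed = seed)
  A <- U[, seq_len(d), drop = FALSE]
  B <- U[, d + seq_len(d), drop = FALSE]
  span <- upper - lower
  map <- function(M) sweep(sweep(M, 2, span, "*"), 2, lower, "+")
  eval_block <- function(M) {
    out <- model_fn(map(M))
    if (is.null(dim(out))) out <- matrix(out, ncol = 1)
    out
  }
  fA <- eval_block(A)
  fB <- eval_block(B)
  n_out <- ncol(fA)
  fAB <- vector("list", d)
  for (i in seq_len(d)) {
    Ai <- A; Ai[, i] <- B[, i]
    fAB[[i]] <- eval_block(Ai)
  }
  fBA <- NULL
  if (second_order) {
    fBA <- vector("list", d)
    for (i in seq_len(d)) {
      Bi <- B; Bi[, i] <- A[, i]
      fBA[[i]] <- eval_block(Bi)
    }
  }
  est <- function(idx, out_j) {
    a <- fA[idx, out_j]; b <- fB[idx, out_j]
    V <- var(c(a, b))
    if (V <= 0) {
      z <- numeric(d)
      return(list(S1 = z, ST = z,
                  S2 = if (second_order) matrix(0, d, d) else NULL))
    }
    S1 <- vapply(seq_len(d), function(i)
      mean(b * (fAB[[i]][idx, out_j] - a)) / V, 0)
    ST <- vapply(seq_len(d), function(i)
      0.5 * mean((a - fAB[[i]][idx, out_j])^2) / V, 0)
    S2 <- NULL
    if (second_order) {
      S2 <- matrix(NA_real_, d, d)
      m0 <- mean(a) * mean(b)
      for (i in seq_len(d)) {
        gi <- fBA[[i]][idx, out_j]
        for (j in seq_len(d)) {
          if (j == i) next
          # closed second-order index of the pair (i, j)
          S2[i, j] <- (mean(gi * fAB[[j]][idx, out_j]) - m0) / V
        }
      }
      S2 <- (S2 + t(S2)) / 2
    }
    list(S1 = S1, ST = ST, S2 = S2)
  }
  full <- est(seq_len(N), seq_len(n_out)[1])
  res <- vector("list", n_out)
  for (j in seq_len(n_out)) res[[j]] <- est(seq_len(N), j)
  # bootstrap standard errors over sample rows (first/total order only)
  se1 <- matrix(0, d, n_out); seT <- matrix(0, d, n_out)
  if (n_boot > 0) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed + 101L)
    b1 <- array(NA_real_, c(n_boot, d, n_out))
    bT <- array(NA_real_, c(n_boot, d, n_out))
    for (r in seq_len(n_boot)) {
      idx <- sample.int(N, N, replace = TRUE)
      for (j in seq_len(n_out)) {
        e <- est(idx, j)
        b1[r, , j] <- e$S1; bT[r, , j] <- e$ST
      }
    }
    for (j in seq_len(n_out)) {
      se1[, j] <- apply(b1[, , j, drop = FALSE], 2, sd)
      seT[, j] <- apply(bT[, , j, drop = FALSE], 2, sd)
    }
  }
  list(per_output = res, se1 = se1, seT = seT, N = N, d = d,
       n_outputs = n_out)
}

#' Variance-based (Sobol) sensitivity indices of the cascade model
#'
#' Estimates first-order, total-order and closed second-order sensitivity
#' indices of a model output (one biomarker at one DPS value) with respect
#' to the free cascade weights, by the Saltelli pick-freeze scheme on a
#' randomized Sobol' low-discrepancy design: `(2d + 2) N` model solves
#' with second order, `(d + 2) N` without.  Fixed (zero-valued) weights
#' are not sampled and receive indices of exactly 0.  Monte-Carlo standard
#' errors come from a bootstrap over sample rows.  Any sample whose
#' integration blows up aborts the run (silently dropping samples would
#' bias the indices).
#'
#' @param ranges a [make_ranges] object.
#' @param output list with `k` (biomarker id) and `s` (DPS value(s) in
#'   `(-10, 20]`); default cognition at s = 0.
#' @param N base sample size, a power of two (default 2^13).
#' @param seed integer seed for the randomized design (mandatory).
#' @param second_order estimate closed second-order indices as well?
#' @param model_fn optional test hook: a function taking an `n x d` matrix
#'   of free-weight draws and returning model outputs, replacing the ODE
#'   solve (used by estimator-validation tests).
#' @return a `sobol_result` object: data frame `indices` with one row per
#'   free parameter and columns `parameter`, `S1`, `ST`, `S1_se`, `ST_se`
#'   (plus one set per output point), matrix list `S2` (closed
#'   second-order) and `interaction` (`S2 - S1_i - S1_j`), `output`,
#'   `N`, `seed`.
#' @export
sobol_indices <- function(ranges, output = list(k = "C", s = 0), N = 2^13,
                          seed = 1L, second_order = TRUE, model_fn = NULL,
                          n_boot = 100L) {
  if (inherits(ranges, "param_ranges")) {
    free <- ranges$free
    lo <- ranges$lower[free]; hi <- ranges$upper[free]
    k <- match.arg(output$k, BIOMARKERS)
    s_targets <- as.numeric(output$s)
    if (any(s_targets <= S_MIN) || any(s_targets > S_MAX))
      stop("output DPS values must lie in (-10, 20]")
    base_w <- ranges$params$w
    y0 <- ranges$params$y0
    k_index <- match(k, BIOMARKERS) - 1L
    if (is.null(model_fn)) {
      model_fn <- function(X) {
        W <- matrix(rep(base_w, each = nrow(X)), nrow(X), 21)
        W[, match(free, W_NAMES)] <- X
        r <- .batch_eval_cpp(W, y0, s_targets, k_index)
        nbad <- sum(r$status != 0)
        if (nbad > 0)
          stop(nbad, " of ", nrow(X), " samples blew up during integration;",
               " the parameter ranges are inconsistent with the model")
        r$values
      }
    }
  } else {
    # raw interface for test hooks: ranges is list(lower=, upper=)
    lo <- ranges$lower; hi <- ranges$upper
    free <- names(lo)
    if (is.null(free)) free <- paste0("x", seq_along(lo))
    if (is.null(model_fn)) stop("model_fn is required with raw ranges")
    k <- output$k; s_targets <- output$s
  }
  sal <- .saltelli(lo, hi, model_fn, N, seed, second_order, n_boot)
  d <- length(free)
  idx_tabs <- lapply(seq_len(sal$n_outputs), function(j) {
    e <- sal$per_output[[j]]
    data.frame(parameter = free, S1 = e$S1, ST = e$ST,
               S1_se = sal$se1[, j], ST_se = sal$seT[, j],
               stringsAsFactors = FALSE)
  })
  S2 <- NULL; inter <- NULL
  if (second_order) {
    S2 <- lapply(seq_len(sal$n_outputs), function(j) {
      m <- sal$per_output[[j]]$S2
      dimnames(m) <- list(free, free)
      m
    })
    inter <- lapply(seq_len(sal$n_outputs), function(j) {
      e <- sal$per_output[[j]]
      m <- e$S2 - outer(e$S1, rep(1, d)) - outer(rep(1, d), e$S1)
      diag(m) <- NA_real_
      dimnames(m) <- list(free, free)
      m
    })
  }
  structure(list(indices = if (sal$n_outputs == 1L) idx_tabs[[1]] else idx_tabs,
                 S2 = if (!is.null(S2) && sal$n_outputs == 1L) S2[[1]] else S2,
                 interaction = if (!is.null(inter) && sal$n_outputs == 1L)
                   inter[[1]] else inter,
                 output = list(k = k, s = s_targets),
                 free = free, N = N, seed = seed),
            class = "sobol_result")
}

#' @export
print.sobol_result <- function(x, ...) {
  cat(sprintf("Sobol sensitivity of %s at s = %s (N = %d, seed %d)\n",
              x$output$k, paste(format(x$output$s), collapse = ", "),
              x$N, x$seed))
  tab <- if (is.data.frame(x$indices)) x$indices else x$indices[[1]]
  tab <- tab[order(-tab$S1), ]
  print(head(tab, 10), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Sensitivity dynamics along the DPS axis
#'
#' First-order (and total-order) indices of one biomarker's output at a
#' grid of DPS values, reusing a single Saltelli design: every ODE solve
#' is scored at all grid points at once.
#'
#' @inheritParams sobol_indices
#' @param s_grid DPS values in `(-10, 20]`.
#' @return list of `sobol_result`-style index tables, one per grid point,
#'   plus a long data frame `dynamics` with columns `s`, `parameter`,
#'   `S1`, `ST`.
#' @export
sensitivity_over_dps <- function(ranges, s_grid, N = 2^13, seed = 1L,
                                 k = "C", second_order = FALSE,
                                 n_boot = 0L) {
  res <- sobol_indices(ranges, output = list(k = k, s = s_grid), N = N,
                       seed = seed, second_order = second_order,
                       n_boot = n_boot)
  tabs <- if (is.data.frame(res$indices)) list(res$indices) else res$indices
  dyn <- do.call(rbind, lapply(seq_along(s_grid), function(j) {
    cbind(s = s_grid[j], tabs[[j]][, c("parameter", "S1", "ST")])
  }))
  list(result = res, dynamics = dyn, s_grid = s_grid)
}

#' Select parameters for personalization by first-order sensitivity
#'
#' Free parameters whose first-order index (clamped below at 0) reaches
#' the threshold, ordered by descending index.  The conventional output
#' for this screening is cognition at disease onset, C(0).
#'
#' @param result a [sobol_indices] result with a single output point.
#' @param tol threshold on the first-order index (default 0.01).
#' @return character vector of parameter names (possibly empty, with a
#'   warning).
#' @export
select_personalized <- function(result, tol = 0.01) {
  tab <- if (is.data.frame(result$indices)) result$indices
         else result$indices[[1]]
  s1 <- pmax(tab$S1, 0)
  sel <- tab$parameter[s1 >= tol]
  sel <- sel[order(-s1[s1 >= tol])]
  if (!length(sel)) warning("no parameter reaches the sensitivity threshold")
  sel
}
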