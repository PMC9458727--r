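#' Per-biomarker variance weight
#'
#' `sigma_k = RSS_k / | n_k - 2 I - 4 |`: the residual sum of squares of
#' biomarker `k` scaled by an absolute-valued degrees-of-freedom
#' correction (`2 I` for the per-subject DPS parameters plus 4).  These
#' weights balance the four biomarkers in the DPS refit step.
#'
#' @param rss residual sum of squares for biomarker `k`.
#' @param n_k number of observations of biomarker `k`.
#' @param n_subjects number of subjects `I`.
#' @return `sigma_k` (0, flagged via attribute `perfect`, when `rss` is 0).
#' @export
compute_sigma <- function(rss, n_k, n_subjects) {
  den <- abs(n_k - 2 * n_subjects - 4)
  if (den == 0)
    stop("degenerate design: |n_k - 2I - 4| = 0; the cohort is too small ",
         "for the variance weighting (n_k = ", n_k, ", I = ", n_subjects, ")")
  sigma <- rss / den
  attr(sigma, "perfect") <- rss == 0
  sigma
}

# ---- cohort helpers ---------------------------------------------------

.check_cohort <- function(cohort) {
  need <- c("subject_id", "age", "group", "biomarker", "value")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort is missing columns: ", paste(miss, collapse = ", "))
  if (!all(cohort$biomarker %in% BIOMARKERS))
    stop("biomarker codes must be A, T, N, C")
  if (any(!is.finite(cohort$age)) || any(cohort$age <= 0))
    stop("ages must be positive and finite")
  key <- paste(cohort$subject_id, cohort$age, cohort$biomarker)
  if (anyDuplicated(key))
    stop("duplicated (subject, age, biomarker) records at rows: ",
         paste(head(which(duplicated(key)), 5), collapse = ", "))
  invisible(cohort)
}

.dps_lookup <- function(dps) {
  stopifnot(all(c("subject_id", "alpha", "beta") %in% names(dps)))
  rownames(dps) <- as.character(dps$subject_id)
  dps
}

# DPS of every observation row under a dps table
.obs_s <- function(cohort, dps) {
  d <- .dps_lookup(dps)
  i <- match(as.character(cohort$subject_id), rownames(d))
  if (anyNA(i)) stop("dps parameters missing for some subjects")
  d$alpha[i] * cohort$age + d$beta[i]
}

# ---- population weight fit (alternating calibration, weight step) -----

# per-equation parameter names, in cascade order; y0 rides with the A block
.EQ_BLOCKS <- list(
  A = c("w_A0", "w_A1", "w_A2"),
  T = paste0("w_T", 0:5),
  N = paste0("w_N", 0:5),
  C = paste0("w_C", 0:5)
)

#' Fit the population weights given fixed DPS warps
#'
#' One weight-update pass: for each biomarker in cascade order A, T, N, C,
#' the block of weights entering that biomarker's equation (plus `y0` for
#' the amyloid block) is fitted by Levenberg-Marquardt nonlinear least
#' squares of the observations against the ODE solution evaluated at each
#' observation's DPS.  Upstream blocks are updated before downstream ones
#' so each equation sees current upstream dynamics.
#'
#' @param cohort long-format cohort (columns `subject_id`, `age`, `group`,
#'   `biomarker`, `value`).
#' @param dps data frame `subject_id`, `alpha`, `beta`.
#' @param w_init starting [cascade_params].
#' @param fit_y0 fit the initial amyloid level with the A block?
#' @return list with `params` ([cascade_params]), `rss` (named per
#'   biomarker), `flags` (character, e.g. underdetermined blocks).
#' @export
fit_weights <- function(cohort, dps, w_init, fit_y0 = TRUE) {
  .check_cohort(cohort)
  s_all <- .obs_s(cohort, dps)
  if (any(s_all < S_MIN - 1e-9) || any(s_all > S_MAX + 1e-9))
    stop("observations map outside the DPS domain [-10, 20]")
  w_cur <- w_init$w
  y0_cur <- w_init$y0
  flags <- character(0)
  rss <- setNames(numeric(4), BIOMARKERS)
  for (k in BIOMARKERS) {
    sel <- cohort$biomarker == k
    sk <- s_all[sel]; yk <- cohort$value[sel]
    block <- .EQ_BLOCKS[[k]]
    par0 <- w_cur[block]
    # box on candidate weights: reference-scale dynamics are O(0.1-4) per
    # unit DPS, and unbounded candidates drive the solver into blow-up
    lower <- rep(-10, length(par0)); upper <- rep(10, length(par0))
    par0 <- pmin(pmax(par0, lower), upper)
    if (k == "A" && fit_y0) {
      par0 <- c(par0, y0 = log(y0_cur))
      lower <- c(lower, log(1e-8)); upper <- c(upper, log(1))
    }
    if (length(yk) <= length(par0)) {
      flags <- c(flags, paste0("biomarker ", k,
                               ": underdetermined (", length(yk),
                               " observations for ", length(par0),
                               " parameters); block left at its start"))
      rss[k] <- NA_real_
      next
    }
    resid_fn <- function(p) {
      wtry <- w_cur
      wtry[block] <- p[seq_along(block)]
      ytry <- if (k == "A" && fit_y0) exp(p[length(p)]) else y0_cur
      vals <- .f_all_at(sk, structure(list(w = wtry, y0 = ytry),
                                      class = "cascade_params"),
                        clamp = TRUE)
      yk - vals[, k]
    }
    # multi-start: the current block values can sit on a blow-up plateau
    # after a bad round, so a generic logistic restart is always tried too
    starts <- list(par0)
    gen <- .default_w_init()$w[block]
    gen_par <- if (k == "A" && fit_y0) c(gen, y0 = log(1e-4)) else gen
    if (max(abs(gen_par - par0)) > 1e-8) starts <- c(starts, list(gen_par))
    best <- NULL
    for (st in starts) {
      fit <- tryCatch(
        suppressWarnings(
          minpack.lm::nls.lm(par = st, fn = resid_fn, lower = lower,
                             upper = upper,
                             control = minpack.lm::nls.lm.control(
                               maxiter = 50, ftol = 1e-10, ptol = 1e-10))),
        error = function(e) NULL)
      if (is.null(fit)) next
      if (is.null(best) || sum(fit$fvec^2) < sum(best$fvec^2)) best <- fit
    }
    if (is.null(best))
      stop("weight fit failed for biomarker ", k)
    w_cur[block] <- best$par[seq_along(block)]
    if (k == "A" && fit_y0) y0_cur <- exp(best$par[length(best$par)])
    rss[k] <- sum(best$fvec^2)
  }
  list(params = cascade_params(w_cur, y0_cur), rss = rss, flags = flags)
}

# ---- per-subject DPS fit (alternating calibration, DPS step) ----------

#' Fit one subject's DPS warp against the current model
#'
#' Minimizes the sigma-weighted squared error of the subject's
#' observations against the model solution over `(alpha, beta)`, with
#' `alpha` constrained to `(0, 4]` and `beta` such that every observed
#' visit maps into the DPS domain `[-10, 20]`.  A coarse feasible grid
#' search supplies the start; Nelder-Mead polishes it with an infeasibility
#' penalty.  If no warp is feasible, the boundary solution is returned
#' flagged.
#'
#' @param ages,biomarkers,values the subject's observations (parallel
#'   vectors).
#' @param params current [cascade_params].
#' @param sigma named per-biomarker variance weights; non-finite or zero
#'   entries fall back to unweighted.
#' @param traj optional precomputed dense [solve_model] trajectory for
#'   `params` (an optimization when fitting many subjects).
#' @return list `alpha`, `beta`, `objective`, `boundary` flag.
#' @export
fit_dps <- function(ages, biomarkers, values, params, sigma = NULL,
                    traj = NULL) {
  stopifnot(length(ages) == length(values),
            length(biomarkers) == length(values))
  if (length(ages) < 2) stop("subject must have at least 2 observations")
  if (is.null(traj)) traj <- .dense_solution(params)
  wts <- rep(1, 4); names(wts) <- BIOMARKERS
  if (!is.null(sigma)) {
    sg <- sigma[BIOMARKERS]
    use <- is.finite(sg) & sg > 0
    wts[use] <- 1 / sg[use]
  }
  wobs <- wts[biomarkers]
  kcol <- match(biomarkers, BIOMARKERS)
  t_min <- min(ages); t_max <- max(ages)
  grid_s <- traj$s
  dx <- grid_s[2] - grid_s[1]
  n_obs <- length(ages)
  # fast linear interpolation of the dense trajectory at a vector of s,
  # per-observation biomarker column
  interp <- function(s) {
    i <- pmin.int(pmax.int(floor((s - grid_s[1]) / dx) + 1, 1),
                  length(grid_s) - 1L)
    frac <- (s - grid_s[i]) / dx
    v0 <- traj$values[cbind(i, kcol)]
    v1 <- traj$values[cbind(i + 1L, kcol)]
    v0 + frac * (v1 - v0)
  }
  obj <- function(alpha, beta) {
    s <- alpha * ages + beta
    if (any(s < S_MIN) || any(s > S_MAX)) return(Inf)
    sum(wobs * (values - interp(s))^2)
  }
  # coarse feasible grid, fully vectorized over (alpha, beta) candidates
  alphas <- seq(0.05, 4, length.out = 24)
  cand_a <- numeric(0); cand_b <- numeric(0)
  for (a in alphas) {
    b_lo <- S_MIN - a * t_min
    b_hi <- S_MAX - a * t_max
    if (b_hi < b_lo) next
    bb <- seq(b_lo, b_hi, length.out = 24)
    cand_a <- c(cand_a, rep(a, length(bb))); cand_b <- c(cand_b, bb)
  }
  best <- list(val = Inf, alpha = alphas[1], beta = S_MIN - alphas[1] * t_min)
  if (length(cand_a)) {
    S <- outer(ages, cand_a) + matrix(cand_b, n_obs, length(cand_a),
                                      byrow = TRUE)
    S[S < S_MIN | S > S_MAX] <- NA
    i <- pmin.int(pmax.int(floor((S - grid_s[1]) / dx) + 1, 1),
                  length(grid_s) - 1L)
    frac <- (S - grid_s[i]) / dx
    kmat <- matrix(kcol, n_obs, length(cand_a))
    v0 <- matrix(traj$values[cbind(as.vector(i), as.vector(kmat))],
                 n_obs, length(cand_a))
    v1 <- matrix(traj$values[cbind(as.vector(i + 1L), as.vector(kmat))],
                 n_obs, length(cand_a))
    fv <- v0 + frac * (v1 - v0)
    objs <- colSums(wobs * (values - fv)^2)
    objs[colSums(is.na(S)) > 0] <- Inf
    j <- which.min(objs)
    if (is.finite(objs[j]))
      best <- list(val = objs[j], alpha = cand_a[j], beta = cand_b[j])
  }
  # local refinement of the coarse optimum on a shrinking grid
  if (is.finite(best$val)) {
    da <- diff(range(alphas)) / 23; db <- 30 / 23
    for (r in 1:3) {
      aa <- seq(max(best$alpha - da, 1e-3), min(best$alpha + da, 4),
                length.out = 9)
      bb <- seq(best$beta - db, best$beta + db, length.out = 9)
      for (a in aa) for (b in bb) {
        v <- obj(a, b)
        if (v < best$val) best <- list(val = v, alpha = a, beta = b)
      }
      da <- da / 4; db <- db / 4
    }
  }
  boundary <- !is.finite(best$val)
  pen_obj <- function(p) {
    a <- p[1]; b <- p[2]
    if (a <= 1e-4 || a > 4) return(1e8 + a^2)
    s <- a * ages + b
    pen <- sum(pmax(S_MIN - s, 0)^2 + pmax(s - S_MAX, 0)^2)
    if (pen > 0) return(1e6 * (1 + pen))
    obj(a, b)
  }
  fit <- optim(c(best$alpha, best$beta), pen_obj, method = "Nelder-Mead",
               control = list(maxit = 400, reltol = 1e-12))
  alpha <- best$alpha; beta <- best$beta; val <- best$val
  a_cl <- min(max(fit$par[1], 1e-4), 4)
  v_cl <- obj(a_cl, fit$par[2])   # feasibility re-checked after clamping
  if (is.finite(v_cl) && v_cl <= val) {
    alpha <- a_cl; beta <- fit$par[2]; val <- v_cl
  }
  list(alpha = alpha, beta = beta, objective = val, boundary = boundary)
}

# ---- alternating population calibration -------------------------------

# generic weakly-informative start: logistic self-dynamics with a weak
# quadratic upstream drive, shaped so the four transitions stagger across
# the whole DPS domain (amyloid first, cognition still rising at the
# right edge) -- the qualitative biomarker-cascade premise.  A start
# whose entire dynamic range collapses into a few DPS units starves the
# initial subject alignment of resolution.
.default_w_init <- function() {
  w <- setNames(numeric(21), W_NAMES)
  w[c("w_A1", "w_T1", "w_N1")] <- 0.7
  w[c("w_A2", "w_T2", "w_N2")] <- -0.7
  w["w_C1"] <- 0.15; w["w_C2"] <- -0.07
  w[c("w_T4", "w_N4")] <- 0.15
  w["w_C3"] <- 0.05
  cascade_params(w, y0 = 1e-4)
}

#' Alternating population calibration
#'
#' Alternates the population weight fit ([fit_weights]), the variance
#' weights ([compute_sigma]) and the per-subject DPS fits ([fit_dps]) for
#' up to `L` outer rounds, stopping early when the relative objective
#' change falls below `tol`.  When no initialization is given, each
#' subject's progression rate `alpha` is drawn uniformly from (0, 4) and
#' the offset `beta` uniformly from the interval keeping all the
#' subject's visits inside the DPS domain; the weights start at a generic
#' weakly-informative cascade.
#'
#' @param cohort long-format cohort table.
#' @param init optional list with elements `w` ([cascade_params]) and/or
#'   `dps` (data frame `subject_id`, `alpha`, `beta`).
#' @param L maximum outer rounds (default 10).
#' @param seed integer seed for the random initialization.
#' @param tol relative objective change for early stop (default 1e-6).
#' @param fit_y0 passed to [fit_weights].
#' @return an object of class `calibration_state`: list with `params`,
#'   `dps`, `sigma`, `objective`, `history` (per-round objective), `rounds`,
#'   `flags`.
#' @export
calibrate <- function(cohort, init = NULL, L = 10L, seed = 1L, tol = 1e-6,
                      fit_y0 = TRUE, trace = FALSE) {
  .check_cohort(cohort)
  subjects <- unique(cohort$subject_id)
  I <- length(subjects)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  if (!is.null(init$dps)) {
    dps <- .dps_lookup(init$dps)
  } else {
    alpha <- runif(I, 0, 4)
    beta <- numeric(I)
    for (i in seq_len(I)) {
      ages <- cohort$age[cohort$subject_id == subjects[i]]
      b_lo <- S_MIN - alpha[i] * min(ages)
      b_hi <- S_MAX - alpha[i] * max(ages)
      while (b_hi < b_lo) {  # too fast for the visit span: redraw
        alpha[i] <- runif(1, 0, 4)
        b_lo <- S_MIN - alpha[i] * min(ages)
        b_hi <- S_MAX - alpha[i] * max(ages)
      }
      beta[i] <- runif(1, b_lo, b_hi)
    }
    dps <- .dps_lookup(data.frame(subject_id = subjects, alpha = alpha,
                                  beta = beta))
  }
  w <- if (!is.null(init$w)) init$w else .default_w_init()
  sigma <- setNames(rep(NA_real_, 4), BIOMARKERS)
  history <- numeric(0)
  flags <- character(0)
  obj_prev <- Inf
  rounds <- 0L
  # alignment pass: place every subject on the initial model's axis by an
  # unweighted DPS fit before the first weight update; a weight fit
  # against completely random warps would only learn noise
  if (L > 0 && is.null(init$dps)) {
    traj0 <- .dense_solution(w, clamp = TRUE)
    for (i in seq_len(I)) {
      sel <- cohort$subject_id == subjects[i]
      fd <- fit_dps(cohort$age[sel], cohort$biomarker[sel],
                    cohort$value[sel], w, NULL, traj = traj0)
      dps[as.character(subjects[i]), c("alpha", "beta")] <-
        c(fd$alpha, fd$beta)
    }
  }
  if (L > 0) for (l in seq_len(L)) {
    rounds <- l
    wf <- tryCatch(fit_weights(cohort, dps, w, fit_y0 = fit_y0),
                   error = function(e)
                     stop("round ", l, ": ", conditionMessage(e)))
    w <- wf$params
    flags <- union(flags, wf$flags)
    nk <- table(factor(cohort$biomarker, BIOMARKERS))
    for (k in BIOMARKERS)
      sigma[k] <- if (is.na(wf$rss[k])) NA_real_
                  else compute_sigma(wf$rss[k], as.integer(nk[k]), I)
    traj <- .dense_solution(w, clamp = TRUE)
    obj_round <- 0
    for (i in seq_len(I)) {
      sel <- cohort$subject_id == subjects[i]
      fd <- fit_dps(cohort$age[sel], cohort$biomarker[sel],
                    cohort$value[sel], w, sigma, traj = traj)
      dps[as.character(subjects[i]), c("alpha", "beta")] <-
        c(fd$alpha, fd$beta)
      obj_round <- obj_round + fd$objective
    }
    # gauge fixing: the model admits an exact invariance
    # s -> -10 + a (s + 10), w -> w / a, alpha -> a alpha, under which the
    # fit is unchanged; left free, the alternation drifts along this
    # valley into poorly conditioned time scales.  Renormalize each round
    # to the convention mean(alpha) = 1 (one DPS unit per year for the
    # average subject), capped so every visit stays inside the domain and
    # every alpha inside (0, 4].
    a_fix <- 1 / mean(dps$alpha)
    s_cur <- .obs_s(cohort, dps)
    a_max <- min(4 / max(dps$alpha),
                 (S_MAX - S_MIN) / (max(s_cur) + 10 + 1e-9))
    # gentle per-round steps: a hard renormalization of a state that is
    # not yet gauge-symmetric would throw the iterate out of its basin
    a_fix <- min(max(a_fix, 0.7), 1.4, a_max)
    if (is.finite(a_fix) && a_fix > 0 && abs(a_fix - 1) > 1e-12) {
      dps$alpha <- a_fix * dps$alpha
      dps$beta <- a_fix * dps$beta + 10 * (a_fix - 1)
      w <- cascade_params(w$w / a_fix, w$y0)
    }
    history <- c(history, obj_round)
    # early stop on the unweighted residual sum, which is insensitive to
    # round-to-round rescaling of the sigma weights
    s_now <- .obs_s(cohort, dps)
    vals <- .f_all_at(s_now, w, clamp = TRUE)
    rss_now <- sum((cohort$value -
                    vals[cbind(seq_len(nrow(cohort)),
                               match(cohort$biomarker, BIOMARKERS))])^2)
    if (trace)
      message(sprintf(
        "round %d: rss(after weights) %.4g | rss(after dps) %.4g | sigma %s",
        l, sum(wf$rss, na.rm = TRUE), rss_now,
        paste(sprintf("%.3g", sigma), collapse = "/")))
    if (l >= 3L && is.finite(obj_prev) &&
        abs(obj_prev - rss_now) <= tol * max(obj_prev, 1e-12)) {
      obj_prev <- rss_now
      break
    }
    obj_prev <- rss_now
  }
  structure(list(params = w, dps = dps[, c("subject_id", "alpha", "beta")],
                 sigma = sigma,
                 objective = if (length(history)) tail(history, 1) else NA,
                 history = history, rounds = rounds, flags = flags,
                 seed = seed),
            class = "calibration_state")
}

#' @export
print.calibration_state <- function(x, ...) {
  cat(sprintf("population calibration: %d rounds, objective %.6g\n",
              x$rounds, x$objective))
  cat("  sigma:", paste(sprintf("%s=%.3g", names(x$sigma), x$sigma),
                        collapse = " "), "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Refit the weights on a cohort subset with DPS held fixed
#'
#' One [fit_weights] pass on a subset of the cohort (for instance the
#' LMCI and AD groups only), reusing previously calibrated per-subject
#' DPS warps without updating them.
#'
#' @param cohort cohort subset (long format).
#' @param dps calibrated DPS table covering every subject in the subset.
#' @param w_init starting [cascade_params].
#' @inheritParams fit_weights
#' @return as [fit_weights].
#' @export
refit_weights_fixed_dps <- function(cohort, dps, w_init, fit_y0 = TRUE) {
  if (nrow(cohort) == 0) stop("empty cohort subset")
  missing <- setdiff(as.character(unique(cohort$subject_id)),
                     as.character(dps$subject_id))
  if (length(missing))
    stop("no DPS parameters for subjects: ",
         paste(missing, collapse = ", "))
  fit_weights(cohort, dps, w_init, fit_y0 = fit_y0)
}

#' Residual-bootstrap uncertainty band for the population trajectory
#'
#' Resamples per-biomarker residuals of the calibrated model onto the
#' fitted values, refits the population weights (DPS fixed) on each
#' replicate, solves each refit, and returns pointwise quantile bands per
#' biomarker over a DPS grid.
#'
#' @param cohort calibrated cohort.
#' @param state a [calibrate] result.
#' @param B number of bootstrap replicates (>= 20).
#' @param coverage pointwise coverage level (default 0.95).
#' @param s_grid DPS grid for the band (default 121 points).
#' @param seed integer seed.
#' @return list with `s`, and per biomarker a matrix with columns `lower`,
#'   `upper`, `center`.
#' @export
bootstrap_band <- function(cohort, state, B = 200L, coverage = 0.95,
                           s_grid = seq(S_MIN, S_MAX, length.out = 121),
                           seed = 1L) {
  if (B < 20) stop("B must be at least 20 for a meaningful interval")
  .check_cohort(cohort)
  # canonical observation order makes the band invariant to the row order
  # of the input table
  cohort <- cohort[order(cohort$subject_id, cohort$age, cohort$biomarker), ]
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  s_obs <- .obs_s(cohort, state$dps)
  vals <- .f_all_at(s_obs, state$params, clamp = TRUE)
  fitted <- vals[cbind(seq_len(nrow(cohort)),
                       match(cohort$biomarker, BIOMARKERS))]
  resid <- cohort$value - fitted
  sols <- array(NA_real_, c(B, length(s_grid), 4))
  for (b in seq_len(B)) {
    boot <- cohort
    for (k in BIOMARKERS) {
      sel <- which(cohort$biomarker == k)
      boot$value[sel] <- fitted[sel] + sample(resid[sel], length(sel),
                                              replace = TRUE)
    }
    wf <- fit_weights(boot, state$dps, state$params)
    # clamped solve: an occasional replicate can diverge when extrapolated
    # beyond the observed DPS range; quantiles are robust to such tails
    sols[b, , ] <- .solve_cascade_cpp(wf$params$w, wf$params$y0, s_grid,
                                      s0 = S_MIN, rtol = 1e-8, atol = 1e-10,
                                      guard = 1e3, clamp = TRUE)
  }
  a <- (1 - coverage) / 2
  center <- solve_model(state$params, s_grid)$values
  out <- list(s = s_grid)
  for (k in BIOMARKERS) {
    j <- match(k, BIOMARKERS)
    lo <- apply(sols[, , j, drop = FALSE], 2, quantile, probs = a)
    hi <- apply(sols[, , j, drop = FALSE], 2, quantile, probs = 1 - a)
    out[[k]] <- cbind(lower = lo, upper = hi, center = center[, k])
  }
  out
}
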