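#' Leave-last-visit-out prediction accuracy
#'
#' `PA = 100 (1 - |prediction - actual| / |actual|)` percent: 100 when the
#' prediction matches the held-out value exactly, lower (possibly
#' negative) as the relative error grows; overshoot and undershoot are
#' penalized symmetrically.  Undefined (NA) when the held-out value is 0.
#'
#' @param actual held-out observed (denoised) value.
#' @param prediction model forecast at the held-out visit.
#' @return accuracy in percent, or NA if `actual` is 0.
#' @export
prediction_accuracy <- function(actual, prediction) {
  ifelse(actual == 0, NA_real_,
         100 * (1 - abs(prediction - actual) / abs(actual)))
}

# visit structure of one subject: unique ages, sorted
.subject_visits <- function(ages) sort(unique(ages))

# raw value matrix (visit x biomarker) for one subject
.visit_matrix <- function(ages, biomarkers, values, alpha, beta) {
  vis <- .subject_visits(ages)
  s <- alpha * vis + beta
  out <- matrix(NA_real_, length(vis), 4, dimnames = list(NULL, BIOMARKERS))
  for (k in BIOMARKERS) {
    sel <- biomarkers == k
    if (!any(sel)) next
    out[match(ages[sel], vis), k] <- values[sel]
  }
  list(visits = vis, s = s, values = out)
}

# denoised value matrix (visit x biomarker) for one subject; falls back to
# raw values when the per-subject sigmoid fit fails
.denoise_matrix <- function(ages, biomarkers, values, alpha, beta) {
  vis <- .subject_visits(ages)
  s <- alpha * vis + beta
  out <- matrix(NA_real_, length(vis), 4, dimnames = list(NULL, BIOMARKERS))
  fallback <- setNames(logical(4), BIOMARKERS)
  for (k in BIOMARKERS) {
    sel <- biomarkers == k
    if (!any(sel)) next
    iv <- match(ages[sel], vis)
    raw <- rep(NA_real_, length(vis))
    raw[iv] <- values[sel]
    dn <- denoise_subject(s[iv], values[sel])
    out[iv, k] <- dn$fitted
    fallback[k] <- dn$fallback
  }
  list(visits = vis, s = s, values = out, fallback = fallback)
}

#' Subjects eligible for personalization
#'
#' A subject qualifies when (1) every one of the four biomarkers has at
#' least `min_visits` observations, and (2) each biomarker's denoised
#' values change weakly monotonically with DPS (direction free per
#' biomarker, ties allowed).
#'
#' @param cohort long-format cohort.
#' @param dps calibrated DPS table.
#' @param min_visits minimum observations per biomarker (default 4).
#' @return character vector of subject ids.
#' @export
eligible_subjects <- function(cohort, dps, min_visits = 4L) {
  .check_cohort(cohort)
  d <- .dps_lookup(dps)
  keep <- character(0)
  for (id in unique(cohort$subject_id)) {
    sel <- cohort$subject_id == id
    cnt <- table(factor(cohort$biomarker[sel], BIOMARKERS))
    if (any(cnt < min_visits)) next
    di <- d[as.character(id), ]
    dn <- .denoise_matrix(cohort$age[sel], cohort$biomarker[sel],
                          cohort$value[sel], di$alpha, di$beta)
    mono <- TRUE
    for (k in BIOMARKERS) {
      v <- dn$values[!is.na(dn$values[, k]), k]
      if (length(v) >= 2) {
        dv <- diff(v)
        if (!(all(dv >= 0) || all(dv <= 0))) { mono <- FALSE; break }
      }
    }
    if (mono) keep <- c(keep, as.character(id))
  }
  keep
}

#' Personalized refit of the sensitive parameter subset
#'
#' Refits only the sensitivity-selected parameters for one subject,
#' starting from (and elsewhere pinned exactly to) the population values,
#' by least squares of the subject's first `M - 1` observed visits over
#' all four biomarkers jointly (the sensitive set spans several
#' equations, so a joint objective is the only self-consistent choice).
#' Fitting and scoring use the raw observed values; the sigmoid
#' denoising enters only the eligibility screening.
#' Each sensitive parameter is box-constrained to 50--150% of its
#' population value (sign-aware) to prevent runaway fits on very short
#' series.  The DPS warp is held fixed.
#'
#' @param ages,biomarkers,values the subject's observations.
#' @param w_pop population [cascade_params].
#' @param sensitive character vector of weight names to personalize.
#' @param alpha,beta the subject's DPS warp.
#' @return an object of class `personalized_fit`: list with `params`
#'   (personalized [cascade_params]), `sensitive`, `w2` (their values),
#'   `data` (visit-by-biomarker value matrix), `M` (visit count),
#'   `s` (visit DPS), `flag`.
#' @export
fit_personalized <- function(ages, biomarkers, values, w_pop, sensitive,
                             alpha, beta) {
  dn <- .visit_matrix(ages, biomarkers, values, alpha, beta)
  M <- length(dn$visits)
  if (M < 4) stop("subject must have at least 4 visits")
  if (!length(sensitive)) {
    return(structure(list(params = w_pop, sensitive = character(0),
                          w2 = numeric(0), data = dn, M = M, s = dn$s,
                          flag = "empty sensitive set"),
                     class = "personalized_fit"))
  }
  stopifnot(all(sensitive %in% W_NAMES))
  train <- seq_len(M - 1)
  s_tr <- dn$s[train]
  ymat <- dn$values[train, , drop = FALSE]
  par0 <- w_pop$w[sensitive]
  lower <- pmin(0.5 * par0, 1.5 * par0)
  upper <- pmax(0.5 * par0, 1.5 * par0)
  resid_fn <- function(p) {
    wtry <- w_pop$w
    wtry[sensitive] <- p
    vals <- .f_all_at(s_tr, structure(list(w = wtry, y0 = w_pop$y0),
                                      class = "cascade_params"),
                      clamp = TRUE)
    r <- ymat - vals
    r[!is.na(r)]
  }
  fit <- suppressWarnings(
    minpack.lm::nls.lm(par = par0, fn = resid_fn, lower = lower,
                       upper = upper,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 100, ftol = 1e-10, ptol = 1e-10)))
  w2 <- fit$par
  wout <- w_pop$w
  wout[sensitive] <- w2
  structure(list(params = cascade_params(wout, w_pop$y0),
                 sensitive = sensitive, w2 = setNames(w2, sensitive),
                 data = dn, M = M, s = dn$s, flag = NULL),
            class = "personalized_fit")
}

#' Score a personalized fit on the held-out last visit
#'
#' Evaluates the personalized model at the subject's last-visit DPS and
#' scores each biomarker with [prediction_accuracy] against the raw
#' held-out value; also scores the sigmoid baseline
#' ([sigmoid_predict_last]) on the same held-out point when enough visits
#' are available.
#'
#' @param fit a [fit_personalized] result.
#' @param scale_spec clinical-unit anchors used for scoring (see
#'   [to_clinical_scale]); accuracies are computed on clinical units,
#'   where relative error is meaningful (a normalized value near 0 --
#'   e.g. ADAS of a healthy subject -- would make the relative error
#'   blow up although the absolute error is tiny).  Pass `NULL` to score
#'   on the normalized scale directly.
#' @return data frame with one row per biomarker: `biomarker`, `actual`,
#'   `predicted` (both normalized), `pa_ode`, `pa_sigmoid` (NA when the
#'   baseline needs more visits or the held-out value is 0).
#' @export
predict_and_score <- function(fit, scale_spec = .DEFAULT_SCALE) {
  dn <- fit$data
  M <- fit$M
  sM <- dn$s[M]
  pred <- .f_all_at(sM, fit$params, clamp = TRUE)[1, ]
  clin <- function(x, k) {
    if (is.null(scale_spec)) return(x)
    row <- scale_spec[scale_spec$biomarker == k, ]
    if (row$flip) x <- 1 - x
    row$low + x * (row$high - row$low)
  }
  out <- data.frame(biomarker = BIOMARKERS, actual = NA_real_,
                    predicted = NA_real_, pa_ode = NA_real_,
                    pa_sigmoid = NA_real_, stringsAsFactors = FALSE)
  for (k in BIOMARKERS) {
    j <- match(k, BIOMARKERS)
    yM <- dn$values[M, k]
    if (is.na(yM)) next
    out$actual[j] <- yM
    out$predicted[j] <- pred[j]
    out$pa_ode[j] <- prediction_accuracy(clin(yM, k), clin(pred[j], k))
    obs <- which(!is.na(dn$values[, k]))
    if (length(obs) >= 5 && obs[length(obs)] == M) {
      sp <- tryCatch(
        sigmoid_predict_last(dn$s[obs], dn$values[obs, k]),
        error = function(e) NULL)
      if (!is.null(sp))
        out$pa_sigmoid[j] <- prediction_accuracy(clin(sp$actual, k),
                                                 clin(sp$prediction, k))
    }
  }
  out
}

#' Cohort-level personalization report
#'
#' Runs eligibility screening, the personalized refit and the held-out
#' scoring for every eligible subject, and summarizes per-biomarker
#' prediction accuracy (model and sigmoid baseline) with group means and
#' standard deviations.
#'
#' @param cohort long-format cohort.
#' @param w_pop population [cascade_params].
#' @param sensitive personalized parameter names (typically from
#'   [select_personalized]).
#' @param dps calibrated DPS table.
#' @param scale_spec clinical anchors for scoring (see
#'   [predict_and_score]).
#' @return list with `table` (one row per subject: id, group, visit count,
#'   DPS span, PA columns) and `summary` (per group: mean and SD per PA
#'   column).
#' @export
cohort_personalization_report <- function(cohort, w_pop, sensitive, dps,
                                          scale_spec = .DEFAULT_SCALE) {
  elig <- eligible_subjects(cohort, dps)
  if (!length(elig)) {
    warning("no eligible subjects")
    return(list(table = data.frame(), summary = data.frame()))
  }
  d <- .dps_lookup(dps)
  rows <- list()
  for (id in elig) {
    sel <- cohort$subject_id == id
    di <- d[as.character(id), ]
    fit <- tryCatch(
      fit_personalized(cohort$age[sel], cohort$biomarker[sel],
                       cohort$value[sel], w_pop, sensitive,
                       di$alpha, di$beta),
      error = function(e) NULL)
    if (is.null(fit)) next
    sc <- predict_and_score(fit, scale_spec)
    grp <- cohort$group[sel][1]
    rows[[id]] <- data.frame(
      subject_id = id, group = grp, n_visits = fit$M,
      dps_span = diff(range(fit$s)),
      pa_ode_A = sc$pa_ode[1], pa_ode_T = sc$pa_ode[2],
      pa_ode_N = sc$pa_ode[3], pa_ode_C = sc$pa_ode[4],
      pa_sig_A = sc$pa_sigmoid[1], pa_sig_T = sc$pa_sigmoid[2],
      pa_sig_N = sc$pa_sigmoid[3], pa_sig_C = sc$pa_sigmoid[4],
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  pa_cols <- grep("^pa_", names(tab), value = TRUE)
  summ <- do.call(rbind, lapply(split(tab, tab$group), function(g) {
    data.frame(group = g$group[1], n = nrow(g),
               t(vapply(pa_cols, function(cc)
                 c(mean = mean(g[[cc]], na.rm = TRUE),
                   sd = if (nrow(g) > 1) sd(g[[cc]], na.rm = TRUE) else 0),
                 c(mean = 0, sd = 0))))
  }))
  list(table = tab, summary = summ)
}
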