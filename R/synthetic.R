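#' Configuration for the synthetic ADNI-like cohort generator
#'
#' Defines the study conditions the generator emulates: three diagnostic
#' groups with ADNI-1-like proportions, baseline ages near 75 +/- 7 years,
#' per-subject linear DPS warps with progression rates in a realistic
#' range, group-dependent baseline disease stage (CN before onset, LMCI
#' around onset, AD after), 2--6 irregular visits per subject, additive
#' Gaussian observation noise on the normalized scale and independent
#' per-biomarker missingness.
#'
#' @param n_subjects number of subjects.
#' @param group_props named proportions for CN/LMCI/AD (default the
#'   ADNI-1 shares 229/398/192).
#' @param truth generating [cascade_params] (default the bundled LMCI+AD
#'   reference column).
#' @param alpha_range uniform range of progression rates (DPS/year).
#' @param age_mean,age_sd,age_bounds baseline-age distribution (years),
#'   truncated.
#' @param dps_baseline named list of `c(mean, sd)` baseline DPS per group.
#' @param visit_range integer range of visits per subject.
#' @param spacing_range uniform range of visit spacing (years).
#' @param noise_sd per-biomarker Gaussian noise SD on the normalized
#'   scale (scalar or named vector).
#' @param miss_prob per-biomarker missingness probability (scalar or
#'   named vector).
#' @param seed mandatory integer seed.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_subjects = 100L,
                             group_props = c(CN = 229, LMCI = 398,
                                             AD = 192) / 819,
                             truth = reference_params("lmci_ad"),
                             alpha_range = c(0.5, 2.0),
                             age_mean = 75, age_sd = 7,
                             age_bounds = c(55, 90),
                             dps_baseline = list(CN = c(-5, 2),
                                                 LMCI = c(0, 2),
                                                 AD = c(5, 2)),
                             visit_range = c(2L, 6L),
                             spacing_range = c(0.5, 1.5),
                             noise_sd = 0.03,
                             miss_prob = 0.05,
                             seed) {
  if (missing(seed) || !is.numeric(seed))
    stop("an integer seed is mandatory")
  if (abs(sum(group_props) - 1) > 1e-8)
    stop("group proportions must sum to 1")
  if (any(noise_sd < 0) || any(miss_prob < 0) || any(miss_prob >= 1))
    stop("noise SDs must be >= 0 and missingness probabilities in [0, 1)")
  stopifnot(is_cascade_params(truth))
  expand <- function(x) {
    if (length(x) == 1) setNames(rep(x, 4), BIOMARKERS) else x[BIOMARKERS]
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 group_props = group_props, truth = truth,
                 alpha_range = alpha_range, age_mean = age_mean,
                 age_sd = age_sd, age_bounds = age_bounds,
                 dps_baseline = dps_baseline,
                 visit_range = as.integer(visit_range),
                 spacing_range = spacing_range,
                 noise_sd = expand(noise_sd),
                 miss_prob = expand(miss_prob),
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a synthetic longitudinal cohort with known ground truth
#'
#' For each subject: draws a diagnostic group, a progression rate
#' `alpha`, a baseline age and a group-dependent baseline DPS; derives
#' `beta = s_baseline - alpha * age_baseline`; samples irregular visit
#' ages; computes the latent biomarker values by solving the truth model
#' at each visit's DPS; adds Gaussian noise; and removes individual
#' (visit, biomarker) cells independently with the missingness
#' probability.  Baseline DPS draws are truncated so every visit stays
#' inside the model domain `[-10, 20]`.
#'
#' @param config a [generator_config].
#' @return list with `cohort` (long-format data frame: `subject_id`,
#'   `age`, `group`, `biomarker`, `value`), and `truth` (list with
#'   `params`, `dps` table, and `latent` long-format noise-free values).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)
  n <- config$n_subjects
  groups <- sample(names(config$group_props), n, replace = TRUE,
                   prob = config$group_props)
  rows <- list(); lat_rows <- list()
  dps <- data.frame(subject_id = character(n), alpha = numeric(n),
                    beta = numeric(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    id <- sprintf("S%04d", i)
    alpha <- runif(1, config$alpha_range[1], config$alpha_range[2])
    repeat {
      t0 <- rnorm(1, config$age_mean, config$age_sd)
      if (t0 >= config$age_bounds[1] && t0 <= config$age_bounds[2]) break
    }
    nv <- sample(seq(config$visit_range[1], config$visit_range[2]), 1)
    gaps <- runif(max(nv - 1, 0), config$spacing_range[1],
                  config$spacing_range[2])
    ages <- t0 + c(0, cumsum(gaps))
    span <- alpha * (max(ages) - t0)
    gb <- config$dps_baseline[[groups[i]]]
    repeat {
      s0 <- rnorm(1, gb[1], gb[2])
      if (s0 > S_MIN + 0.5 && s0 + span < S_MAX - 0.5) break
    }
    beta <- s0 - alpha * t0
    dps$subject_id[i] <- id; dps$alpha[i] <- alpha; dps$beta[i] <- beta
    s <- alpha * ages + beta
    latent <- .f_all_at(s, config$truth)
    for (k in BIOMARKERS) {
      j <- match(k, BIOMARKERS)
      noisy <- latent[, j] + rnorm(nv, 0, config$noise_sd[k])
      keep <- runif(nv) >= config$miss_prob[k]
      if (any(keep)) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = id, age = ages[keep], group = groups[i],
          biomarker = k, value = noisy[keep], stringsAsFactors = FALSE)
      }
      lat_rows[[length(lat_rows) + 1L]] <- data.frame(
        subject_id = id, age = ages, group = groups[i], biomarker = k,
        value = latent[, j], stringsAsFactors = FALSE)
    }
  }
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL
  latent <- do.call(rbind, lat_rows)
  rownames(latent) <- NULL
  list(cohort = cohort,
       truth = list(params = config$truth, dps = dps, latent = latent))
}

# default clinical anchors: ADNI-1 CN and AD group means (CSF Abeta42 and
# hippocampal volume decrease with disease, so their latent map is flipped)
.DEFAULT_SCALE <- data.frame(
  biomarker = c("A", "T", "N", "C"),
  low = c(139.79, 72.69, 5488.95, 10.29),
  high = c(201.74, 122.01, 7045.38, 32.49),
  flip = c(TRUE, FALSE, TRUE, FALSE),
  stringsAsFactors = FALSE)

#' Map a normalized cohort to clinical units
#'
#' Affine per-biomarker map from the normalized latent scale (0 =
#' healthy, 1 = diseased) to clinical units, flipping orientation for
#' CSF amyloid-beta 1-42 and hippocampal volume, which decrease as the
#' disease progresses.  Default anchors are the ADNI-1 CN and AD group
#' means.  Inverse of [normalize_cohort] with the same spec (round-trips
#' to 1e-10).
#'
#' @param cohort long-format cohort on the normalized scale.
#' @param scale_spec data frame with columns `biomarker`, `low`, `high`,
#'   `flip`.
#' @return the cohort with `value` in clinical units.
#' @export
to_clinical_scale <- function(cohort, scale_spec = .DEFAULT_SCALE) {
  miss <- setdiff(unique(cohort$biomarker), scale_spec$biomarker)
  if (length(miss))
    stop("scale spec missing biomarkers: ", paste(miss, collapse = ", "))
  out <- cohort
  for (k in unique(cohort$biomarker)) {
    row <- scale_spec[scale_spec$biomarker == k, ]
    sel <- cohort$biomarker == k
    x <- cohort$value[sel]
    if (row$flip) x <- 1 - x
    out$value[sel] <- row$low + x * (row$high - row$low)
  }
  out
}
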