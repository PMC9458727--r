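# canonical long-format column names and the wide-format biomarker headers
# (ADNIMERGE-like) accepted by the reader
.WIDE_MAP <- c(ABETA = "A", TAU = "T", HIPPR = "N", ADAS13 = "C")

#' Read a longitudinal biomarker cohort from CSV
#'
#' Long dialect: columns `subject_id`, `age_years`, `group`, `biomarker`
#' (A/T/N/C), `value`.  Wide dialect: `subject_id`, `age_years`, `group`
#' plus biomarker columns `ABETA`, `TAU`, `HIPPR`, `ADAS13` (missing
#' cells dropped).  Validates column presence, numeric values and
#' duplicate (subject, age, biomarker) keys, reporting offending rows.
#'
#' @param path CSV file path.
#' @param dialect `"long"` or `"wide"`.
#' @return a long-format cohort data frame (columns `subject_id`, `age`,
#'   `group`, `biomarker`, `value`), with a summary of subjects, visits
#'   and groups attached as attribute `"summary"`.
#' @export
read_cohort <- function(path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  if (dialect == "long") {
    need <- c("subject_id", "age_years", "group", "biomarker", "value")
    miss <- setdiff(need, names(raw))
    if (length(miss))
      stop("missing columns: ", paste(miss, collapse = ", "))
    cohort <- data.frame(subject_id = as.character(raw$subject_id),
                         age = raw$age_years, group = raw$group,
                         biomarker = raw$biomarker, value = raw$value,
                         stringsAsFactors = FALSE)
  } else {
    need <- c("subject_id", "age_years", "group")
    miss <- setdiff(need, names(raw))
    if (length(miss))
      stop("missing columns: ", paste(miss, collapse = ", "))
    have <- intersect(names(.WIDE_MAP), names(raw))
    if (!length(have)) stop("no biomarker columns found (expected ",
                            paste(names(.WIDE_MAP), collapse = ", "), ")")
    parts <- lapply(have, function(h) {
      v <- raw[[h]]
      keep <- !is.na(v)
      data.frame(subject_id = as.character(raw$subject_id[keep]),
                 age = raw$age_years[keep], group = raw$group[keep],
                 biomarker = .WIDE_MAP[[h]], value = v[keep],
                 stringsAsFactors = FALSE)
    })
    cohort <- do.call(rbind, parts)
  }
  bad <- which(!is.finite(suppressWarnings(as.numeric(cohort$value))))
  if (length(bad))
    stop("non-numeric biomarker values at rows: ",
         paste(head(bad, 5), collapse = ", "))
  cohort$value <- as.numeric(cohort$value)
  key <- paste(cohort$subject_id, cohort$age, cohort$biomarker)
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicated (subject, age, biomarker) records at rows: ",
         paste(head(dup, 5), collapse = ", "))
  .check_cohort(cohort)
  attr(cohort, "summary") <- list(
    n_subjects = length(unique(cohort$subject_id)),
    n_records = nrow(cohort),
    groups = table(cohort$group[!duplicated(cohort$subject_id)]))
  cohort
}

#' Write a cohort to long-format CSV
#'
#' @param cohort long-format cohort.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- data.frame(subject_id = cohort$subject_id,
                    age_years = cohort$age, group = cohort$group,
                    biomarker = cohort$biomarker, value = cohort$value)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Orientation and normalization spec for the four biomarkers
#'
#' Clinical orientation: CSF amyloid-beta 1-42 and hippocampal volume
#' decrease with disease (flipped onto the latent scale where everything
#' grows from 0); CSF total tau and ADAS-13 increase.  Anchors are either
#' cohort-level robust quantiles (default) or the ADNI-1 CN/AD group
#' means preset.
#'
#' @param cohort cohort in clinical units (needed for the quantile
#'   preset).
#' @param preset `"cohort_quantiles"` (2.5th/97.5th percentiles per
#'   biomarker) or `"adni_means"`.
#' @return data frame `biomarker`, `low`, `high`, `flip`.
#' @export
orientation_spec <- function(cohort = NULL,
                             preset = c("cohort_quantiles", "adni_means")) {
  preset <- match.arg(preset)
  flips <- c(A = TRUE, T = FALSE, N = TRUE, C = FALSE)
  if (preset == "adni_means") return(.DEFAULT_SCALE)
  if (is.null(cohort)) stop("cohort required for the quantile preset")
  do.call(rbind, lapply(BIOMARKERS, function(k) {
    v <- cohort$value[cohort$biomarker == k]
    q <- quantile(v, c(0.025, 0.975), names = FALSE, na.rm = TRUE)
    hl <- if (flips[[k]]) c(q[1], q[2]) else c(q[1], q[2])
    data.frame(biomarker = k, low = q[1], high = q[2], flip = flips[[k]],
               stringsAsFactors = FALSE)
  }))
}

#' Normalize a clinical-unit cohort onto the latent scale
#'
#' `value -> (value - low) / (high - low)`, then `x -> 1 - x` for
#' flip-flagged biomarkers, so every biomarker starts near 0 in health
#' and grows toward 1 with disease.  Inverse of [to_clinical_scale] with
#' the same spec.
#'
#' @param cohort cohort in clinical units.
#' @param spec an [orientation_spec] (default: quantile anchors from this
#'   cohort).
#' @return normalized cohort.
#' @export
normalize_cohort <- function(cohort, spec = NULL) {
  if (is.null(spec)) spec <- orientation_spec(cohort)
  out <- cohort
  for (k in unique(cohort$biomarker)) {
    row <- spec[spec$biomarker == k, ]
    if (!nrow(row)) stop("no orientation spec for biomarker ", k)
    if (row$high == row$low)
      stop("degenerate anchors for biomarker ", k)
    sel <- cohort$biomarker == k
    x <- (cohort$value[sel] - row$low) / (row$high - row$low)
    if (row$flip) x <- 1 - x
    out$value[sel] <- x
  }
  out
}

#' Write a calibrated DPS table to CSV
#' @param dps data frame `subject_id`, `alpha`, `beta`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dps <- function(dps, path) {
  write.csv(dps[, c("subject_id", "alpha", "beta")], path,
            row.names = FALSE)
  invisible(path)
}

#' Read a DPS table written by [write_dps]
#' @param path CSV path.
#' @return data frame `subject_id`, `alpha`, `beta`.
#' @export
read_dps <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("subject_id", "alpha", "beta") %in% names(d)))
  d$subject_id <- as.character(d$subject_id)
  d
}

#' Run the full analysis pipeline
#'
#' Executes the stages of the modelling workflow in order -- simulate (or
#' read) a cohort, fit population sigmoids, discover the model structure,
#' calibrate the population model and DPS warps, run the sensitivity
#' screening, personalize and score -- writing per-stage artifacts and a
#' machine-readable manifest into `outdir`.  All randomness derives from
#' one top-level seed, expanded into fixed per-stage offsets recorded in
#' the manifest.
#'
#' @param config list with optional blocks: `simulate` (a
#'   [generator_config] argument list without seed), or `cohort_csv` +
#'   `dialect`; `calibrate` (`L`); `sensitivity` (`N`, `tol`);
#'   `discover` (`m_max`, `lambda`).
#' @param outdir output directory (created if missing).
#' @param seed top-level integer seed.
#' @return the manifest list, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config = list(), outdir, seed = 1L) {
  if (missing(outdir)) stop("outdir is required")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed, started = format(Sys.time()),
                   package_version = as.character(
                     utils::packageVersion("adcascade")),
                   stages = list())
  t_stage <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- force(expr)
    list(value = v, secs = proc.time()[["elapsed"]] - t0)
  }
  stage_seed <- function(k) as.integer((seed * 1000L + k) %% .Machine$integer.max)

  # stage 1: cohort
  st <- t_stage({
    if (!is.null(config$cohort_csv)) {
      cohort <- read_cohort(config$cohort_csv,
                            config$dialect %||% "long")
      cohort <- normalize_cohort(cohort,
                                 orientation_spec(cohort,
                                                  config$anchors %||%
                                                    "cohort_quantiles"))
      list(cohort = cohort, truth = NULL)
    } else {
      args <- config$simulate %||% list()
      args$seed <- stage_seed(1L)
      gc_ <- do.call(generator_config, args)
      generate_cohort(gc_)
    }
  })
  sim <- st$value
  cohort <- sim$cohort
  write_cohort(cohort, file.path(outdir, "cohort.csv"))
  manifest$stages$cohort <- list(secs = st$secs, n = nrow(cohort),
                                 seed = stage_seed(1L))

  # stage 2: population sigmoids on provisional DPS (truth DPS when
  # simulated, otherwise a crude age-anchored warp refined by calibration)
  st <- t_stage({
    dps0 <- if (!is.null(sim$truth)) sim$truth$dps else
      data.frame(subject_id = unique(cohort$subject_id), alpha = 1,
                 beta = -mean(cohort$age))
    s <- .obs_s(cohort, dps0)
    sig <- lapply(BIOMARKERS, function(k) {
      sel <- cohort$biomarker == k
      fit_sigmoid(s[sel], cohort$value[sel])
    })
    names(sig) <- BIOMARKERS
    sig
  })
  sig <- st$value
  manifest$stages$sigmoid <- list(
    secs = st$secs,
    rss = vapply(sig, function(f) f$rss, 0))

  # stage 3: structure discovery
  st <- t_stage({
    dargs <- config$discover %||% list()
    discover_model(sig, m_max = dargs$m_max %||% 4L,
                   lam = dargs$lambda %||% 1e-7)
  })
  disc <- st$value
  manifest$stages$discover <- list(secs = st$secs, m_star = disc$m_star)

  # stage 4: population calibration
  st <- t_stage({
    cargs <- config$calibrate %||% list()
    calibrate(cohort, L = cargs$L %||% 10L, seed = stage_seed(4L))
  })
  cal <- st$value
  write_params(cal$params, file.path(outdir, "population_params.json"))
  write_dps(cal$dps, file.path(outdir, "dps.csv"))
  write.csv(data.frame(round = seq_along(cal$history),
                       objective = cal$history),
            file.path(outdir, "objective_history.csv"), row.names = FALSE)
  manifest$stages$calibrate <- list(secs = st$secs,
                                    objective = cal$objective,
                                    rounds = cal$rounds,
                                    seed = stage_seed(4L))

  # stage 5: sensitivity screening.  A freshly calibrated model can sit
  # near the edge of stability, where the default 90-110% boxes produce
  # integration blow-ups; retry with narrower screening boxes and record
  # the fraction used.
  st <- t_stage({
    sargs <- config$sensitivity %||% list()
    res <- NULL; frac_used <- NA_real_
    for (frac in c(sargs$frac %||% 0.1, 0.05, 0.02)) {
      res <- tryCatch(
        sobol_indices(make_ranges(cal$params, frac = frac),
                      N = sargs$N %||% 2^11,
                      seed = stage_seed(5L), second_order = FALSE,
                      n_boot = 50L),
        error = function(e) NULL)
      if (!is.null(res)) { frac_used <- frac; break }
    }
    if (is.null(res))
      stop("sensitivity stage failed: calibrated model unstable under ",
           "even the narrowest screening boxes")
    list(res = res, frac = frac_used,
         sensitive = select_personalized(res, sargs$tol %||% 0.01))
  })
  sens <- st$value
  write.csv(sens$res$indices, file.path(outdir, "sobol_indices.csv"),
            row.names = FALSE)
  manifest$stages$sensitivity <- list(secs = st$secs,
                                      sensitive = sens$sensitive,
                                      frac = sens$frac,
                                      seed = stage_seed(5L))

  # stage 6: personalization
  st <- t_stage(
    cohort_personalization_report(cohort, cal$params, sens$sensitive,
                                  cal$dps))
  rep_ <- st$value
  if (nrow(rep_$table))
    write.csv(rep_$table, file.path(outdir, "personalization.csv"),
              row.names = FALSE)
  manifest$stages$personalize <- list(secs = st$secs,
                                      n_eligible = nrow(rep_$table))

  manifest$finished <- format(Sys.time())
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
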