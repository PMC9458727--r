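test_that("prediction accuracy penalizes both directions symmetrically", {
  expect_equal(prediction_accuracy(2.0, 1.9), 95)
  expect_equal(prediction_accuracy(2.0, 2.1), 95)
  expect_equal(prediction_accuracy(1.5, 1.5), 100)
  expect_true(is.na(prediction_accuracy(0, 1)))
  expect_lt(prediction_accuracy(1, 3), 0)
})

test_that("eligibility needs four observations of every biomarker", {
  g <- personalization_cohort(seed = 1, n = 10, noise = 0)
  dps <- g$truth$dps
  # drop hippocampal observations of the first subject down to 3
  id <- dps$subject_id[1]
  rows_n <- which(g$cohort$subject_id == id & g$cohort$biomarker == "N")
  coh <- g$cohort[-rows_n[4:length(rows_n)], ]
  expect_false(id %in% eligible_subjects(coh, dps))
  expect_true(id %in% eligible_subjects(g$cohort, dps))
})

test_that("non-monotone denoised series are screened out", {
  dps <- data.frame(subject_id = "Z1", alpha = 1, beta = -75)
  ages <- 70 + 0:4
  mk <- function(vals_c) {
    do.call(rbind, lapply(c("A", "T", "N", "C"), function(k) {
      v <- if (k == "C") vals_c else seq(0.1, 0.5, length.out = 5)
      data.frame(subject_id = "Z1", age = ages, group = "LMCI",
                 biomarker = k, value = v, stringsAsFactors = FALSE)
    }))
  }
  # a strong interior dip survives sigmoid denoising as non-monotone
  expect_false("Z1" %in% eligible_subjects(mk(c(0.1, 0.6, 0.2, 0.7, 0.3)),
                                           dps))
  expect_true("Z1" %in% eligible_subjects(mk(c(0.1, 0.2, 0.3, 0.4, 0.5)),
                                          dps))
})

test_that("population-consistent data is a fixed point of the refit", {
  g <- personalization_cohort(seed = 2, n = 6, noise = 0)
  p <- ref_lmci()
  id <- g$truth$dps$subject_id[1]
  sel <- g$cohort$subject_id == id
  di <- g$truth$dps[1, ]
  sens <- c("w_A1", "w_N1", "w_T4")
  fit <- fit_personalized(g$cohort$age[sel], g$cohort$biomarker[sel],
                          g$cohort$value[sel], p, sens, di$alpha, di$beta)
  expect_lt(max(abs(fit$w2 - p$w[sens]) / abs(p$w[sens])), 1e-3)
  # non-sensitive parameters pinned bitwise to population values
  others <- setdiff(names(p$w), sens)
  expect_identical(fit$params$w[others], p$w[others])
})

test_that("a perturbed sensitive parameter is recovered from one subject", {
  g <- personalization_cohort(seed = 3, n = 4, noise = 0)
  p <- ref_lmci()
  id <- g$truth$dps$subject_id[1]
  di <- g$truth$dps[1, ]
  sel <- g$cohort$subject_id == id
  w2 <- replace(p$w, "w_A1", p$w[["w_A1"]] * 1.08)
  p2 <- cascade_params(w2, p$y0)
  s <- di$alpha * g$cohort$age[sel] + di$beta
  vals <- adcascade:::.f_all_at(s, p2)
  coh <- g$cohort[sel, ]
  coh$value <- vals[cbind(seq_len(nrow(coh)),
                          match(coh$biomarker, c("A", "T", "N", "C")))]
  fit <- fit_personalized(coh$age, coh$biomarker, coh$value, p,
                          c("w_A1", "w_A2"), di$alpha, di$beta)
  expect_lt(abs(fit$w2[["w_A1"]] - w2[["w_A1"]]) / w2[["w_A1"]], 0.02)
})

test_that("empty sensitive set returns the population model flagged", {
  g <- personalization_cohort(seed = 4, n = 3, noise = 0)
  p <- ref_lmci()
  id <- g$truth$dps$subject_id[1]
  sel <- g$cohort$subject_id == id
  fit <- fit_personalized(g$cohort$age[sel], g$cohort$biomarker[sel],
                          g$cohort$value[sel], p, character(0),
                          g$truth$dps$alpha[1], g$truth$dps$beta[1])
  expect_identical(fit$params$w, p$w)
  expect_match(fit$flag, "empty")
})

test_that("accuracy never exceeds 100 and is exact without noise", {
  p <- ref_lmci()
  sens <- c("w_A1", "w_N1", "w_T4", "w_N3", "w_C3")
  for (seed in 1:3) {
    g <- personalization_cohort(seed = seed, n = 20, noise = 0.05)
    rep_ <- cohort_personalization_report(g$cohort, p, sens, g$truth$dps)
    pa <- as.matrix(rep_$table[, grep("^pa_", names(rep_$table))])
    expect_true(all(pa <= 100 + 1e-9, na.rm = TRUE))
  }
  g0 <- personalization_cohort(seed = 9, n = 15, noise = 0)
  rep0 <- cohort_personalization_report(g0$cohort, p, sens, g0$truth$dps)
  pa0 <- as.matrix(rep0$table[, grep("^pa_ode_", names(rep0$table))])
  expect_equal(max(abs(pa0 - 100), na.rm = TRUE), 0, tolerance = 1e-4)
})

test_that("longer histories do not hurt average accuracy", {
  p <- ref_lmci()
  sens <- c("w_A1", "w_N1", "w_T4", "w_N3", "w_C3")
  mean_pa <- function(visits, seed) {
    g <- generate_cohort(generator_config(
      n_subjects = 40, noise_sd = 0.03, miss_prob = 0,
      visit_range = visits,
      dps_baseline = list(CN = c(-2, 2), LMCI = c(2, 2), AD = c(6, 2)),
      seed = seed))
    tab <- suppressWarnings(
      cohort_personalization_report(g$cohort, p, sens, g$truth$dps)$table)
    if (is.null(tab) || nrow(tab) == 0) return(NA_real_)
    mean(as.matrix(tab[, grep("^pa_ode_", names(tab))]), na.rm = TRUE)
  }
  gain <- vapply(1:10, function(seed)
    mean_pa(c(6, 6), seed) - mean_pa(c(4, 4), seed + 100), 0)
  gain <- gain[is.finite(gain)]
  expect_gte(length(gain), 5)
  expect_gte(mean(gain), -1)
})

test_that("summaries report group means and zero SD for single subjects", {
  p <- ref_lmci()
  g <- personalization_cohort(seed = 11, n = 12, noise = 0.03)
  rep_ <- cohort_personalization_report(g$cohort, p, c("w_A1"), g$truth$dps)
  expect_true(all(c("group", "n") %in% names(rep_$summary)))
  ones <- rep_$summary[rep_$summary$n == 1, ]
  if (nrow(ones)) expect_true(all(ones$sd == 0 | is.na(ones$sd)))
  # empty eligibility set warns and returns empty tables
  tiny <- g$cohort[g$cohort$biomarker == "A", ]
  expect_warning(out <- cohort_personalization_report(tiny, p, "w_A1",
                                                      g$truth$dps),
                 "no eligible")
  expect_equal(nrow(out$table), 0)
})
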