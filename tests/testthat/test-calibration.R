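test_that("sigma follows the degrees-of-freedom-corrected formula", {
  expect_equal(as.numeric(compute_sigma(2.0, 10, 2)), 1.0)
  s0 <- compute_sigma(0, 50, 10)
  expect_equal(as.numeric(s0), 0)
  expect_true(attr(s0, "perfect"))
  expect_error(compute_sigma(1, 8, 2), "degenerate")
})

test_that("weight fit is a fixed point at the truth on noiseless data", {
  g <- small_cohort(seed = 7, n = 30, noise = 0, visits = c(4, 5))
  p <- ref_lmci()
  wf <- fit_weights(g$cohort, g$truth$dps, p)
  expect_lt(max(abs(wf$params$w - p$w)), 5e-3)
  expect_lt(max(wf$rss), 1e-10)
})

test_that("noiseless weights are recovered from a generic start", {
  g <- small_cohort(seed = 11, n = 60, noise = 0, visits = c(5, 5))
  p <- ref_lmci()
  wf <- fit_weights(g$cohort, g$truth$dps, adcascade:::.default_w_init())
  nz <- nonzero_names(p)
  rel <- abs(wf$params$w[nz] - p$w[nz]) / abs(p$w[nz])
  expect_lt(max(rel), 0.05)
})

test_that("underdetermined blocks are flagged, not fitted", {
  g <- small_cohort(seed = 3, n = 2, noise = 0, visits = c(2, 2))
  # keep a single tau observation
  coh <- rbind(g$cohort[g$cohort$biomarker != "T", ],
               g$cohort[g$cohort$biomarker == "T", ][1, ])
  wf <- fit_weights(coh, g$truth$dps, ref_lmci())
  expect_match(paste(wf$flags, collapse = " "), "underdetermined")
})

test_that("per-subject DPS warps are recovered given the true model", {
  g <- small_cohort(seed = 5, n = 12, noise = 0, visits = c(4, 5))
  p <- ref_lmci()
  for (i in c(1, 5, 9)) {
    id <- g$truth$dps$subject_id[i]
    sel <- g$cohort$subject_id == id
    fd <- fit_dps(g$cohort$age[sel], g$cohort$biomarker[sel],
                  g$cohort$value[sel], p)
    expect_lt(abs(fd$alpha - g$truth$dps$alpha[i]) / g$truth$dps$alpha[i],
              0.02)
    expect_lt(abs(fd$beta - g$truth$dps$beta[i]), 0.5)
    expect_false(fd$boundary)
  }
  expect_error(fit_dps(80, "A", 0.5, p), "at least 2")
})

test_that("shrinking one biomarker's sigma pulls the warp toward it", {
  g <- small_cohort(seed = 6, n = 6, noise = 0.05, visits = c(5, 5))
  p <- ref_lmci()
  id <- g$truth$dps$subject_id[2]
  sel <- g$cohort$subject_id == id
  args <- list(g$cohort$age[sel], g$cohort$biomarker[sel],
               g$cohort$value[sel], p)
  sig_even <- c(A = 1, T = 1, N = 1, C = 1)
  sig_c <- c(A = 1, T = 1, N = 1, C = 0.02)
  f1 <- do.call(fit_dps, c(args, list(sigma = sig_even)))
  f2 <- do.call(fit_dps, c(args, list(sigma = sig_c)))
  rss_c <- function(fd) {
    s <- fd$alpha * args[[1]] + fd$beta
    kc <- args[[2]] == "C"
    sum((args[[3]][kc] - evaluate_f("C", s[kc], p))^2)
  }
  expect_lte(rss_c(f2), rss_c(f1) + 1e-10)
})

test_that("calibrate with L = 0 returns the initialization unchanged", {
  g <- small_cohort(seed = 2, n = 5, noise = 0.03)
  p <- ref_lmci()
  cal <- calibrate(g$cohort, init = list(w = p, dps = g$truth$dps), L = 0)
  expect_identical(cal$params$w, p$w)
  expect_equal(cal$dps$alpha, g$truth$dps$alpha)
  expect_length(cal$history, 0)
})

test_that("sigma scales roughly quadratically with the noise level", {
  ratios <- vapply(1:8, function(seed) {
    p <- ref_lmci()
    g1 <- small_cohort(seed = seed, n = 40, noise = 0.03, visits = c(4, 5))
    g2 <- small_cohort(seed = seed, n = 40, noise = 0.06, visits = c(4, 5))
    s1 <- fit_weights(g1$cohort, g1$truth$dps, p)$rss
    s2 <- fit_weights(g2$cohort, g2$truth$dps, p)$rss
    mean(s2 / s1)
  }, 0)
  expect_gt(mean(ratios), 3)
  expect_lt(mean(ratios), 5)
})

test_that("subset refit with fixed DPS recovers subset-specific weights", {
  p <- ref_lmci()
  g <- small_cohort(seed = 9, n = 40, noise = 0, visits = c(4, 5))
  # one fit_weights round on the full cohort equals refit on the full set
  a <- fit_weights(g$cohort, g$truth$dps, p)
  b <- refit_weights_fixed_dps(g$cohort, g$truth$dps, p)
  expect_identical(a$params$w, b$params$w)
  expect_error(refit_weights_fixed_dps(g$cohort[0, ], g$truth$dps, p),
               "empty")
  bad_dps <- g$truth$dps[-1, ]
  expect_error(refit_weights_fixed_dps(g$cohort, bad_dps, p), "no DPS")
  # two-regime cohort: the subset was generated under different weights
  w2 <- p$w
  w2[c("w_A1", "w_A2")] <- w2[c("w_A1", "w_A2")] * 1.3
  p2 <- cascade_params(w2, p$y0)
  g2 <- small_cohort(seed = 10, n = 40, noise = 0, visits = c(4, 5),
                     truth = p2)
  wf <- refit_weights_fixed_dps(g2$cohort, g2$truth$dps, p)
  nz <- nonzero_names(p2)
  rel <- abs(wf$params$w[nz] - p2$w[nz]) / abs(p2$w[nz])
  expect_lt(max(rel), 0.10)
})

test_that("bootstrap band collapses without noise and is order-invariant", {
  p <- ref_lmci()
  g0 <- small_cohort(seed = 2, n = 20, noise = 0, visits = c(3, 5))
  st0 <- structure(list(params = p, dps = g0$truth$dps),
                   class = "calibration_state")
  grid <- seq(-10, 15, length.out = 11)
  bb0 <- bootstrap_band(g0$cohort, st0, B = 25, seed = 9, s_grid = grid)
  widths <- sapply(c("A", "T", "N", "C"),
                   function(k) max(bb0[[k]][, "upper"] - bb0[[k]][, "lower"]))
  expect_lt(max(widths), 1e-3)
  # permuting the cohort rows leaves the band unchanged
  perm <- sample(nrow(g0$cohort))
  bb1 <- bootstrap_band(g0$cohort[perm, ], st0, B = 25, seed = 9,
                        s_grid = grid)
  expect_equal(bb1$C, bb0$C, tolerance = 1e-12)
  expect_error(bootstrap_band(g0$cohort, st0, B = 10), "at least 20")
})

test_that("the bootstrap band usually contains the generating trajectory", {
  p <- ref_lmci()
  grid <- 0
  hits <- vapply(1:10, function(seed) {
    g <- small_cohort(seed = seed, n = 20, noise = 0.03, visits = c(3, 5))
    st <- structure(list(params = p, dps = g$truth$dps),
                    class = "calibration_state")
    bb <- bootstrap_band(g$cohort, st, B = 30, seed = seed,
                         s_grid = c(-10, 0, 10))
    truth <- solve_model(p, c(-10, 0, 10))$values
    all(bb$C[2, "lower"] - 1e-9 <= truth[2, "C"] &
        truth[2, "C"] <= bb$C[2, "upper"] + 1e-9)
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})

test_that("cohort validation rejects malformed tables", {
  g <- small_cohort(seed = 1, n = 3, noise = 0)
  bad <- g$cohort
  bad$age[1] <- -1
  expect_error(calibrate(bad, L = 0), "positive")
  dup <- rbind(g$cohort, g$cohort[1, ])
  expect_error(calibrate(dup, L = 0), "duplicated")
})
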