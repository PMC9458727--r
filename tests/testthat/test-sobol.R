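test_that("parameter ranges are 90-110% boxes with zero weights fixed", {
  rng <- make_ranges(ref_full())
  expect_equal(unname(rng$lower["w_A1"]), 0.9 * 0.917)
  expect_equal(unname(rng$upper["w_A1"]), 1.1 * 0.917)
  # negative weight: bounds reordered
  expect_equal(unname(rng$lower["w_A2"]), -0.9603)
  expect_equal(unname(rng$upper["w_A2"]), -0.7857)
  expect_true(all(c("w_A0", "w_T0", "w_N0", "w_C0") %in% rng$fixed))
  expect_length(rng$free, 17L)
  expect_length(make_ranges(ref_lmci())$free, 16L)
})

test_that("Sobol' points are balanced and seed-reproducible", {
  x <- sobol_points(256, 6)
  expect_true(all(x >= 0 & x < 1))
  # one-dimensional balance of the plain sequence
  expect_lt(max(abs(colMeans(x) - 0.5)), 0.01)
  a <- sobol_points(64, 10, seed = 42)
  b <- sobol_points(64, 10, seed = 42)
  expect_identical(a, b)
  expect_false(identical(a, sobol_points(64, 10, seed = 43)))
})

test_that("additive two-input model matches the analytic decomposition", {
  raw <- list(lower = c(x1 = 0, x2 = 0), upper = c(x1 = 1, x2 = 1))
  res <- sobol_indices(raw, N = 2^14, seed = 3, n_boot = 30,
                       model_fn = function(X) X[, 1] + 2 * X[, 2])
  expect_lt(abs(res$indices$S1[1] - 1 / 5), 0.02)
  expect_lt(abs(res$indices$S1[2] - 4 / 5), 0.02)
  expect_lt(abs(res$indices$ST[1] - 1 / 5), 0.02)
  expect_lt(abs(res$indices$ST[2] - 4 / 5), 0.02)
  # no interactions: closed second order = S1 + S2 (= 1), interaction ~ 0
  expect_lt(abs(res$S2[1, 2] - 1), 0.02)
  expect_lt(abs(res$interaction[1, 2]), 0.02)
})

test_that("symmetric product model gives equal first-order indices", {
  raw <- list(lower = c(a = 0.9, b = 0.9), upper = c(a = 1.1, b = 1.1))
  res <- sobol_indices(raw, N = 2^14, seed = 5, n_boot = 0,
                       model_fn = function(X) X[, 1] * X[, 2])
  expect_lt(abs(res$indices$S1[1] - res$indices$S1[2]), 0.02)
})

test_that("tensor-grid integration of the variance decomposition agrees", {
  # reduced model: only w_A1, w_A2, y0 free; brute-force conditional
  # variances on a 21^3 midpoint grid vs the Saltelli estimate
  p <- ref_lmci()
  w0 <- p$w
  mf3 <- function(X) {
    out <- numeric(nrow(X))
    for (i in seq_len(nrow(X))) {
      W <- matrix(w0, 1, 21)
      W[1, match(c("w_A1", "w_A2"), names(w0))] <- X[i, 1:2]
      out[i] <- adcascade:::.batch_eval_cpp(W, X[i, 3], 0, 3L)$values[1, 1]
    }
    out
  }
  lo <- c(w_A1 = 0.9 * 0.745, w_A2 = -1.1 * 0.749, y0 = 0.9 * 1.41e-4)
  hi <- c(w_A1 = 1.1 * 0.745, w_A2 = -0.9 * 0.749, y0 = 1.1 * 1.41e-4)
  est <- sobol_indices(list(lower = lo, upper = hi), N = 2^12, seed = 2,
                       n_boot = 0, model_fn = mf3)
  g1 <- (seq_len(21) - 0.5) / 21
  grid <- as.matrix(expand.grid(g1, g1, g1))
  Xg <- sweep(sweep(grid, 2, hi - lo, "*"), 2, lo, "+")
  arr <- array(mf3(Xg), c(21, 21, 21))
  n <- length(arr)
  V <- var(as.vector(arr)) * (n - 1) / n
  m0 <- mean(arr)
  oracle <- vapply(1:3, function(d) {
    cm <- apply(arr, d, mean)
    (mean(cm^2) - m0^2) / V
  }, 0)
  expect_lt(max(abs(oracle - est$indices$S1)), 0.05)
})

test_that("identical seeds give bitwise-identical indices", {
  rng <- make_ranges(ref_lmci())
  a <- sobol_indices(rng, N = 2^9, seed = 4, second_order = FALSE,
                     n_boot = 0)
  b <- sobol_indices(rng, N = 2^9, seed = 4, second_order = FALSE,
                     n_boot = 0)
  expect_identical(a$indices, b$indices)
})

test_that("indices satisfy the variance-decomposition inequalities", {
  rng <- make_ranges(ref_lmci())
  res <- sobol_indices(rng, N = 2^11, seed = 6, second_order = FALSE,
                       n_boot = 50)
  tab <- res$indices
  expect_lte(sum(tab$S1), 1 + 3 * sqrt(sum(tab$S1_se^2)))
  expect_true(all(tab$ST >= tab$S1 - 3 * (tab$S1_se + tab$ST_se + 1e-6)))
})

test_that("estimates are stable between N = 2^12 and N = 2^14", {
  rng <- make_ranges(ref_lmci())
  a <- sobol_indices(rng, N = 2^12, seed = 8, second_order = FALSE,
                     n_boot = 0)$indices
  b <- sobol_indices(rng, N = 2^14, seed = 8, second_order = FALSE,
                     n_boot = 0)$indices
  expect_lt(max(abs(a$S1 - b$S1)), 0.03)
})

test_that("DPS dynamics reuse one design and reproduce the single-point run", {
  rng <- make_ranges(ref_lmci())
  single <- sobol_indices(rng, output = list(k = "C", s = 5), N = 2^10,
                          seed = 9, second_order = FALSE, n_boot = 0)
  dyn <- sensitivity_over_dps(rng, s_grid = c(5, 10), N = 2^10, seed = 9)
  first <- dyn$dynamics[dyn$dynamics$s == 5, ]
  expect_equal(first$S1, single$indices$S1, tolerance = 1e-12)
  # amyloid growth dominates at onset and fades with DPS
  s1_wA1 <- dyn$dynamics$S1[dyn$dynamics$parameter == "w_A1"]
  expect_gt(s1_wA1[1], s1_wA1[2])
})

test_that("threshold selection clamps negatives and orders by index", {
  fake <- structure(list(indices = data.frame(
    parameter = c("p1", "p2", "p3", "p4"),
    S1 = c(0.5, 0.009, 0.02, -0.002),
    ST = c(0.5, 0.01, 0.02, 0),
    S1_se = 0, ST_se = 0)), class = "sobol_result")
  expect_equal(select_personalized(fake, 0.01), c("p1", "p3"))
  # at tol = 0 every free parameter qualifies (negatives clamp to 0)
  expect_setequal(select_personalized(fake, 0), fake$indices$parameter)
  empty <- fake
  empty$indices$S1 <- rep(-0.01, 4)
  expect_warning(sel <- select_personalized(empty, 0.01), "no parameter")
  expect_length(sel, 0)
})

test_that("blow-up samples abort the sensitivity run", {
  # strongly self-exciting cognition equation: part of the +/-10% box
  # drives the integration over the guard
  w <- ref_lmci()$w
  w["w_C2"] <- 5; w["w_C3"] <- 0.5; w["w_C1"] <- 1.5
  p <- cascade_params(w, 1.41e-4)
  tryCatch({
    solve_model(p, seq(-10, 20, by = 0.5))
    skip("constructed parameters did not blow up on this domain")
  }, error = function(e) NULL)
  rng <- make_ranges(p)
  expect_error(sobol_indices(rng, output = list(k = "C", s = 20), N = 2^6,
                             seed = 1, second_order = FALSE, n_boot = 0),
               "blew up")
})
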