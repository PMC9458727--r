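# population sigmoids fitted to the noiseless reference trajectories
ref_sigmoids <- function(which = "lmci_ad") {
  p <- reference_params(which)
  s <- seq(-10, 20, by = 0.1)
  tr <- solve_model(p, s)
  sig <- lapply(c(A = 1, T = 2, N = 3, C = 4),
                function(k) fit_sigmoid(s, tr$values[, k]))
  names(sig) <- c("A", "T", "N", "C")
  sig
}

test_that("design matrices respect the per-equation variable restriction", {
  sig <- ref_sigmoids()
  sys <- build_design(sig, "T", build_library(2, "pair"))
  expect_equal(ncol(sys$D), 6L)
  expect_equal(length(sys$b), 301L)
  expect_equal(unname(sys$D[, 1]), rep(1, 301))
  expect_equal(sys$labels, c("1", "T", "T^2", "A", "A^2", "T*A"))
  # constant sigmoids give a zero derivative vector
  flat <- lapply(1:4, function(i) c(0, 1, 0, 0.3))
  names(flat) <- c("A", "T", "N", "C")
  sysf <- build_design(flat, "N", build_library(2, "pair"))
  expect_equal(sysf$b, rep(0, 301))
  expect_match(paste(sysf$diagnostics, collapse = " "), "rank-deficient")
  expect_error(build_design(sig, "A", build_library(2, "pair")), "mode")
})

test_that("penalty-free lasso coincides with the OLS oracle", {
  set.seed(7)
  D <- matrix(rnorm(50 * 6), 50, 6)
  colnames(D) <- paste0("x", 1:6)
  wtrue <- c(2, -1, 0, 0.5, 0, 0)
  b <- as.numeric(D %*% wtrue) + rnorm(50, 0, 0.1)
  fit <- lasso_fit(list(D = D, b = b, lam = 0))
  ols <- qr.solve(D, b)
  expect_lt(max(abs(fit$w - ols)), 1e-8)
})

test_that("homotopy solution matches glmnet where coordinate descent works", {
  skip_if_not_installed("glmnet")
  set.seed(8)
  D <- matrix(rnorm(80 * 8), 80, 8)
  colnames(D) <- paste0("x", 1:8)
  b <- as.numeric(D %*% c(3, -2, 0, 0, 1, 0, 0, 0)) + rnorm(80, 0, 0.1)
  for (lam in c(5, 0.5)) {
    mine <- lasso_fit(list(D = D, b = b, lam = lam), zero_tol = 0)$w
    cn <- sqrt(colSums(D^2))
    Ds <- sweep(D, 2, cn, "/")
    ref <- glmnet::glmnet(Ds, b, lambda = lam / (2 * 80),
                          standardize = FALSE, intercept = FALSE,
                          thresh = 1e-16, maxit = 1e7)
    wg <- as.numeric(coef(ref))[-1] / cn
    expect_lt(max(abs(mine - wg)), 1e-7)
  }
})

test_that("zero response yields the zero solution", {
  D <- matrix(rnorm(30 * 4), 30, 4)
  colnames(D) <- paste0("x", 1:4)
  fit <- lasso_fit(list(D = D, b = rep(0, 30), lam = 1e-7))
  expect_equal(unname(fit$w), rep(0, 4))
  expect_length(fit$support, 0)
})

test_that("returned weights are locally optimal for the lasso objective", {
  set.seed(9)
  D <- matrix(rnorm(60 * 5), 60, 5)
  colnames(D) <- paste0("x", 1:5)
  b <- as.numeric(D %*% c(1, 0, -2, 0, 0.3)) + rnorm(60, 0, 0.2)
  lam <- 1
  fit <- lasso_fit(list(D = D, b = b, lam = lam), zero_tol = 0)
  cn <- sqrt(colSums(D^2))
  obj <- function(w) sum((D %*% w - b)^2) + lam * sum(abs(w * cn))
  o0 <- obj(fit$w)
  for (i in 1:100) {
    delta <- rnorm(5, 0, 1e-4)
    expect_gte(obj(fit$w + delta), o0 - 1e-10)
  }
})

test_that("amyloid structure is recovered from exact equation data", {
  # D, b generated directly from the amyloid equation (not via sigmoids):
  # true support {A, A^2} inside a degree-4 single-variable library
  p <- ref_lmci()
  s <- seq(-10, 20, length.out = 301)
  A <- solve_model(p, s)$values[, "A"]
  D <- outer(A, 0:4, `^`)
  colnames(D) <- c("1", "A", "A^2", "A^3", "A^4")
  b <- p$w[["w_A1"]] * A + p$w[["w_A2"]] * A^2
  fit <- lasso_fit(list(D = D, b = b, lam = 1e-7))
  expect_setequal(fit$support_labels, c("A", "A^2"))
  expect_lt(abs(fit$w[["A"]] - p$w[["w_A1"]]), 5e-3)
  expect_lt(abs(fit$w[["A^2"]] - p$w[["w_A2"]]), 5e-3)
  # OLS refit on the recovered support reproduces the generating weights
  refit <- qr.solve(D[, fit$support, drop = FALSE], b)
  expect_lt(max(abs(refit - c(p$w[["w_A1"]], p$w[["w_A2"]])) /
                abs(c(p$w[["w_A1"]], p$w[["w_A2"]]))), 0.05)
})

test_that("over-penalization empties every support", {
  sig <- ref_sigmoids()
  for (eq in c("A", "T")) {
    mode <- if (eq == "A") "single" else "pair"
    sys <- build_design(sig, eq, build_library(2, mode), lam = 1e3)
    expect_length(lasso_fit(sys)$support, 0)
  }
})

test_that("residuals collapse at degree 2 and not at degree 1", {
  # the degree-adequacy signal behind the quadratic cascade: the sigmoid
  # derivative is exactly a quadratic in the sigmoid itself
  sig <- ref_sigmoids()
  for (eq in c("A", "T", "N", "C")) {
    mode <- if (eq == "A") "single" else "pair"
    sys1 <- build_design(sig, eq, build_library(1, mode))
    sys2 <- build_design(sig, eq, build_library(2, mode))
    rss1 <- sum((sys1$D %*% lasso_fit(sys1)$w - sys1$b)^2)
    rss2 <- sum((sys2$D %*% lasso_fit(sys2)$w - sys2$b)^2)
    expect_gt(rss1, 1e-3)
    expect_lt(rss2, 1e-6)
  }
})

test_that("discovery report runs across degrees and emits parameters at m*=2", {
  sig <- ref_sigmoids()
  rep_ <- discover_model(sig, m_max = 3, lam = 1e-7)
  expect_length(rep_$supports, 3L)
  expect_s3_class(rep_, "discovery_report")
  expect_output(print(rep_), "discovery")
  if (!is.na(rep_$m_star) && rep_$m_star == 2)
    expect_true(is.null(rep_$params) || inherits(rep_$params, "cascade_params"))
})
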