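# simulate a response over a depth transect with a known fraction effect,
# an optional smooth depth signal, and iid noise
sim_lmm_data <- function(n = 48, beta_frac = 0.05, depth_amp = 0,
                         sigma = 0.01, seed = 1, shape = c("saturating", "peak"),
                         unique_depths = FALSE) {
  shape <- match.arg(shape)
  withr::with_seed(seed, {
    depths <- if (unique_depths) seq(10, 500, length.out = n)
              else rep(c(15, 30, 50, 75, 100, 125, 150, 200, 300, 500),
                       length.out = n)
    fraction <- rep(c(0, 1), length.out = n)
    log_reads <- rnorm(n, 7, 0.15)
    trend <- if (shape == "saturating") 1 - exp(-depths / 50)
             else exp(-((depths - 100) / 60)^2)  # oxycline-style peak
    y <- 0.5 + beta_frac * fraction + 0.002 * log_reads +
      depth_amp * trend + rnorm(n, 0, sigma)
    tibble::tibble(y = y, fraction = fraction, depth = depths,
                   log_reads = log_reads)
  })
}

test_that("the marginal loglik matches a dense multivariate-normal oracle", {
  d <- sim_lmm_data(n = 8, depth_amp = 0.03, sigma = 0.02, seed = 2)
  fit <- fit_depth_lmm(d, "y")
  # brute-force density at the fitted parameters
  X <- cbind(1, d$fraction, d$log_reads)
  K <- exp(-abs(outer(d$depth, d$depth, "-")) / fit$range_rho)
  Sigma <- fit$sigma_b2 * K + fit$sigma2 * diag(8)
  r <- d$y - X %*% fit$coefficients
  ll_manual <- -0.5 * (8 * log(2 * pi) +
                         determinant(Sigma, logarithm = TRUE)$modulus +
                         t(r) %*% solve(Sigma, r))
  expect_equal(fit$loglik, as.numeric(ll_manual), tolerance = 1e-8)
})

test_that("noiseless fixed effects are recovered exactly", {
  d <- sim_lmm_data(sigma = 0, seed = 3)
  d$y <- 1 + 2 * d$fraction
  fit <- fit_depth_lmm(d, "y")
  expect_equal(unname(fit$coefficients["fraction"]), 2, tolerance = 1e-8)
})

test_that("fixed-only fit equals ordinary ML regression", {
  d <- sim_lmm_data(seed = 4)
  fit <- fit_fixed_only(d, "y", include_depth = FALSE)
  ref <- lm(y ~ fraction + log_reads, data = d)
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-10)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)
  expect_equal(fit$sigma2, sum(resid(ref)^2) / nrow(d))  # ML, divisor n
  # perfect linear data -> exact coefficients
  d2 <- d; d2$y <- 3 - 0.5 * d2$fraction + 0.1 * d2$log_reads
  f2 <- fit_fixed_only(d2, "y", include_depth = FALSE)
  expect_equal(unname(f2$coefficients[1:3]), c(3, -0.5, 0.1),
               tolerance = 1e-8)
  expect_error(fit_fixed_only(dplyr::mutate(d, log_reads = fraction), "y"),
               "collinear")
})

test_that("mixed fit degenerates to the fixed fit when sigma_b is negligible", {
  d <- sim_lmm_data(depth_amp = 0, sigma = 0.02, seed = 5)
  full <- fit_depth_lmm(d, "y")
  ols <- fit_fixed_only(d, "y", include_depth = FALSE)
  # no depth signal: the boundary solution can only improve on OLS slightly
  expect_gte(full$loglik, ols$loglik - 1e-6)
  expect_lt(full$sigma_b2 / full$sigma2, 1.5)
})

test_that("the LRT compares nested fits and reports the AIC gap", {
  d <- sim_lmm_data(depth_amp = 0.05, sigma = 0.01, seed = 6)
  full <- fit_depth_lmm(d, "y")
  null <- fit_fixed_only(d, "y")
  lrt <- likelihood_ratio_test(full, null)
  expect_equal(lrt$statistic, 2 * (full$loglik - null$loglik))
  expect_equal(lrt$df, 2L)
  expect_equal(lrt$p_value_boundary, lrt$p_value / 2)
  expect_equal(lrt$delta_aic, null$aic - full$aic)
  expect_error(likelihood_ratio_test(full, full), "must not")
  d2 <- sim_lmm_data(n = 24, seed = 7)
  expect_error(likelihood_ratio_test(full, fit_fixed_only(d2, "y")),
               "same data")
})

test_that("AIC prefers the random depth effect when a strong trend is present", {
  d <- sim_lmm_data(depth_amp = 0.06, sigma = 0.01, seed = 8, shape = "peak")
  full <- fit_depth_lmm(d, "y")
  null <- fit_fixed_only(d, "y")
  expect_lt(full$aic, null$aic)
  expect_equal(full$aic, 2 * full$k - 2 * full$loglik)
  expect_equal(null$aic, 2 * null$k - 2 * null$loglik)
})

test_that("BLUPs track a monotone injected depth trend", {
  d <- sim_lmm_data(depth_amp = 0.06, sigma = 0.005, seed = 9)
  fit <- fit_depth_lmm(d, "y")
  sp <- blup_depth_correlation(fit)
  expect_gt(sp$rho_spearman, 0.8)
  # strictly monotone BLUPs give |rho| = 1
  fake <- fit
  fake$blups$blup <- sort(rnorm(nrow(fake$blups)))
  expect_equal(blup_depth_correlation(fake)$rho_spearman, 1)
  fake$blups$blup <- rev(fake$blups$blup)
  expect_equal(blup_depth_correlation(fake)$rho_spearman, -1)
})

test_that("estimates agree with nlme gls under the equivalent correlation", {
  skip_if_not_installed("nlme")
  d <- sim_lmm_data(n = 24, depth_amp = 0.04, sigma = 0.01, seed = 10,
                    unique_depths = TRUE)
  full <- fit_depth_lmm(d, "y")
  ref <- nlme::gls(y ~ fraction + log_reads, data = d, method = "ML",
                   correlation = nlme::corExp(form = ~depth, nugget = TRUE))
  expect_equal(unname(full$coefficients), unname(coef(ref)),
               tolerance = 1e-3)
  expect_equal(full$loglik, as.numeric(logLik(ref)), tolerance = 1e-3)
})

test_that("estimator bias shrinks with sample size", {
  est <- function(n) {
    mean(vapply(1:12, function(i) {
      d <- sim_lmm_data(n = n, beta_frac = 0.05, depth_amp = 0.02,
                        sigma = 0.02, seed = 100 + i)
      unname(fit_depth_lmm(d, "y")$coefficients["fraction"])
    }, numeric(1)))
  }
  expect_lte(abs(est(96) - 0.05), abs(est(24) - 0.05) + 0.004)
})

test_that("input validation catches degenerate designs", {
  d <- sim_lmm_data()
  expect_error(fit_depth_lmm(d[1:6, ], "y"), "at least 8")
  d2 <- dplyr::mutate(d, depth = 100)
  expect_error(fit_depth_lmm(d2, "y"), "unique depths")
  expect_error(blup_depth_correlation(
    fit_depth_lmm(dplyr::mutate(d, depth = rep(c(10, 50), 24)), "y")),
    "3 unique depths")
  tt <- tidy(fit_depth_lmm(d, "y"))
  expect_named(tt, c("term", "estimate", "std.error", "p.value"))
})
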