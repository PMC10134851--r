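#' Linear mixed model with an exponential depth correlation structure
#'
#' Fits, by maximum likelihood, the marginal Gaussian model
#' \deqn{y = X\beta + b(depth) + \epsilon,\qquad
#'       b \sim N(0, \sigma_b^2 K),\quad K_{ij} = \exp(-|d_i - d_j|/\rho),}
#' where the fixed effects are an intercept, the size fraction
#' (particle = 1, free-living = 0) and log10 total reads, and the random
#' effect is indexed by the unique sampling depths with an exponential
#' spatial correlation of range `rho` (meters) to capture autocorrelation
#' and nonlinearity in the water column. The likelihood is profiled over
#' the fixed effects and the residual variance and maximized over
#' `(log(sigma_b^2/sigma^2), log(rho))` with a multi-start grid
#' (rho in 1, 10, 100, 1000 m) to avoid local optima; the variance-ratio
#' boundary (no depth effect) is an admissible solution.
#'
#' @param data Tibble with one row per sample: the response column, a
#'   binary `fraction`, `depth` in meters, and either `log_reads` or
#'   `total_reads` (log10 is taken).
#' @param response Name of the response column (string).
#' @return An object of class `depth_lmm`: fixed-effect estimates with
#'   Wald standard errors and t p-values (n - k residual df), variance
#'   components `sigma_b2`, `sigma2`, correlation range `range_rho` (m),
#'   `loglik`, `aic` (`2k - 2 loglik`, k = 6 estimated parameters), and
#'   per-unique-depth random-effect predictions (`blups`).
#' @export
#' @seealso [fit_fixed_only()], [likelihood_ratio_test()],
#'   [blup_depth_correlation()]
fit_depth_lmm <- function(data, response) {
  prep <- .lmm_design(data, response)
  y <- prep$y; X <- prep$X; n <- length(y)
  if (n < 8) stop("need at least 8 samples", call. = FALSE)
  du <- sort(unique(prep$depth))
  if (length(du) < 2) stop("need at least 2 unique depths", call. = FALSE)
  Z <- outer(prep$depth, du, `==`) * 1
  D <- abs(outer(du, du, `-`))

  profile_ll <- function(log_lambda, log_rho) {
    lambda <- exp(log_lambda); rho <- exp(log_rho)
    V <- diag(n) + lambda * (Z %*% exp(-D / rho) %*% t(Z))
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(list(ll = -1e10))
    Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
    Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
    XtViX <- crossprod(X, Vi_X)
    beta <- solve(XtViX, crossprod(X, Vi_y))
    r <- y - X %*% beta
    Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
    s2 <- max(as.numeric(crossprod(r, Vi_r)) / n, 1e-300)
    ll <- -n / 2 * log(2 * pi * s2) - sum(log(diag(ch))) - n / 2
    list(ll = ll, beta = as.vector(beta), s2 = s2, ch = ch,
         XtViX = XtViX, Vi_r = Vi_r)
  }

  obj <- function(par) -profile_ll(par[1], par[2])$ll
  starts <- expand.grid(log_lambda = log(c(0.01, 1, 100)),
                        log_rho = log(c(1, 10, 100, 1000)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(as.numeric(starts[i, ]), obj, method = "L-BFGS-B",
                   lower = c(-25, log(1e-2)), upper = c(25, log(1e6))),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("mixed-model optimization failed to converge",
                          call. = FALSE)
  sol <- profile_ll(best$par[1], best$par[2])
  lambda <- exp(best$par[1]); rho <- exp(best$par[2])
  s2 <- sol$s2; sb2 <- lambda * s2
  beta <- sol$beta
  se <- sqrt(pmax(diag(s2 * solve(sol$XtViX)), 0))
  k_fixed <- ncol(X)
  tval <- ifelse(se > 0, beta / se, sign(beta) * Inf)
  pval <- 2 * stats::pt(abs(tval), df = n - k_fixed, lower.tail = FALSE)
  Ku <- exp(-D / rho)
  blup <- as.vector(sb2 / s2 * Ku %*% t(Z) %*% sol$Vi_r)
  k_total <- k_fixed + 3L  # sigma_b2, rho, sigma2
  structure(list(
    coefficients = stats::setNames(beta, colnames(X)),
    se = stats::setNames(se, colnames(X)),
    p_value = stats::setNames(pval, colnames(X)),
    sigma_b2 = sb2, sigma2 = s2, range_rho = rho,
    loglik = sol$ll, aic = 2 * k_total - 2 * sol$ll,
    k = k_total, n = n, response = response,
    blups = tibble::tibble(depth = du, blup = blup),
    random = TRUE), class = "depth_lmm")
}

.lmm_design <- function(data, response) {
  stopifnot(is.data.frame(data), response %in% names(data),
            all(c("fraction", "depth") %in% names(data)))
  lr <- if ("log_reads" %in% names(data)) data$log_reads
        else if ("total_reads" %in% names(data)) log10(data$total_reads)
        else stop("need a log_reads or total_reads column", call. = FALSE)
  X <- cbind(`(Intercept)` = 1,
             fraction = as.numeric(data$fraction),
             log_reads = lr)
  if (qr(X)$rank < ncol(X)) stop("collinear fixed effects", call. = FALSE)
  list(y = data[[response]], X = X, depth = data$depth)
}

#' Fixed-effects-only null model (depth as a fixed covariate)
#'
#' Ordinary maximum-likelihood regression of the response on fraction,
#' log10 reads and asinh-transformed depth as a fixed effect — the null
#' against which the depth random effect is tested. asinh compresses the
#' weak variation below the upper water column the same way the ordination
#' treats depth.
#'
#' @inheritParams fit_depth_lmm
#' @param include_depth Include `asinh(depth)` as a fixed covariate
#'   (default TRUE).
#' @return A `depth_lmm` object with `sigma_b2 = 0` and no BLUPs.
#' @export
fit_fixed_only <- function(data, response, include_depth = TRUE) {
  prep <- .lmm_design(data, response)
  X <- prep$X
  if (include_depth) X <- cbind(X, asinh_depth = asinh(prep$depth))
  if (qr(X)$rank < ncol(X)) stop("collinear fixed effects", call. = FALSE)
  fit <- stats::lm.fit(X, prep$y)
  n <- length(prep$y); k_fixed <- ncol(X)
  r <- fit$residuals
  s2 <- max(sum(r^2) / n, 1e-300)  # ML estimate
  ll <- -n / 2 * log(2 * pi * s2) - n / 2
  XtXi <- chol2inv(chol(crossprod(X)))
  se <- sqrt(diag(s2 * XtXi))
  tval <- ifelse(se > 0, fit$coefficients / se, sign(fit$coefficients) * Inf)
  pval <- 2 * stats::pt(abs(tval), df = n - k_fixed, lower.tail = FALSE)
  k_total <- k_fixed + 1L  # + sigma2
  structure(list(
    coefficients = stats::setNames(fit$coefficients, colnames(X)),
    se = stats::setNames(se, colnames(X)),
    p_value = stats::setNames(pval, colnames(X)),
    sigma_b2 = 0, sigma2 = s2, range_rho = NA_real_,
    loglik = ll, aic = 2 * k_total - 2 * ll,
    k = k_total, n = n, response = response,
    blups = NULL, random = FALSE), class = "depth_lmm")
}

#' Likelihood ratio test between the depth random-effect model and its null
#'
#' `statistic = 2 (loglik_full - loglik_null)`, referred to a chi-squared
#' with 2 df (the random-structure parameters `sigma_b2` and `rho` that
#' replace the fixed depth term). Because `sigma_b2 = 0` lies on the
#' boundary the naive p-value is conservative; a halved (50:50 mixture)
#' p-value is also reported. The AIC difference (null minus full) is
#' returned alongside.
#'
#' @param full A `depth_lmm` from [fit_depth_lmm()].
#' @param null A `depth_lmm` from [fit_fixed_only()] on the same data.
#' @return A one-row tibble: `statistic`, `df`, `p_value`,
#'   `p_value_boundary`, `delta_aic`.
#' @export
likelihood_ratio_test <- function(full, null) {
  stopifnot(inherits(full, "depth_lmm"), inherits(null, "depth_lmm"))
  if (!isTRUE(full$random) || isTRUE(null$random)) {
    stop("`full` must carry the depth random effect and `null` must not",
         call. = FALSE)
  }
  if (full$n != null$n || full$response != null$response) {
    stop("models were not fitted to the same data", call. = FALSE)
  }
  stat <- 2 * (full$loglik - null$loglik)
  df <- 2L
  p <- stats::pchisq(max(stat, 0), df = df, lower.tail = FALSE)
  tibble::tibble(statistic = stat, df = df, p_value = p,
                 p_value_boundary = p / 2,
                 delta_aic = null$aic - full$aic)
}

#' Spearman correlation of depth random effects with depth
#'
#' Rank correlation between the per-depth random-effect predictions
#' (BLUPs) and depth itself: a monotone depth trend in the response shows
#' up as |rho| near 1.
#'
#' @param fit A `depth_lmm` from [fit_depth_lmm()].
#' @return A one-row tibble: `rho_spearman`, `p_value`, `n_depths`.
#' @export
blup_depth_correlation <- function(fit) {
  stopifnot(inherits(fit, "depth_lmm"), isTRUE(fit$random))
  if (nrow(fit$blups) < 3) stop("need at least 3 unique depths", call. = FALSE)
  ct <- suppressWarnings(
    stats::cor.test(fit$blups$blup, fit$blups$depth, method = "spearman"))
  tibble::tibble(rho_spearman = unname(ct$estimate),
                 p_value = ct$p.value,
                 n_depths = nrow(fit$blups))
}

#' @exportS3Method base::print
print.depth_lmm <- function(x, ...) {
  cat("Depth ", if (x$random) "mixed model" else "fixed-effects model",
      " for '", x$response, "' (n = ", x$n, ")\n", sep = "")
  print(round(cbind(estimate = x$coefficients, se = x$se, p = x$p_value), 5))
  if (x$random) {
    cat(sprintf("sigma_b2 = %.4g, sigma2 = %.4g, rho = %.4g m\n",
                x$sigma_b2, x$sigma2, x$range_rho))
  }
  cat(sprintf("logLik = %.3f, AIC = %.3f\n", x$loglik, x$aic))
  invisible(x)
}

#' @rdname fit_depth_lmm
#' @param x A `depth_lmm` object.
#' @param ... Unused.
#' @export
tidy.depth_lmm <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients),
                 std.error = unname(x$se),
                 p.value = unname(x$p_value))
}

#' @rdname fit_depth_lmm
#' @export
glance.depth_lmm <- function(x, ...) {
  tibble::tibble(sigma_b2 = x$sigma_b2, sigma2 = x$sigma2,
                 range_rho = x$range_rho, logLik = x$loglik, AIC = x$aic,
                 n = x$n, df = x$k)
}
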