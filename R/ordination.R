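#' Partial out a covariate from a multivariate response
#'
#' Regresses every (centered) property column on an intercept plus the
#' covariate and returns the residuals, so that all downstream ordination
#' axes are exactly uncorrelated with the covariate (here, sequencing
#' depth, whose technical bias would otherwise contaminate the axes).
#'
#' @param Y Numeric matrix or data frame, samples by properties.
#' @param z Numeric covariate vector, one value per sample.
#' @return A numeric matrix of residuals with the dimensions of `Y`; every
#'   column has zero mean and zero linear correlation with `z`.
#' @export
condition_out <- function(Y, z) {
  Y <- as.matrix(Y)
  stopifnot(is.numeric(Y), length(z) == nrow(Y))
  if (stats::sd(z) == 0) stop("covariate is constant; nothing to condition on",
                              call. = FALSE)
  X <- cbind(1, z)
  qr_x <- qr(X)
  Y - X %*% qr.coef(qr_x, Y)
}

#' Principal axes of a (residual) property matrix
#'
#' Eigen-decomposition of the covariance of the samples-by-properties
#' matrix, typically after [condition_out()]: unconstrained ordination of
#' the residual space, with site scores and the fraction of residual
#' variance carried by each axis.
#'
#' @param Y Numeric matrix, samples by properties (rows will be centered).
#' @param sample_id Optional sample identifiers for the score rows.
#' @param conditioned Name of the covariate removed upstream (metadata
#'   only; recorded in the result).
#' @return An object of class `stoich_ordination`: list with `scores`
#'   (tibble of site scores), `var_fraction` (per-axis variance fractions,
#'   nonincreasing), `conditioned`.
#' @export
principal_axes <- function(Y, sample_id = NULL, conditioned = NA_character_) {
  Y <- as.matrix(Y)
  if (nrow(Y) < 2) stop("need at least 2 samples", call. = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  sv <- svd(Yc)
  ev <- sv$d^2 / (nrow(Y) - 1)
  if (sum(ev) <= .Machine$double.eps) {
    stop("residual matrix has rank 0; no axes to extract", call. = FALSE)
  }
  keep <- ev > max(ev) * 1e-12
  scores <- Yc %*% sv$v[, keep, drop = FALSE]
  colnames(scores) <- paste0("axis", seq_len(ncol(scores)))
  scores <- tibble::as_tibble(scores)
  if (!is.null(sample_id)) scores <- dplyr::bind_cols(
    tibble::tibble(sample_id = sample_id), scores)
  structure(
    list(scores = scores,
         var_fraction = ev[keep] / sum(ev),
         conditioned = conditioned),
    class = "stoich_ordination")
}

#' Covariate-conditioned ordination of sample profiles
#'
#' Standardizes the property columns (they mix Daltons, fractions and
#' atom counts), removes the sequencing-depth covariate with
#' [condition_out()], and ordinates the residuals with [principal_axes()].
#'
#' @param data Tibble with `sample_id`, the covariate column and numeric
#'   property columns.
#' @param condition Name of the covariate column to condition out
#'   (e.g. `"seq_depth"`).
#' @param properties Character vector of property columns; default all
#'   numeric columns except the covariate.
#' @param standardize Scale properties to unit variance first (default
#'   TRUE). Constant columns are dropped.
#' @return A `stoich_ordination` object (see [principal_axes()]).
#' @export
ordinate_profiles <- function(data, condition, properties = NULL,
                              standardize = TRUE) {
  stopifnot(is.data.frame(data), condition %in% names(data))
  if (is.null(properties)) {
    properties <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                          condition)
  }
  Y <- as.matrix(data[, properties, drop = FALSE])
  keep <- apply(Y, 2, stats::sd) > 0
  Y <- Y[, keep, drop = FALSE]
  if (standardize) Y <- scale(Y)
  R <- condition_out(Y, data[[condition]])
  principal_axes(R,
                 sample_id = if ("sample_id" %in% names(data)) data$sample_id,
                 conditioned = condition)
}

#' @exportS3Method base::print
print.stoich_ordination <- function(x, ...) {
  cat("Ordination (conditioned on ", x$conditioned, "): ",
      length(x$var_fraction), " axes\n", sep = "")
  cat("variance fractions:",
      paste(sprintf("%.3f", utils::head(x$var_fraction, 5)), collapse = " "),
      if (length(x$var_fraction) > 5) "...", "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname ordinate_profiles
#' @param x A `stoich_ordination` object.
#' @param ... Unused.
#' @export
tidy.stoich_ordination <- function(x, ...) x$scores

#' @rdname ordinate_profiles
#' @export
glance.stoich_ordination <- function(x, ...) {
  tibble::tibble(axis = seq_along(x$var_fraction),
                 var_fraction = x$var_fraction,
                 conditioned = x$conditioned)
}

#' Permutational variance partitioning for a single factor
#'
#' Fraction of multivariate variance explained by one factor
#' (`R^2 = SS_fit / SS_total` from multivariate least squares) with a
#' permutation p-value: factor labels are permuted `n_perm` times and
#' `p = (1 + #(R2_perm >= R2_obs)) / (1 + n_perm)`. Used after conditioning
#' to ask how much residual stoichiogenomic variation size fraction and
#' asinh-transformed depth each explain.
#'
#' @param Y Numeric matrix or data frame, samples by properties (e.g.
#'   ordination residuals or scores).
#' @param fac Factor, character or numeric vector, one value per sample.
#'   Depth should be passed as `asinh(depth)`.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @param name Label stored in the output (defaults to the expression).
#' @return A one-row tibble: `factor`, `r2`, `p_value`, `n_permutations`,
#'   `seed`.
#' @export
permanova_r2 <- function(Y, fac, n_perm = 999, seed = 1L,
                         name = deparse(substitute(fac))) {
  Y <- as.matrix(Y)
  stopifnot(length(fac) == nrow(Y))
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  ss_tot <- sum(Yc^2)
  r2_of <- function(f) {
    X <- stats::model.matrix(~f)
    fit <- qr.fitted(qr(X), Yc)
    sum(fit^2) / ss_tot
  }
  r2_obs <- r2_of(fac)
  perm_r2 <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) r2_of(sample(fac)), numeric(1))
  })
  p <- (1 + sum(perm_r2 >= r2_obs)) / (1 + n_perm)
  tibble::tibble(factor = name, r2 = r2_obs, p_value = p,
                 n_permutations = as.integer(n_perm), seed = as.integer(seed))
}
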