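#' Center and scale a matrix of predictors or responses
#'
#' Standardizes columns to mean 0 and unit *population* standard deviation
#' (divisor n), as done to the weighted amino-acid averages before the
#' driver regression so that residues with very different dynamic ranges
#' compete on the same penalty scale. Constant columns become all zeros
#' with a warning.
#'
#' @param x Numeric matrix or data frame (>= 2 rows).
#' @return A numeric matrix with attributes `scaled:center` and
#'   `scaled:scale`.
#' @export
#' @examples
#' center_scale(cbind(a = c(1, 2, 3)))
center_scale <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 rows to scale", call. = FALSE)
  mu <- colMeans(x)
  sd_pop <- sqrt(colMeans(sweep(x, 2, mu)^2))
  if (any(sd_pop == 0)) {
    warning("constant column(s) set to zero: ",
            paste(colnames(x)[sd_pop == 0], collapse = ", "), call. = FALSE)
  }
  out <- sweep(sweep(x, 2, mu), 2, ifelse(sd_pop == 0, 1, sd_pop), `/`)
  attr(out, "scaled:center") <- mu
  attr(out, "scaled:scale") <- sd_pop
  out
}

#' Multiresponse lasso linking amino-acid frequencies to stoichiogenomic
#' responses
#'
#' Fits an L1-regularized multiresponse ("multigaussian") linear model of
#' the three responses — binarized size fraction, weighted N-ARSC and
#' weighted side-chain N:C — on the 20 standardized amino-acid
#' frequencies of a marker gene. The grouped penalty
#' \eqn{\lambda \sum_j \|\beta_{j\cdot}\|_2} couples each residue's
#' coefficients across the responses, removing redundant amino acids as a
#' block; a plain per-entry L1 penalty (independent gaussian fits) is
#' available with `grouped = FALSE`. The penalty is chosen by k-fold
#' cross-validation at the minimum mean squared error averaged over folds
#' and responses; fold assignment is a deterministic function of
#' `(n, folds, seed)`.
#'
#' @param X Numeric matrix, samples by 20 amino acids, standardized (see
#'   [center_scale()]).
#' @param Y Numeric matrix, samples by responses, standardized.
#' @param folds Number of CV folds (default 10).
#' @param seed Integer seed controlling fold assignment.
#' @param grouped Use the grouped multiresponse penalty (default TRUE).
#' @param nlambda,lambda.min.ratio Penalty grid: `nlambda` log-spaced
#'   values from the smallest all-zero penalty down to
#'   `lambda.min.ratio` times it.
#' @return An object of class `aa_driver_fit`: `coefficients` (amino acid
#'   by response), `intercepts`, `lambda_star`, `cv_path` (tibble of
#'   lambda and mean CV MSE), the underlying glmnet fit(s), `seed`.
#' @export
fit_multitask_lasso <- function(X, Y, folds = 10, seed = 1L, grouped = TRUE,
                                nlambda = 100, lambda.min.ratio = 1e-4) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  stopifnot(nrow(Y) == n)
  if (n < folds) stop("fewer samples than CV folds", call. = FALSE)
  foldid <- withr::with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  if (grouped) {
    cv <- glmnet::cv.glmnet(X, Y, family = "mgaussian", foldid = foldid,
                            standardize = FALSE, nlambda = nlambda,
                            lambda.min.ratio = lambda.min.ratio)
    cf <- stats::coef(cv, s = "lambda.min")
    beta <- do.call(cbind, lapply(cf, function(m) as.matrix(m)[-1, 1]))
    colnames(beta) <- colnames(Y)
    intercepts <- vapply(cf, function(m) as.matrix(m)[1, 1], numeric(1))
    cv_path <- tibble::tibble(lambda = cv$lambda, cv_mse = cv$cvm)
    lambda_star <- cv$lambda.min
    fits <- cv
  } else {
    fits <- lapply(seq_len(ncol(Y)), function(j) {
      glmnet::cv.glmnet(X, Y[, j], family = "gaussian", foldid = foldid,
                        standardize = FALSE, nlambda = nlambda,
                        lambda.min.ratio = lambda.min.ratio)
    })
    beta <- vapply(fits, function(f) as.matrix(stats::coef(f, s = "lambda.min"))[-1, 1],
                   numeric(ncol(X)))
    colnames(beta) <- colnames(Y)
    intercepts <- vapply(fits, function(f) as.matrix(stats::coef(f, s = "lambda.min"))[1, 1],
                         numeric(1))
    cv_path <- tibble::tibble(lambda = fits[[1]]$lambda,
                              cv_mse = rowMeans(vapply(fits, function(f)
                                f$cvm[seq_along(fits[[1]]$lambda)],
                                numeric(length(fits[[1]]$lambda)))))
    lambda_star <- vapply(fits, function(f) f$lambda.min, numeric(1))
  }
  rownames(beta) <- colnames(X)
  structure(list(coefficients = beta,
                 intercepts = stats::setNames(intercepts, colnames(Y)),
                 lambda_star = lambda_star, cv_path = cv_path,
                 grouped = grouped, fit = fits, seed = as.integer(seed),
                 folds = as.integer(folds)),
            class = "aa_driver_fit")
}

#' Train/test split evaluation of the amino-acid driver model
#'
#' Draws a deterministic 70/30 split, trains the multiresponse lasso (with
#' internal cross-validation) on the training samples only, predicts the
#' held-out samples, and regresses actual on predicted per response,
#' reporting the slope and adjusted R-squared of each regression.
#'
#' @inheritParams fit_multitask_lasso
#' @param train_fraction Fraction of samples used for training (default
#'   0.7).
#' @return A list with `model` (the `aa_driver_fit` trained on the split)
#'   and `evaluation`, a tibble with one row per response: `response`,
#'   `test_slope`, `test_adj_r2`, `n_test`.
#' @export
split_and_evaluate <- function(X, Y, seed = 1L, train_fraction = 0.7,
                               folds = 10, grouped = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  idx <- withr::with_seed(seed, sample(n))
  n_train <- floor(train_fraction * n)
  train <- sort(idx[seq_len(n_train)])
  test <- sort(idx[-seq_len(n_train)])
  if (length(test) < 3) stop("test split has fewer than 3 samples", call. = FALSE)
  model <- fit_multitask_lasso(X[train, , drop = FALSE], Y[train, , drop = FALSE],
                               folds = folds, seed = seed, grouped = grouped)
  pred <- X[test, , drop = FALSE] %*% model$coefficients +
    matrix(model$intercepts, nrow = length(test), ncol = ncol(Y), byrow = TRUE)
  evaluation <- purrr::map_dfr(seq_len(ncol(Y)), function(j) {
    if (stats::sd(pred[, j]) == 0) {
      return(tibble::tibble(response = colnames(Y)[j], test_slope = NA_real_,
                            test_adj_r2 = NA_real_, n_test = length(test)))
    }
    fit <- stats::lm(Y[test, j] ~ pred[, j])
    tibble::tibble(response = colnames(Y)[j],
                   test_slope = unname(stats::coef(fit)[2]),
                   test_adj_r2 = summary(fit)$adj.r.squared,
                   n_test = length(test))
  })
  list(model = model, evaluation = evaluation)
}

#' Rank amino-acid drivers of each response
#'
#' Orders amino acids by absolute coefficient magnitude within each
#' response of a fitted driver model; zero-coefficient residues are
#' omitted and exact ties are broken alphabetically.
#'
#' @param model An `aa_driver_fit`.
#' @return A tibble `response`, `residue`, `coefficient`, `rank`.
#' @export
rank_drivers <- function(model) {
  stopifnot(inherits(model, "aa_driver_fit"))
  beta <- model$coefficients
  out <- tibble::as_tibble(beta, rownames = "residue") |>
    tidyr::pivot_longer(-"residue", names_to = "response",
                        values_to = "coefficient") |>
    dplyr::filter(.data$coefficient != 0) |>
    dplyr::arrange(.data$response, dplyr::desc(abs(.data$coefficient)),
                   .data$residue) |>
    dplyr::group_by(.data$response) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
  if (nrow(out) == 0) {
    warning("all coefficients are zero; empty ranking", call. = FALSE)
  }
  out
}

#' Amino-acid driver analysis from tidy profile tables
#'
#' Data-frame front end: takes a per-sample marker amino-acid profile
#' (columns `aa_A` ... `aa_Y` or bare residue codes) together with the
#' response columns, standardizes both sides, and runs
#' [split_and_evaluate()].
#'
#' @param data Tibble with `sample_id`, 20 amino-acid frequency columns
#'   and the response columns.
#' @param responses Character vector of response column names (default
#'   `c("fraction", "n_arsc", "nc_ratio")`).
#' @param ... Passed to [split_and_evaluate()].
#' @return As [split_and_evaluate()].
#' @export
fit_aa_drivers <- function(data, responses = c("fraction", "n_arsc", "nc_ratio"),
                           ...) {
  stopifnot(is.data.frame(data), all(responses %in% names(data)))
  aa_cols <- intersect(c(paste0("aa_", .aa_codes), .aa_codes), names(data))
  if (length(aa_cols) != 20) {
    stop("expected 20 amino-acid frequency columns (aa_A ... aa_Y)", call. = FALSE)
  }
  X <- center_scale(as.matrix(data[, aa_cols]))
  colnames(X) <- sub("^aa_", "", aa_cols)
  Y <- center_scale(as.matrix(data[, responses]))
  split_and_evaluate(X, Y, ...)
}

#' @exportS3Method base::print
print.aa_driver_fit <- function(x, ...) {
  nz <- sum(rowSums(x$coefficients != 0) > 0)
  cat("Multiresponse lasso driver model (",
      if (x$grouped) "grouped" else "independent", " penalty)\n", sep = "")
  cat("lambda* =", format(x$lambda_star, digits = 4),
      "|", nz, "of", nrow(x$coefficients), "amino acids retained\n")
  invisible(x)
}

#' @rdname fit_multitask_lasso
#' @param x An `aa_driver_fit` object.
#' @param ... Unused.
#' @export
tidy.aa_driver_fit <- function(x, ...) {
  tibble::as_tibble(x$coefficients, rownames = "residue") |>
    tidyr::pivot_longer(-"residue", names_to = "response",
                        values_to = "coefficient")
}

#' @rdname fit_multitask_lasso
#' @export
glance.aa_driver_fit <- function(x, ...) {
  tibble::tibble(lambda_star = x$lambda_star[1],
                 n_nonzero = sum(rowSums(x$coefficients != 0) > 0),
                 grouped = x$grouped, folds = x$folds, seed = x$seed)
}
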