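# The L1-penalised least-squares fitting contract used by both regression
# stages and the expression-only baseline.
#
# Conventions: predictors are standardised here (zero mean, unit 1/n
# variance) and glmnet is called with standardize = FALSE, so the objective
# is exactly (1/2n)||y - b0 - Xs b||^2 + lambda ||b||_1 on the standardised
# design; coefficients are returned on the original predictor scale. The
# intercept is never penalised. lambda = 0 is fitted by ordinary least
# squares so the OLS limit is exact.

#' Fit a LASSO regression
#'
#' @param x Numeric predictor matrix, n x p (column names kept on the
#'   coefficients). Zero-variance columns are dropped to coefficient 0 and
#'   recorded in the result.
#' @param y Numeric response of length n.
#' @param lambda Penalty weight: a nonnegative number, or `"cv"` to select
#'   the value minimising mean k-fold cross-validated squared error over a
#'   log-spaced path of 100 values from `lambda_max` down to
#'   `1e-3 * lambda_max`.
#' @param cv_folds Number of CV folds when `lambda = "cv"` (default 10).
#' @param seed Integer seed fixing the CV fold assignment.
#' @return A `lasso_fit` list: `coefficients` (named, original scale),
#'   `intercept`, `lambda_selected`, `rss`, `fitted`, `dropped` (names of
#'   zero-variance columns).
#' @export
lasso_fit <- function(x, y, lambda = "cv", cv_folds = 10L, seed = 1L) {
  x <- as.matrix(x)
  n <- length(y)
  if (n < 2L) stopf("lasso_fit needs at least 2 observations")
  if (!identical(lambda, "cv") &&
      (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0))
    stopf("lambda must be \"cv\" or a single nonnegative number")
  if (nrow(x) != n) stopf("nrow(x) must equal length(y)")
  p <- ncol(x)
  if (is.null(colnames(x)) && p > 0L) colnames(x) <- paste0("V", seq_len(p))
  coefs <- stats::setNames(numeric(p), colnames(x))
  finish <- function(intercept, lam) {
    intercept <- unname(intercept)
    fitted <- as.numeric(intercept + if (p > 0L) x %*% coefs else 0)
    structure(list(coefficients = coefs, intercept = intercept,
                   lambda_selected = lam, rss = sum((y - fitted)^2),
                   fitted = fitted,
                   dropped = names(coefs)[is_dropped]),
              class = "lasso_fit")
  }
  ctr <- colMeans(x)
  scl <- sqrt(colMeans(sweep(x, 2L, ctr)^2))
  is_dropped <- scl < 1e-12
  keep <- which(!is_dropped)
  if (length(keep) == 0L) {
    lam0 <- if (identical(lambda, "cv")) 0 else lambda
    return(finish(mean(y), lam0))
  }
  xs <- sweep(sweep(x[, keep, drop = FALSE], 2L, ctr[keep]), 2L, scl[keep], "/")
  # glmnet needs >= 2 columns; pad single-predictor designs with a null column
  padded <- ncol(xs) == 1L
  if (padded) xs <- cbind(xs, 0)
  unscale <- function(b_std, b0_std) {
    if (padded) b_std <- b_std[1L]
    b <- b_std / scl[keep]
    coefs[keep] <<- b
    b0_std - sum(b * ctr[keep])
  }
  if (!identical(lambda, "cv") && lambda == 0) {
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1, xs), y)
    b <- fit$coefficients
    b[is.na(b)] <- 0
    return(finish(unscale(b[-1L], b[1L]), 0))
  }
  lambda_max <- max(abs(crossprod(xs, y - mean(y)))) / n
  if (lambda_max < 1e-12) {
    # response carries no linear signal on any predictor
    lam0 <- if (identical(lambda, "cv")) 0 else lambda
    return(finish(mean(y), lam0))
  }
  if (identical(lambda, "cv")) {
    k <- max(3L, min(cv_folds, n))
    path <- exp(seq(log(lambda_max), log(lambda_max * 1e-3), length.out = 100L))
    foldid <- make_folds(n, k, seed)
    cvfit <- glmnet::cv.glmnet(xs, y, family = "gaussian", lambda = path,
                               foldid = foldid, standardize = FALSE,
                               thresh = 1e-10, grouped = n >= 3L * k)
    lam <- cvfit$lambda.min
    i <- which.min(abs(cvfit$glmnet.fit$lambda - lam))
    b0 <- unscale(as.numeric(cvfit$glmnet.fit$beta[, i]),
                  cvfit$glmnet.fit$a0[i])
    return(finish(b0, lam))
  }
  hi <- max(lambda_max, lambda * (1 + 1e-6))
  path <- exp(seq(log(hi), log(lambda), length.out = 50L))
  path[length(path)] <- lambda
  fit <- glmnet::glmnet(xs, y, family = "gaussian", lambda = path,
                        standardize = FALSE, thresh = 1e-12, maxit = 1e7)
  i <- length(fit$lambda)
  b0 <- unscale(as.numeric(fit$beta[, i]), fit$a0[i])
  finish(b0, lambda)
}

#' @export
print.lasso_fit <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat(sprintf("lasso_fit: %d/%d nonzero coefficients, lambda = %.4g, rss = %.4g\n",
              nz, length(x$coefficients), x$lambda_selected, x$rss))
  invisible(x)
}
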