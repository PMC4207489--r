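# Leave-one-regulator-out nested-model F-test with Benjamini-Hochberg
# correction, identifying the predominant TF/miRNA regulators.
#
# The test operates on the stage-1 regressions (the stage where regulator
# data columns enter the design): dropping regulator r removes one predictor
# column from every sample's design, i.e. N activity parameters. Residual
# sums of squares are pooled over samples. By default both the full and the
# reduced models are refit by ordinary least squares on the full candidate
# set ("refit_ols"), which guarantees exact nesting (penalised fits are not
# nested, so their RSS difference can be negative); a "lasso" mode using the
# penalised fits is available, with negative F clipped to 0.

# Per-sample OLS residual sum of squares for a design (intercept added).
ols_rss <- function(design, y) {
  fit <- stats::lm.fit(cbind(1, design), y)
  sum(fit$residuals^2)
}

#' Pooled stage-1 RSS with one regulator left out
#'
#' Refits every sample's stage-1 regression without the named regulator's
#' predictor column and returns the pooled (summed) residual sum of squares.
#'
#' @param bundle An [omics_bundle()].
#' @param regulator_id A TF or miRNA identifier from the bundle.
#' @param mode `"refit_ols"` (default) or `"lasso"`.
#' @param lambda,cv_folds,seed Passed to [lasso_fit()] in `"lasso"` mode.
#' @return Pooled RSS (a single number).
#' @export
leave_one_out_rss <- function(bundle, regulator_id, mode = c("refit_ols", "lasso"),
                              lambda = "cv", cv_folds = 10L, seed = 1L) {
  mode <- match.arg(mode)
  if (!regulator_id %in% c(bundle$tfs, bundle$mirnas))
    stopf("unknown regulator '%s'", regulator_id)
  seeds <- sub_seeds(seed, length(bundle$samples))
  total <- 0
  for (i in seq_along(bundle$samples)) {
    s <- bundle$samples[i]
    des <- stage1_design(bundle, s)
    des <- des[, colnames(des) != regulator_id, drop = FALSE]
    total <- total + if (mode == "refit_ols") ols_rss(des, bundle$E[, s])
    else lasso_fit(des, bundle$E[, s], lambda = lambda,
                   cv_folds = cv_folds, seed = seeds[i])$rss
  }
  total
}

#' F statistic for a nested model comparison
#'
#' `f = max(0, ((rss_reduced - rss_full) / df_num) / (rss_full / df_den))`
#' with the upper-tail p-value from the F(df_num, df_den) distribution.
#'
#' @param rss_full,rss_reduced Residual sums of squares of the full and
#'   reduced models (`rss_full` must be positive).
#' @param df_num,df_den Positive degrees of freedom.
#' @return List with `f` and `p`.
#' @export
f_statistic <- function(rss_full, rss_reduced, df_num, df_den) {
  if (rss_full <= 0) stopf("rss_full must be positive")
  if (df_num < 1 || df_den < 1) stopf("degrees of freedom must be >= 1")
  f <- max(0, ((rss_reduced - rss_full) / df_num) / (rss_full / df_den))
  list(f = f, p = stats::pf(f, df_num, df_den, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values (monotone in the sorted order, capped at 1,
#' input order restored). Thin validating wrapper over
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p_values Numeric vector in \[0, 1\].
#' @return Adjusted values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE) || anyNA(p_values))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Select predominant regulators by leave-one-out F-test
#'
#' Runs one nested-model test per TF and miRNA: the full stage-1 model
#' against the model with that regulator's column removed from every
#' sample's design. Default degrees of freedom: `df_num = N` (one activity
#' parameter removed per sample) and `df_den = N * (G - T - M - 3)` (pooled
#' per-sample residual dof); both are configurable. P-values are BH-adjusted
#' over the T + M regulators and regulators with FDR below the threshold are
#' flagged.
#'
#' @param bundle An [omics_bundle()].
#' @param fdr_threshold Selection threshold in (0, 1), default 0.1.
#' @param mode,lambda,cv_folds,seed As in [leave_one_out_rss()].
#' @param df_num,df_den Optional overrides of the default dof.
#' @return `data.frame` (one row per regulator, ranked by decreasing F) with
#'   columns `regulator`, `kind`, `rss_full`, `rss_reduced`, `f_statistic`,
#'   `p_value`, `fdr`, `selected`.
#' @export
select_regulators <- function(bundle, fdr_threshold = 0.1,
                              mode = c("refit_ols", "lasso"), lambda = "cv",
                              cv_folds = 10L, seed = 1L,
                              df_num = NULL, df_den = NULL) {
  mode <- match.arg(mode)
  if (fdr_threshold <= 0 || fdr_threshold >= 1)
    stopf("fdr_threshold must lie in (0, 1)")
  N <- length(bundle$samples); G <- length(bundle$genes)
  T_ <- length(bundle$tfs); M <- length(bundle$mirnas)
  if (is.null(df_num)) df_num <- N
  if (is.null(df_den)) df_den <- N * (G - T_ - M - 3L)
  if (df_den <= 0)
    stopf("too few genes for the F-test: df_den = %d", df_den)
  regs <- c(bundle$tfs, bundle$mirnas)
  kind <- rep(c("TF", "miRNA"), c(T_, M))
  seeds <- sub_seeds(seed, N)
  # full-model RSS pooled over samples, and per-regulator reduced RSS
  rss_full <- 0
  rss_red <- stats::setNames(numeric(length(regs)), regs)
  for (i in seq_len(N)) {
    s <- bundle$samples[i]
    des <- stage1_design(bundle, s)
    y <- bundle$E[, s]
    rss_full <- rss_full + if (mode == "refit_ols") ols_rss(des, y)
    else lasso_fit(des, y, lambda = lambda, cv_folds = cv_folds,
                   seed = seeds[i])$rss
    for (r in regs) {
      red <- des[, colnames(des) != r, drop = FALSE]
      rss_red[r] <- rss_red[r] + if (mode == "refit_ols") ols_rss(red, y)
      else lasso_fit(red, y, lambda = lambda, cv_folds = cv_folds,
                     seed = seeds[i])$rss
    }
  }
  stat <- lapply(rss_red, function(rr) f_statistic(rss_full, rr, df_num, df_den))
  out <- data.frame(regulator = regs, kind = kind,
                    rss_full = rss_full, rss_reduced = unname(rss_red),
                    f_statistic = vapply(stat, `[[`, numeric(1L), "f"),
                    p_value = vapply(stat, `[[`, numeric(1L), "p"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$fdr <- bh_adjust(out$p_value)
  out$selected <- out$fdr < fdr_threshold
  out[order(-out$f_statistic, out$regulator), , drop = FALSE]
}
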