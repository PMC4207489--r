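# The two-stage regression at the core of the package.
#
# Stage 1 (per sample s): y_gs ~ alpha_s + phi_s c_gs + psi_s d_gs
#                                + sum_t w_ts b_tg + sum_m u_ms (s_mg x_ms)
# regressed over genes g, yielding sample-specific TF activities w_ts and
# miRNA activities u_ms.
#
# Stage 2 (per gene g): y_gs ~ a_g + rho_g c_gs + tau_g d_gs
#                              + sum_{t: b_tg>0} theta_gt w_ts
#                              + sum_{m: s_mg>0} theta_gm u~_ms
# regressed over samples s, yielding regulator-gene interaction scores.
# u~ is the activity row rescaled by its cross-sample mean (see
# weight_mir_activities), which stabilises the sample-to-sample sign pattern.

# Stage-1 design matrix for one sample: G x (2 + T + M).
stage1_design <- function(bundle, s) {
  cbind(CNV = bundle$C[, s], DM = bundle$D[, s],
        t(bundle$B),
        t(bundle$S * bundle$X[, s]))
}

#' Infer sample-specific TF and miRNA activities (stage 1)
#'
#' For each sample independently, regresses the gene expression column on
#' copy number, methylation, the TF binding profiles and the
#' seed-count-times-miRNA-expression profiles via [lasso_fit()]. The fitted
#' coefficients of the binding columns are the latent TF activities, those of
#' the seed columns the miRNA activities, for that sample.
#'
#' @param bundle An [omics_bundle()].
#' @param lambda Penalty: `"cv"` (default) or a nonnegative number, passed to
#'   [lasso_fit()].
#' @param cv_folds CV folds for lambda selection.
#' @param seed Integer seed; per-sample CV fold assignments are derived from
#'   it deterministically.
#' @return A `stage1_fit` list with `alpha`, `phi`, `psi` (N-vectors:
#'   intercept, CNV and methylation offsets), activity matrices `W` (T x N)
#'   and `U` (M x N), `rss_per_sample` and `lambda_per_sample`.
#' @export
fit_stage1 <- function(bundle, lambda = "cv", cv_folds = 10L, seed = 1L) {
  N <- length(bundle$samples); G <- length(bundle$genes)
  T_ <- length(bundle$tfs); M <- length(bundle$mirnas)
  if (G <= 2L + T_ + M)
    warnf("stage 1 is under-determined: %d genes <= %d predictors (LASSO still defined)",
          G, 2L + T_ + M)
  seeds <- sub_seeds(seed, N)
  W <- matrix(0, T_, N, dimnames = list(bundle$tfs, bundle$samples))
  U <- matrix(0, M, N, dimnames = list(bundle$mirnas, bundle$samples))
  alpha <- phi <- psi <- rss <- lam <- stats::setNames(numeric(N), bundle$samples)
  for (i in seq_len(N)) {
    s <- bundle$samples[i]
    fit <- lasso_fit(stage1_design(bundle, s), bundle$E[, s],
                     lambda = lambda, cv_folds = cv_folds, seed = seeds[i])
    alpha[i] <- fit$intercept
    phi[i] <- fit$coefficients[["CNV"]]
    psi[i] <- fit$coefficients[["DM"]]
    W[, i] <- fit$coefficients[bundle$tfs]
    U[, i] <- fit$coefficients[bundle$mirnas]
    rss[i] <- fit$rss
    lam[i] <- fit$lambda_selected
  }
  structure(list(alpha = alpha, phi = phi, psi = psi, W = W, U = U,
                 rss_per_sample = rss, lambda_per_sample = lam),
            class = "stage1_fit")
}

#' @export
print.stage1_fit <- function(x, ...) {
  cat(sprintf("stage1_fit: %d TF x %d samples, %d miRNA activities; pooled rss = %.4g\n",
              nrow(x$W), ncol(x$W), nrow(x$U), sum(x$rss_per_sample)))
  invisible(x)
}

#' Rescale miRNA activities by their cross-sample means
#'
#' Row `m` of `U` is multiplied by its own mean over samples:
#' `U~[m, s] = U[m, s] * mean_s(U[m, ])`. A consistently repressive miRNA
#' (negative activities) therefore gets positive rescaled values whose
#' magnitude tracks its overall activity; note the rescaling squares the sign
#' of a row, so negating a row leaves the output unchanged.
#'
#' @param U M x N activity matrix.
#' @return Matrix of the same shape.
#' @export
weight_mir_activities <- function(U) {
  U * rowMeans(U)
}

#' Infer regulator-gene interaction scores (stage 2)
#'
#' For each gene independently, regresses its expression across samples on
#' its copy-number and methylation rows (optional) plus the stage-1 activity
#' rows of its candidate regulators: TFs with a nonzero binding score and
#' miRNAs with a nonzero seed count for that gene. Genes with no candidates
#' get an intercept/CNV/DM-only fit and all-zero score rows.
#'
#' @param bundle An [omics_bundle()].
#' @param stage1 A `stage1_fit` for the same bundle.
#' @param lambda,cv_folds,seed As in [fit_stage1()].
#' @param use_cnv_dm Include CNV and methylation covariates (default TRUE).
#' @param mir_weighting `"average_scaled"` (default; use
#'   [weight_mir_activities()] on `U`) or `"raw"`.
#' @return A `stage2_fit` list with per-gene `gene_intercept`,
#'   `gene_cnv_coef`, `gene_dm_coef`, score matrices `Theta_TF` (G x T) and
#'   `Theta_miR` (G x M, zero outside the candidate masks), their
#'   standardised counterparts `Theta_TF_std` / `Theta_miR_std` (coefficient
#'   times the activity row's standard deviation, i.e. expression change per
#'   SD of regulator activity -- the scale on which scores of different
#'   regulators are comparable and rankings are computed), `rss_per_gene`,
#'   `lambda_per_gene`, and the settings used.
#' @export
fit_stage2 <- function(bundle, stage1, lambda = "cv", cv_folds = 10L,
                       use_cnv_dm = TRUE,
                       mir_weighting = c("average_scaled", "raw"),
                       seed = 1L) {
  mir_weighting <- match.arg(mir_weighting)
  G <- length(bundle$genes); N <- length(bundle$samples)
  T_ <- length(bundle$tfs); M <- length(bundle$mirnas)
  if (!identical(dim(stage1$W), c(T_, N)) || !identical(dim(stage1$U), c(M, N)))
    stopf("stage1 fit dimensions do not match the bundle")
  Uw <- if (mir_weighting == "average_scaled") weight_mir_activities(stage1$U)
        else stage1$U
  seeds <- sub_seeds(seed, G)
  Theta_TF <- matrix(0, G, T_, dimnames = list(bundle$genes, bundle$tfs))
  Theta_miR <- matrix(0, G, M, dimnames = list(bundle$genes, bundle$mirnas))
  a <- rho <- tau <- rss <- lam <- stats::setNames(numeric(G), bundle$genes)
  warned <- FALSE
  for (i in seq_len(G)) {
    g <- bundle$genes[i]
    tf_idx <- which(bundle$B[, g] > 0)
    mir_idx <- which(bundle$S[, g] > 0)
    if (!warned && N <= length(tf_idx) + length(mir_idx) + 2L * use_cnv_dm) {
      warnf("stage 2: some genes have at least as many candidate predictors as samples (LASSO still defined)")
      warned <- TRUE
    }
    des <- cbind(
      if (use_cnv_dm) cbind(CNV = bundle$C[g, ], DM = bundle$D[g, ]),
      t(stage1$W[tf_idx, , drop = FALSE]),
      t(Uw[mir_idx, , drop = FALSE]))
    fit <- lasso_fit(des, bundle$E[g, ], lambda = lambda,
                     cv_folds = cv_folds, seed = seeds[i])
    a[i] <- fit$intercept
    if (use_cnv_dm) {
      rho[i] <- fit$coefficients[["CNV"]]
      tau[i] <- fit$coefficients[["DM"]]
    }
    if (length(tf_idx))
      Theta_TF[i, tf_idx] <- fit$coefficients[bundle$tfs[tf_idx]]
    if (length(mir_idx))
      Theta_miR[i, mir_idx] <- fit$coefficients[bundle$mirnas[mir_idx]]
    rss[i] <- fit$rss
    lam[i] <- fit$lambda_selected
  }
  # coefficients are kept on the raw activity scale for prediction; for
  # cross-regulator ranking they are rescaled to expression-change-per-SD of
  # activity (a raw coefficient on a near-constant activity row can be huge
  # while contributing nothing)
  sd_n <- function(m) sqrt(rowMeans(sweep(m, 1L, rowMeans(m))^2))
  Theta_TF_std <- sweep(Theta_TF, 2L, sd_n(stage1$W), "*")
  Theta_miR_std <- sweep(Theta_miR, 2L, sd_n(Uw), "*")
  structure(list(gene_intercept = a, gene_cnv_coef = rho, gene_dm_coef = tau,
                 Theta_TF = Theta_TF, Theta_miR = Theta_miR,
                 Theta_TF_std = Theta_TF_std, Theta_miR_std = Theta_miR_std,
                 rss_per_gene = rss, lambda_per_gene = lam,
                 use_cnv_dm = use_cnv_dm, mir_weighting = mir_weighting),
            class = "stage2_fit")
}

#' @export
print.stage2_fit <- function(x, ...) {
  cat(sprintf("stage2_fit: %d genes; %d nonzero TF scores, %d nonzero miRNA scores\n",
              nrow(x$Theta_TF), sum(x$Theta_TF != 0), sum(x$Theta_miR != 0)))
  invisible(x)
}

#' Predict expression from a fitted stage
#'
#' Reconstructs the fitted G x N expression matrix from either stage's linear
#' model; the residual sums of squares of `E - Ehat` per sample (stage 1) or
#' per gene (stage 2) equal the stored `rss` values.
#'
#' @param fit A `stage1_fit` or `stage2_fit`.
#' @param bundle The matching [omics_bundle()].
#' @param stage1 For a `stage2_fit`, the `stage1_fit` whose activities feed
#'   the stage-2 model.
#' @return G x N matrix of predicted expression.
#' @export
predict_expression <- function(fit, bundle, stage1 = NULL) {
  G <- length(bundle$genes); N <- length(bundle$samples)
  if (inherits(fit, "stage1_fit")) {
    if (!identical(dim(fit$W), c(length(bundle$tfs), N)))
      stopf("fit dimensions do not match the bundle")
    tf_term <- t(bundle$B) %*% fit$W                    # G x N
    mir_term <- t(bundle$S) %*% (fit$U * bundle$X)     # G x N
    base <- sweep(bundle$C, 2L, fit$phi, "*") + sweep(bundle$D, 2L, fit$psi, "*")
    out <- sweep(base + tf_term + mir_term, 2L, fit$alpha, "+")
    dimnames(out) <- list(bundle$genes, bundle$samples)
    return(out)
  }
  if (inherits(fit, "stage2_fit")) {
    if (!identical(dim(fit$Theta_TF), c(G, length(bundle$tfs))))
      stopf("fit dimensions do not match the bundle")
    if (is.null(stage1))
      stopf("stage2_fit prediction needs the stage-1 activities (stage1 argument)")
    Uw <- if (fit$mir_weighting == "average_scaled")
      weight_mir_activities(stage1$U) else stage1$U
    out <- fit$Theta_TF %*% stage1$W + fit$Theta_miR %*% Uw
    out <- out + fit$gene_intercept +
      fit$gene_cnv_coef * bundle$C + fit$gene_dm_coef * bundle$D
    dimnames(out) <- list(bundle$genes, bundle$samples)
    return(out)
  }
  stopf("fit must be a stage1_fit or stage2_fit")
}
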