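# Cross-validation harness for comparing the full model against reduced and
# alternative variants (factor exclusions, motif-count TF source, unweighted
# seed counts, shuffled gene labels).

#' Describe a model variant
#'
#' @param name Label used in output tables.
#' @param exclude Character subset of `c("CNV", "DM", "TF", "miRNA")`; the
#'   named factor matrices are removed from the predictor set.
#' @param tf_source `"binding_scores"` (ChIP-seq signal, default) or
#'   `"motif_counts"` (requires a motif-count matrix at application time).
#' @param mir_weighting `"expression_weighted"` (seed counts times miRNA
#'   expression, default) or `"counts_only"` (seed counts alone).
#' @param shuffle_labels Randomly permute gene labels of the expression
#'   matrix (negative-control baseline); incompatible with exclusions.
#' @return A `model_variant` list.
#' @export
model_variant <- function(name, exclude = character(),
                          tf_source = c("binding_scores", "motif_counts"),
                          mir_weighting = c("expression_weighted", "counts_only"),
                          shuffle_labels = FALSE) {
  tf_source <- match.arg(tf_source)
  mir_weighting <- match.arg(mir_weighting)
  if (!all(exclude %in% c("CNV", "DM", "TF", "miRNA")))
    stopf("exclude must be a subset of CNV, DM, TF, miRNA")
  if (shuffle_labels && length(exclude))
    stopf("a shuffled-label variant must not exclude factors")
  structure(list(name = name, exclude = exclude, tf_source = tf_source,
                 mir_weighting = mir_weighting,
                 shuffle_labels = shuffle_labels),
            class = "model_variant")
}

#' Standard variant set for the model comparison table
#'
#' The full model, the four single-factor exclusions, and the shuffled-label
#' negative control.
#' @return Named list of [model_variant()] objects.
#' @export
standard_variants <- function() {
  list(full = model_variant("full"),
       no_cnv = model_variant("excl_CNV", exclude = "CNV"),
       no_mirna = model_variant("excl_miRNA", exclude = "miRNA"),
       no_dm = model_variant("excl_DM", exclude = "DM"),
       no_tf = model_variant("excl_TF", exclude = "TF"),
       shuffled = model_variant("shuffled", shuffle_labels = TRUE))
}

#' Apply a model variant to a bundle
#'
#' Excluded factor matrices are zeroed (a zero column is dropped by the
#' fitting contract, and zero seed counts empty the stage-2 candidate sets,
#' so zeroing removes the factor from both stages). `counts_only` sets the
#' miRNA expression matrix to 1 so the stage-1 miRNA predictor equals the
#' seed counts alone. `shuffle_labels` permutes the rows of `E` under the
#' given seed while keeping the gene labels in place.
#'
#' @param bundle An [omics_bundle()].
#' @param variant A [model_variant()].
#' @param seed Seed for the label permutation.
#' @param motif_counts Optional T x G motif-count matrix, required when
#'   `tf_source = "motif_counts"`.
#' @return A modified [omics_bundle()].
#' @export
apply_variant <- function(bundle, variant, seed = 1L, motif_counts = NULL) {
  b <- bundle
  if ("CNV" %in% variant$exclude) b$C[] <- 0
  if ("DM" %in% variant$exclude) b$D[] <- 0
  if ("TF" %in% variant$exclude) b$B[] <- 0
  if ("miRNA" %in% variant$exclude) b$S[] <- 0L
  if (variant$tf_source == "motif_counts") {
    if (is.null(motif_counts))
      stopf("variant '%s' needs a motif_counts matrix", variant$name)
    if (!identical(colnames(motif_counts), b$genes))
      stopf("motif_counts columns must match the bundle genes")
    b$B <- motif_counts
    b$tfs <- rownames(motif_counts)
  }
  if (variant$mir_weighting == "counts_only") b$X[] <- 1
  if (variant$shuffle_labels) {
    perm <- with_seed(seed, sample(length(b$genes)))
    E <- b$E[perm, , drop = FALSE]
    rownames(E) <- b$genes
    b$E <- E
  }
  b
}

# Shared CV engine: folds over rows of a design/response pair.
cv_unit <- function(design, y, folds, seed, lambda, cv_folds) {
  n <- length(y)
  fold_id <- make_folds(n, folds, seed)
  if (min(tabulate(fold_id, folds)) < 2L)
    stopf("cross-validation fold with fewer than 2 units")
  sp <- r2 <- numeric(folds)
  flagged <- FALSE
  inner_seeds <- sub_seeds(seed, folds)
  for (f in seq_len(folds)) {
    test <- fold_id == f
    fit <- lasso_fit(design[!test, , drop = FALSE], y[!test],
                     lambda = lambda, cv_folds = cv_folds,
                     seed = inner_seeds[f])
    pred <- as.numeric(fit$intercept +
                         design[test, , drop = FALSE] %*% fit$coefficients)
    sc <- spearman_or_zero(pred, y[test])
    flagged <- flagged || sc$flagged
    sp[f] <- sc$value
    ss_tot <- sum((y[test] - mean(y[test]))^2)
    r2[f] <- if (ss_tot == 0) { flagged <- TRUE; 0 }
             else 1 - sum((y[test] - pred)^2) / ss_tot
  }
  list(spearman = mean(sp), r2 = mean(r2), flagged = flagged)
}

#' Cross-validate the stage-1 model per sample
#'
#' For each sample, genes are partitioned into seeded folds; the model is fit
#' on the training genes and Spearman correlation and out-of-sample R-squared
#' (which may be negative) are computed on the held-out genes, then averaged
#' over folds. The penalty is re-selected inside every training fold, so no
#' information leaks from held-out genes.
#'
#' @param bundle An [omics_bundle()].
#' @param variant Optional [model_variant()] applied first.
#' @param folds Number of CV folds (default 10).
#' @param seed Integer seed (fold assignments and any label shuffle).
#' @param lambda Penalty passed to [lasso_fit()] (default `"cv"`).
#' @param cv_folds Inner folds for lambda selection.
#' @return A `cv_metrics` list: `unit = "sample"`, per-sample `spearman` and
#'   `r2` vectors, and `flagged` (units where a degenerate metric was
#'   recorded as 0).
#' @export
cv_stage1 <- function(bundle, variant = NULL, folds = 10L, seed = 1L,
                      lambda = "cv", cv_folds = 10L) {
  if (!is.null(variant)) bundle <- apply_variant(bundle, variant, seed = seed)
  N <- length(bundle$samples)
  seeds <- sub_seeds(seed + 1L, N)
  sp <- r2 <- stats::setNames(numeric(N), bundle$samples)
  flagged <- logical(N)
  for (i in seq_len(N)) {
    s <- bundle$samples[i]
    res <- cv_unit(stage1_design(bundle, s), bundle$E[, s],
                   folds, seeds[i], lambda, cv_folds)
    sp[i] <- res$spearman; r2[i] <- res$r2; flagged[i] <- res$flagged
  }
  structure(list(unit = "sample", spearman = sp, r2 = r2, flagged = flagged),
            class = "cv_metrics")
}

#' Cross-validate the stage-2 model per gene
#'
#' For each gene, samples are partitioned into seeded folds; metrics are
#' computed on held-out samples and averaged over folds.
#'
#' @param stage1 A `stage1_fit` matching the (variant-applied) bundle.
#' @inheritParams cv_stage1
#' @param use_cnv_dm,mir_weighting As in [fit_stage2()].
#' @return A `cv_metrics` list with `unit = "gene"` and length-G vectors.
#' @export
cv_stage2 <- function(bundle, stage1, variant = NULL, folds = 10L, seed = 1L,
                      lambda = "cv", cv_folds = 10L, use_cnv_dm = TRUE,
                      mir_weighting = c("average_scaled", "raw")) {
  mir_weighting <- match.arg(mir_weighting)
  if (!is.null(variant)) bundle <- apply_variant(bundle, variant, seed = seed)
  N <- length(bundle$samples); G <- length(bundle$genes)
  if (N < folds) stopf("need at least as many samples as folds")
  Uw <- if (mir_weighting == "average_scaled") weight_mir_activities(stage1$U)
        else stage1$U
  seeds <- sub_seeds(seed + 1L, G)
  sp <- r2 <- stats::setNames(numeric(G), bundle$genes)
  flagged <- logical(G)
  for (i in seq_len(G)) {
    g <- bundle$genes[i]
    tf_idx <- which(bundle$B[, g] > 0)
    mir_idx <- which(bundle$S[, g] > 0)
    des <- cbind(
      if (use_cnv_dm) cbind(CNV = bundle$C[g, ], DM = bundle$D[g, ]),
      t(stage1$W[tf_idx, , drop = FALSE]),
      t(Uw[mir_idx, , drop = FALSE]))
    if (is.null(des)) des <- matrix(numeric(0), N, 0L)
    res <- cv_unit(des, bundle$E[g, ], folds, seeds[i], lambda, cv_folds)
    sp[i] <- res$spearman; r2[i] <- res$r2; flagged[i] <- res$flagged
  }
  structure(list(unit = "gene", spearman = sp, r2 = r2, flagged = flagged),
            class = "cv_metrics")
}

#' Paired comparison of per-unit CV metrics
#'
#' Wilcoxon signed-rank test on paired metric vectors (exact for n <= 25
#' without ties, normal approximation with continuity correction otherwise).
#' All-zero differences give p = 1.
#'
#' @param a,b Equal-length paired metric vectors.
#' @param alternative `"two.sided"` (default), `"greater"` (a > b) or
#'   `"less"`.
#' @return List with `statistic` (signed-rank V) and `p_value`.
#' @export
compare_paired_metrics <- function(a, b,
                                   alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(a) != length(b)) stopf("paired vectors must have equal length")
  d <- (a - b)[a != b]
  if (length(d) == 0L) return(list(statistic = 0, p_value = 1))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (length(d) <= 25L) {
    p <- exact_signed_rank_p(r, v, alternative)
  } else {
    res <- suppressWarnings(stats::wilcox.test(d, alternative = alternative,
                                               exact = FALSE, correct = TRUE))
    p <- res$p.value
  }
  list(statistic = v, p_value = p)
}

# Exact null distribution of the signed-rank statistic by convolution over
# the (possibly tied, hence half-integer) ranks; doubling makes them integer.
exact_signed_rank_p <- function(ranks, v, alternative) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  w <- numeric(total + 1L)          # w[k+1] = #sign vectors with doubled V = k
  w[1L] <- 1
  for (ri in r2) {
    shifted <- c(numeric(ri), w[seq_len(total + 1L - ri)])
    w <- w + shifted
  }
  w <- w / sum(w)
  v2 <- as.integer(round(2 * v))
  p_le <- sum(w[seq_len(v2 + 1L)])
  p_ge <- sum(w[(v2 + 1L):(total + 1L)])
  switch(alternative,
         greater = p_ge,
         less = p_le,
         two.sided = min(1, 2 * min(p_le, p_ge)))
}

#' Run the model-comparison table
#'
#' Applies [cv_stage1()] to each variant and summarises median Spearman,
#' median R-squared and the paired one-sided signed-rank p-value of the full
#' model against each alternative.
#'
#' @param bundle An [omics_bundle()].
#' @param variants Named list of [model_variant()]s (default
#'   [standard_variants()]); must contain an element named `full`.
#' @inheritParams cv_stage1
#' @return List with `table` (a `data.frame`: variant, median_spearman,
#'   median_r2, p_vs_full) and `metrics` (per-variant `cv_metrics`).
#' @export
compare_models <- function(bundle, variants = standard_variants(), folds = 10L,
                           seed = 1L, lambda = "cv", cv_folds = 10L) {
  if (!"full" %in% names(variants))
    stopf("variants must include an element named 'full'")
  metrics <- lapply(variants, function(v)
    cv_stage1(bundle, v, folds = folds, seed = seed, lambda = lambda,
              cv_folds = cv_folds))
  full_sp <- metrics$full$spearman
  tab <- do.call(rbind, lapply(names(variants), function(nm) {
    m <- metrics[[nm]]
    p <- if (nm == "full") NA_real_
         else compare_paired_metrics(full_sp, m$spearman,
                                     alternative = "greater")$p_value
    data.frame(variant = variants[[nm]]$name,
               median_spearman = stats::median(m$spearman),
               median_r2 = stats::median(m$r2),
               p_vs_full = p, stringsAsFactors = FALSE)
  }))
  list(table = tab, metrics = metrics)
}
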