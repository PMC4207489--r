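# Power analysis of regulator-target predictions: ranked interaction lists,
# validated-overlap curves, precision-recall, and the comparison baselines
# (pairwise correlation, expression-only LASSO, raw peak score).

#' Rank regulator-gene interactions by score
#'
#' Only candidate pairs (mask TRUE) with a nonzero score enter the list.
#' miRNA interactions rank most-negative-first (repression semantics); TF
#' interactions rank by decreasing magnitude (activation and repression both
#' count). Ties break lexicographically by (regulator, gene) so rankings are
#' deterministic.
#'
#' @param Theta G x R score matrix (genes x regulators) with dimnames.
#' @param mask G x R logical candidate mask (e.g. `t(S) > 0`).
#' @param kind `"miRNA"` or `"TF"` (sets the default direction).
#' @param direction Override: `"most_negative_first"`,
#'   `"largest_magnitude_first"` or `"largest_first"`.
#' @return A `ranked_interactions` data.frame with columns `regulator`,
#'   `gene`, `score`, ordered; the direction is kept as an attribute.
#' @export
rank_interactions <- function(Theta, mask, kind = c("miRNA", "TF"),
                              direction = NULL) {
  kind <- match.arg(kind)
  if (is.null(direction))
    direction <- if (kind == "miRNA") "most_negative_first" else "largest_magnitude_first"
  direction <- match.arg(direction,
                         c("most_negative_first", "largest_magnitude_first",
                           "largest_first"))
  idx <- which(mask & Theta != 0, arr.ind = TRUE)
  df <- data.frame(regulator = colnames(Theta)[idx[, 2L]],
                   gene = rownames(Theta)[idx[, 1L]],
                   score = Theta[idx], stringsAsFactors = FALSE)
  key <- switch(direction,
                most_negative_first = df$score,
                largest_magnitude_first = -abs(df$score),
                largest_first = -df$score)
  df <- df[order(key, df$regulator, df$gene), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, direction = direction, class = c("ranked_interactions",
                                                 "data.frame"))
}

pair_keys <- function(reg, gene) paste(reg, gene, sep = "\r")

#' Count validated interactions among top-ranked predictions
#'
#' `counts[i]` is the number of validated pairs among the top `ks[i]` entries
#' of the ranking; non-decreasing in `k`. `ks` values beyond the list length
#' are capped (with a warning).
#'
#' @param ranked A `ranked_interactions` data.frame.
#' @param validated Two-column data.frame (`regulator`, `gene`) of validated
#'   pairs.
#' @param ks Increasing integer vector of list depths (default 1000 to 5000
#'   in steps of 200).
#' @return Named integer vector of counts (names are the requested `ks`).
#' @export
validated_overlap_curve <- function(ranked, validated,
                                    ks = seq(1000L, 5000L, by = 200L)) {
  if (is.unsorted(ks)) stopf("ks must be sorted ascending")
  n <- nrow(ranked)
  if (length(ks) && max(ks) > n) {
    warnf("ranking has only %d entries; deeper cutoffs capped", n)
  }
  vkeys <- pair_keys(validated$regulator, validated$gene)
  hit <- pair_keys(ranked$regulator, ranked$gene) %in% vkeys
  cum <- cumsum(hit)
  counts <- if (n == 0L) rep(0L, length(ks)) else cum[pmin(ks, n)]
  stats::setNames(as.integer(counts), ks)
}

#' Precision-recall curve and area
#'
#' Scores are thresholded at every rank where recall increases (i.e. at each
#' recovered positive); precision `TP/(TP+FP)` and recall `TP/P` are computed
#' there, and the area is the trapezoid over recall with the curve anchored
#' at recall 0 with the first precision value. Negatives default to all
#' scored items not in the positive set. Ties break lexicographically by
#' item name.
#'
#' @param scores Named numeric vector (names are item identifiers, e.g.
#'   genes or regulator-gene pair keys).
#' @param positives Character vector of positive item names (must be
#'   nonempty after intersection with the scored items... items never scored
#'   count as missed positives, depressing recall honestly).
#' @param negatives Optional character vector; defaults to scored items not
#'   in `positives`. Must be disjoint from `positives`.
#' @param direction Score ordering as in [rank_interactions()]
#'   (default `"largest_first"`).
#' @return A `pr_curve` list: `thresholds`, `precision`, `recall`, `auc`.
#' @export
precision_recall <- function(scores, positives, negatives = NULL,
                             direction = c("largest_first",
                                           "most_negative_first",
                                           "largest_magnitude_first")) {
  direction <- match.arg(direction)
  if (length(positives) == 0L) stopf("positive set must be nonempty")
  if (is.null(negatives)) negatives <- setdiff(names(scores), positives)
  if (length(intersect(positives, negatives)))
    stopf("positives and negatives must be disjoint")
  items <- names(scores)[names(scores) %in% c(positives, negatives)]
  s <- scores[items]
  P <- length(unique(positives))
  if (length(s) == 0L)
    return(structure(list(thresholds = numeric(0), precision = numeric(0),
                          recall = numeric(0), auc = 0), class = "pr_curve"))
  key <- switch(direction,
                largest_first = -s,
                most_negative_first = s,
                largest_magnitude_first = -abs(s))
  ord <- order(key, names(s))
  s <- s[ord]
  is_pos <- names(s) %in% positives
  tp <- cumsum(is_pos)
  fp <- cumsum(!is_pos)
  prec <- tp / (tp + fp)
  rec <- tp / P
  at <- which(is_pos)                     # ranks where recall increases
  if (length(at) == 0L)
    return(structure(list(thresholds = numeric(0), precision = numeric(0),
                          recall = numeric(0), auc = 0), class = "pr_curve"))
  pr <- prec[at]; rc <- rec[at]
  auc <- sum(diff(c(0, rc)) * (c(pr[1L], utils::head(pr, -1L)) + pr) / 2)
  structure(list(thresholds = unname(s[at]), precision = unname(pr),
                 recall = unname(rc), auc = auc), class = "pr_curve")
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("pr_curve: %d points, AUC = %.4f\n", length(x$recall), x$auc))
  invisible(x)
}

#' Pairwise-correlation baseline for miRNA target scoring
#'
#' Pearson correlation of every miRNA expression row with every gene
#' expression row across samples; strongly negative values suggest
#' repression. Constant rows get score 0 (flagged via attribute).
#'
#' @param X M x N miRNA expression matrix.
#' @param E G x N gene expression matrix.
#' @return M x G score matrix in \[-1, 1\].
#' @export
pcc_baseline <- function(X, E) {
  if (ncol(X) < 3L) stopf("need at least 3 samples for correlation scores")
  out <- suppressWarnings(stats::cor(t(X), t(E)))
  flagged <- which(is.na(out), arr.ind = TRUE)
  out[is.na(out)] <- 0
  attr(out, "flagged_constant") <- nrow(flagged)
  out
}

#' Expression-only LASSO baseline for miRNA target scoring
#'
#' For each gene, a LASSO of its expression on the expression of the miRNAs
#' with nonzero seed counts for that gene (no activities, no CNV/DM); the
#' coefficients are the scores. Genes without seed-matched miRNAs get zero
#' rows.
#'
#' @param bundle An [omics_bundle()].
#' @param lambda,cv_folds,seed As in [lasso_fit()].
#' @return M x G score matrix.
#' @export
expression_lasso_baseline <- function(bundle, lambda = "cv", cv_folds = 10L,
                                      seed = 1L) {
  M <- length(bundle$mirnas); G <- length(bundle$genes)
  out <- matrix(0, M, G, dimnames = list(bundle$mirnas, bundle$genes))
  seeds <- sub_seeds(seed, G)
  for (i in seq_len(G)) {
    g <- bundle$genes[i]
    mir_idx <- which(bundle$S[, g] > 0)
    if (length(mir_idx) == 0L) next
    fit <- lasso_fit(t(bundle$X[mir_idx, , drop = FALSE]), bundle$E[g, ],
                     lambda = lambda, cv_folds = cv_folds, seed = seeds[i])
    out[mir_idx, i] <- fit$coefficients
  }
  out
}

#' Peak-score baseline for TF target ranking
#'
#' TF-gene pairs ranked by raw binding score, descending; the no-model
#' comparison point for the stage-2 TF scores.
#'
#' @param B T x G nonnegative binding matrix.
#' @return A `ranked_interactions` data.frame.
#' @export
peak_score_baseline <- function(B) {
  if (any(B < 0)) stopf("binding matrix must be nonnegative")
  rank_interactions(t(B), t(B) > 0, kind = "TF", direction = "largest_first")
}

#' Intersect two evidence gene lists into a positive set
#'
#' Deduplicated intersection (e.g. pull-down hits with transfection
#' down-regulated genes); warns when empty.
#'
#' @param list_a,list_b Character vectors of gene identifiers.
#' @return Character vector.
#' @export
build_positive_set <- function(list_a, list_b) {
  out <- sort(unique(intersect(list_a, list_b)))
  if (length(out) == 0L) warnf("positive set is empty: the lists do not overlap")
  out
}
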