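# Downstream characterisation of selected regulators: activity clustering
# against risk groups, Rand index, mean-split log-rank survival tests,
# hypergeometric gene-set enrichment, and 3-layer network assignment.

#' Hierarchical clustering of samples by feature profiles
#'
#' Agglomerative average-linkage clustering on the pairwise distance
#' `1 - Pearson(sample_i, sample_j)` computed over features, with the
#' dendrogram cut into `k` groups. A constant sample column has no defined
#' correlation; it is flagged and placed at maximal distance (2) from every
#' other sample.
#'
#' @param features F x N matrix (features x samples).
#' @param k Number of clusters to cut (default 4).
#' @return A `cluster_assignment` list: `labels` (named integer vector,
#'   sample -> 1..k), `heights` (dendrogram merge heights), `hclust`, and
#'   `flagged` (constant samples).
#' @export
hierarchical_cluster <- function(features, k = 4L) {
  N <- ncol(features)
  if (k > N) stopf("cannot cut %d samples into %d clusters", N, k)
  cc <- suppressWarnings(stats::cor(features))
  flagged <- colnames(features)[apply(features, 2L, stats::sd) == 0]
  d <- 1 - cc
  d[is.na(d)] <- 2
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  labels <- stats::cutree(hc, k = k)
  structure(list(labels = labels, heights = hc$height, hclust = hc,
                 flagged = flagged), class = "cluster_assignment")
}

#' Rand index between two partitions
#'
#' Fraction of item pairs on which the partitions agree (both together or
#' both apart). The adjusted (chance-corrected) variant is reported
#' alongside.
#'
#' @param labels_a,labels_b Partitions of the same items: equal-length
#'   vectors, or named vectors over the same name set (matched by name).
#' @return List with `rand` in \[0, 1\] and `adjusted_rand`.
#' @export
rand_index <- function(labels_a, labels_b) {
  if (!is.null(names(labels_a)) && !is.null(names(labels_b))) {
    if (!setequal(names(labels_a), names(labels_b)))
      stopf("partitions cover different item sets")
    labels_b <- labels_b[names(labels_a)]
  }
  if (length(labels_a) != length(labels_b))
    stopf("partitions cover different item sets")
  n <- length(labels_a)
  tab <- table(labels_a, labels_b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  rand <- (total + 2 * sum_ij - sum_a - sum_b) / total
  expected <- sum_a * sum_b / total
  denom <- (sum_a + sum_b) / 2 - expected
  ari <- if (denom == 0) 1 else (sum_ij - expected) / denom
  list(rand = rand, adjusted_rand = ari)
}

#' Mean-split log-rank survival test for one feature
#'
#' Samples are split into "high" and "low" groups at the arithmetic mean of
#' the feature values and the two survival curves are compared with the
#' standard (hypergeometric-variance) log-rank statistic, chi-squared with
#' 1 df. A degenerate split (fewer than 2 samples in a group) yields a
#' flagged result with p = 1. BH correction across a feature panel is the
#' caller's job (see [survival_panel()]).
#'
#' @param values Named numeric vector, sample -> feature value.
#' @param clinical Clinical `data.frame` from [read_clinical()].
#' @return List with `statistic`, `p_value`, `groups` (named high/low
#'   factor) and `flagged`.
#' @export
logrank_split_test <- function(values, clinical) {
  common <- intersect(names(values), clinical$sample_id)
  if (length(common) < 4L) stopf("need at least 4 samples with clinical data")
  v <- values[common]
  cl <- clinical[match(common, clinical$sample_id), ]
  grp <- factor(ifelse(v > mean(v), "high", "low"), levels = c("low", "high"))
  if (min(table(grp)) < 2L)
    return(list(statistic = 0, p_value = 1, groups = grp, flagged = TRUE))
  sd <- survival::survdiff(survival::Surv(cl$time_to_event, cl$event) ~ grp)
  list(statistic = unname(sd$chisq),
       p_value = stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE),
       groups = stats::setNames(grp, common), flagged = FALSE)
}

#' Mean-split log-rank tests over a feature panel
#'
#' Runs [logrank_split_test()] for every row of a feature matrix and applies
#' BH correction across the panel.
#'
#' @param features F x N matrix (features x samples, column names are sample
#'   ids).
#' @param clinical Clinical `data.frame`.
#' @return `data.frame` with columns `feature`, `statistic`, `p_value`,
#'   `fdr`, `flagged`.
#' @export
survival_panel <- function(features, clinical) {
  res <- lapply(rownames(features), function(f)
    logrank_split_test(features[f, ], clinical))
  out <- data.frame(feature = rownames(features),
                    statistic = vapply(res, `[[`, numeric(1L), "statistic"),
                    p_value = vapply(res, `[[`, numeric(1L), "p_value"),
                    flagged = vapply(res, `[[`, logical(1L), "flagged"),
                    stringsAsFactors = FALSE)
  out$fdr <- bh_adjust(out$p_value)
  out[, c("feature", "statistic", "p_value", "fdr", "flagged")]
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test of the overlap between a target list and
#' each gene set, within a background universe. Sets are intersected with
#' the background first; sets smaller than `min_set` genes are dropped; BH
#' correction runs across the surviving sets.
#'
#' @param targets Character vector of genes (must lie inside `background`).
#' @param sets Named list of gene sets (e.g. from [read_gmt()]).
#' @param background Character vector: the gene universe.
#' @param min_set Minimum (background-intersected) set size (default 5).
#' @return `data.frame` with columns `set`, `hits`, `set_size`, `p_value`,
#'   `fdr`, sorted by p-value.
#' @export
hypergeometric_enrichment <- function(targets, sets, background, min_set = 5L) {
  if (length(background) == 0L) stopf("background gene universe is empty")
  targets <- unique(targets)
  if (!all(targets %in% background))
    stopf("targets must be a subset of the background universe")
  bg <- unique(background)
  sets <- lapply(sets, function(s) intersect(unique(s), bg))
  sets <- sets[lengths(sets) >= min_set]
  if (length(sets) == 0L)
    return(data.frame(set = character(), hits = integer(),
                      set_size = integer(), p_value = numeric(),
                      fdr = numeric(), stringsAsFactors = FALSE))
  hits <- vapply(sets, function(s) length(intersect(targets, s)), integer(1L))
  sizes <- lengths(sets)
  p <- stats::phyper(hits - 1L, sizes, length(bg) - sizes, length(targets),
                     lower.tail = FALSE)
  out <- data.frame(set = names(sets), hits = hits, set_size = sizes,
                    p_value = p, fdr = bh_adjust(p),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p_value, out$set), , drop = FALSE]
}

#' Assign regulators to layers of a 3-level regulatory hierarchy
#'
#' Based only on regulator-to-regulator edges: `top` regulators regulate at
#' least one other regulator and are regulated by none (master regulators);
#' `middle` both regulate and are regulated by regulators; `bottom` are
#' regulated by a regulator but themselves regulate only non-regulator
#' targets. Regulators with no regulator-regulator edges at all sit in the
#' top layer; members of a cycle both regulate and are regulated, hence land
#' in the middle layer.
#'
#' @param edges `data.frame` with columns `source`, `target` (and optionally
#'   `score`; zero-score edges are ignored).
#' @param regulators Character vector of regulator identifiers.
#' @return Named character vector, regulator -> `"top"|"middle"|"bottom"`.
#' @export
assign_network_layers <- function(edges, regulators) {
  if (!is.null(edges$score)) edges <- edges[edges$score != 0, , drop = FALSE]
  rr <- edges[edges$source %in% regulators & edges$target %in% regulators, ,
              drop = FALSE]
  out_reg <- regulators %in% rr$source
  in_reg <- regulators %in% rr$target
  layer <- ifelse(in_reg & out_reg, "middle",
                  ifelse(in_reg, "bottom", "top"))
  stats::setNames(layer, regulators)
}
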