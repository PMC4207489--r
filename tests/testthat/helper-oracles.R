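# Independent brute-force oracles. Each reimplements a quantity from its
# definition (loops, enumeration, closed forms) without touching the package
# code paths it checks.

# Closed-form LASSO solution on a design whose standardised columns are
# orthonormal under the 1/n inner product: soft-thresholded OLS.
oracle_soft_threshold <- function(X, y, lambda) {
  n <- nrow(X)
  ols <- drop(crossprod(X, y - mean(y))) / n
  sign(ols) * pmax(abs(ols) - lambda, 0)
}

# Design with exactly orthonormal (1/n scaling) mean-zero columns.
make_orthonormal_design <- function(n, p, seed) {
  set.seed(seed)
  X0 <- matrix(rnorm(n * p), n, p)
  X0 <- sweep(X0, 2, colMeans(X0))
  sqrt(n) * qr.Q(qr(X0))
}

# All-pairs interval overlap scan: mean signal per (tf, gene).
oracle_binding_matrix <- function(peaks, promoters) {
  tfs <- sort(unique(peaks$tf_name))
  genes <- sort(promoters$gene_id)
  B <- matrix(0, length(tfs), length(genes), dimnames = list(tfs, genes))
  for (t in tfs) for (g in genes) {
    pr <- promoters[promoters$gene_id == g, ]
    hits <- c()
    pk <- peaks[peaks$tf_name == t, ]
    for (i in seq_len(nrow(pk)))
      if (pk$chrom[i] == pr$chrom && pk$start[i] < pr$end && pr$start < pk$end[i])
        hits <- c(hits, pk$signal_value[i])
    if (length(hits)) B[t, g] <- mean(hits)
  }
  B
}

# All-pairs segment/exon overlap: mean segment score per (gene, sample).
oracle_cnv_matrix <- function(segments, genes) {
  gids <- sort(vapply(genes, `[[`, character(1), "gene_id"))
  samples <- sort(unique(segments$sample_id))
  C <- matrix(0, length(gids), length(samples), dimnames = list(gids, samples))
  for (g in gids) for (s in samples) {
    gm <- genes[[g]]
    seg <- segments[segments$sample_id == s & segments$chrom == gm$chrom, ]
    vals <- c()
    for (i in seq_len(nrow(seg))) {
      touches <- FALSE
      for (e in seq_len(nrow(gm$exons)))
        if (seg$start[i] < gm$exons[e, 2] && gm$exons[e, 1] < seg$end[i])
          touches <- TRUE
      if (touches) vals <- c(vals, seg$segment_mean[i])
    }
    if (length(vals)) C[g, s] <- mean(vals)
  }
  C
}

# Precision-recall by direct counting at every rank where a positive is
# recovered; trapezoid over recall anchored at (0, first precision).
oracle_pr <- function(scores, positives, negatives,
                      direction = "largest_first") {
  items <- names(scores)[names(scores) %in% c(positives, negatives)]
  s <- scores[items]
  key <- switch(direction,
                largest_first = -s,
                most_negative_first = s,
                largest_magnitude_first = -abs(s))
  s <- s[order(key, names(s))]
  P <- length(positives)
  tp <- 0; fp <- 0
  rec <- c(); prec <- c()
  for (i in seq_along(s)) {
    if (names(s)[i] %in% positives) {
      tp <- tp + 1
      rec <- c(rec, tp / P)
      prec <- c(prec, tp / i)
    } else fp <- fp + 1
  }
  if (length(rec) == 0) return(0)
  auc <- 0
  prev_r <- 0; prev_p <- prec[1]
  for (i in seq_along(rec)) {
    auc <- auc + (rec[i] - prev_r) * (prec[i] + prev_p) / 2
    prev_r <- rec[i]; prev_p <- prec[i]
  }
  auc
}

# Step-up BH from the definition: sorted p * m / i, cumulative minimum from
# the largest rank down, capped at 1, original order restored.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(1, adj)[order(o)]
}

# Rand index by direct pair enumeration.
oracle_rand <- function(a, b) {
  n <- length(a)
  agree <- 0; total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    total <- total + 1
    same_a <- a[i] == a[j]; same_b <- b[i] == b[j]
    if (same_a == same_b) agree <- agree + 1
  }
  agree / total
}

# Naive O(n^3) average-linkage agglomeration on a distance matrix; returns
# cluster labels after cutting at k clusters.
oracle_average_linkage <- function(d, k) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  while (length(clusters) > k) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      dd <- mean(d[clusters[[i]], clusters[[j]]])
      if (dd < best_d) { best_d <- dd; best <- c(i, j) }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
  }
  labels <- integer(n)
  for (i in seq_along(clusters)) labels[clusters[[i]]] <- i
  labels
}

# Exact signed-rank p by enumeration over all sign vectors (n <= 12).
oracle_signed_rank <- function(d, alternative = "greater") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  vs <- numeric(2^n)
  for (mask in 0:(2^n - 1)) {
    signs <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    vs[mask + 1] <- sum(r[signs])
  }
  p_ge <- mean(vs >= v_obs)
  p_le <- mean(vs <= v_obs)
  switch(alternative,
         greater = p_ge, less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

# Two-group log-rank statistic from the event-by-event 2x2 tables
# (hypergeometric mean/variance), as computed by hand.
oracle_logrank <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2)
  g1 <- unique(group)[1]
  obs_minus_exp <- 0; var_sum <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    e1 <- d * n1 / n
    obs_minus_exp <- obs_minus_exp + (d1 - e1)
    if (n > 1)
      var_sum <- var_sum + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  obs_minus_exp^2 / var_sum
}

# Upper-tail hypergeometric p by direct summation.
oracle_hyper <- function(hits, set_size, bg_size, n_draw) {
  ks <- hits:min(set_size, n_draw)
  sum(choose(set_size, ks) * choose(bg_size - set_size, n_draw - ks)) /
    choose(bg_size, n_draw)
}

# Small deterministic hand-built bundle for unit tests.
make_tiny_bundle <- function(G = 30, M = 3, T_ = 2, N = 8, seed = 99) {
  set.seed(seed)
  genes <- sprintf("g%02d", 1:G); mirnas <- paste0("m", 1:M)
  tfs <- paste0("t", 1:T_); samples <- paste0("s", 1:N)
  B <- matrix(rbinom(T_ * G, 1, 0.4) * runif(T_ * G, 0.5, 2), T_, G,
              dimnames = list(tfs, genes))
  S <- matrix(rbinom(M * G, 1, 0.4) * rpois(M * G, 1), M, G,
              dimnames = list(mirnas, genes))
  storage.mode(S) <- "integer"
  X <- matrix(runif(M * N, 2, 6), M, N, dimnames = list(mirnas, samples))
  C <- matrix(rnorm(G * N), G, N, dimnames = list(genes, samples))
  D <- matrix(rbeta(G * N, 2, 2), G, N, dimnames = list(genes, samples))
  W <- matrix(rnorm(T_ * N), T_, N, dimnames = list(tfs, samples))
  U <- matrix(rnorm(M * N, -1), M, N, dimnames = list(mirnas, samples))
  E <- t(B) %*% W + t(S) %*% (U * X) + 0.8 * C - 0.5 * D +
    matrix(rnorm(G * N, 0, 0.05), G, N)
  dimnames(E) <- list(genes, samples)
  list(bundle = omics_bundle(E = E, X = X, C = C, D = D, B = B, S = S),
       W = W, U = U)
}
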