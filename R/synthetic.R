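# Synthetic study generator with planted ground truth. The generative model
# is the stage-1 linear model read forwards: for sample s,
#   E[g, s] = alpha_s + phi_s C[g, s] + psi_s D[g, s]
#             + sum_t B[t, g] W*[t, s] + sum_m S[m, g] X[m, s] U*[m, s]
#             + Gaussian noise,
# optionally per-gene mean-centred afterwards (the default, matching how
# expression matrices are preprocessed). Activities of active regulators
# carry risk-group-specific mean shifts; inactive regulators contribute
# nothing. Survival times are exponential with a rate tied (optionally) to
# one regulator's activity, with independent exponential censoring
# calibrated to ~25%.

#' Configuration for a synthetic study
#'
#' @param G,M,T_,N Numbers of genes, miRNAs, TFs and samples
#'   (defaults 500, 15, 10, 40).
#' @param edge_density Support density of the binding (`B`) and seed-count
#'   (`S`) matrices, in (0, 1\] (default 0.05).
#' @param noise_sd Standard deviation of the additive expression noise
#'   (default 0.1).
#' @param confounder_sd Scale of an optional rank-1 structured confounder
#'   (gene loading times sample loading, e.g. a batch or cell-composition
#'   effect) added to expression. Default 0: the expression model is then
#'   exactly the additive regression model. A positive value creates
#'   between-sample expression correlation unrelated to the risk groups,
#'   which inflates expression-based clustering but is orthogonal to the
#'   binding columns and hence largely filtered out of activity estimates.
#' @param n_active_regulators How many of the T + M regulators carry nonzero
#'   activities. Default `ceiling(0.6 * (T_ + M))`, split proportionally
#'   between kinds: keeping a margin of inactive regulators means their
#'   support pairs provide genuine non-edges for recovery benchmarks.
#' @param risk_groups Number of patient risk groups (default 3).
#' @param activity_group_shift Scale of the group-specific activity mean
#'   shifts (default 1; 0 removes group structure).
#' @param survival_link_feature Optional regulator id whose activity drives
#'   the survival hazard.
#' @param center Per-gene mean-centre the expression matrix (default TRUE).
#' @param seed Integer master seed; every random draw derives from it.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(G = 500L, M = 15L, T_ = 10L, N = 40L,
                             edge_density = 0.05, noise_sd = 0.1,
                             confounder_sd = 0,
                             n_active_regulators = NULL, risk_groups = 3L,
                             activity_group_shift = 1,
                             survival_link_feature = NULL,
                             center = TRUE, seed = 1L) {
  if (is.null(n_active_regulators))
    n_active_regulators <- ceiling(0.6 * (T_ + M))
  if (n_active_regulators > T_ + M)
    stopf("n_active_regulators must be <= T + M")
  if (edge_density <= 0 || edge_density > 1)
    stopf("edge_density must lie in (0, 1]")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (confounder_sd < 0) stopf("confounder_sd must be >= 0")
  if (risk_groups < 1L) stopf("risk_groups must be >= 1")
  structure(list(G = as.integer(G), M = as.integer(M), T_ = as.integer(T_),
                 N = as.integer(N), edge_density = edge_density,
                 noise_sd = noise_sd, confounder_sd = confounder_sd,
                 n_active_regulators = as.integer(n_active_regulators),
                 risk_groups = as.integer(risk_groups),
                 activity_group_shift = activity_group_shift,
                 survival_link_feature = survival_link_feature,
                 center = isTRUE(center), seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic omics bundle with planted truth
#'
#' @param config A [synthetic_config()].
#' @return List with `bundle` (an [omics_bundle()]) and `truth`: planted
#'   `W_true`, `U_true`, `alpha_true`, `phi_true`, `psi_true`, `edges_true`
#'   (data.frame regulator/gene/kind over the active regulators' support),
#'   `active_set`, `risk_labels` (named), and `clinical`.
#' @export
generate_bundle <- function(config) {
  cf <- config
  with_seed(cf$seed, {
    genes <- sprintf("g%04d", seq_len(cf$G))
    mirnas <- sprintf("miR-%02d", seq_len(cf$M))
    tfs <- sprintf("TF%02d", seq_len(cf$T_))
    samples <- sprintf("S%03d", seq_len(cf$N))

    # regulator priors: ChIP signal is right-skewed, seed counts small ints
    B <- matrix(stats::rbinom(cf$T_ * cf$G, 1L, cf$edge_density) *
                  stats::rlnorm(cf$T_ * cf$G, 0, 1),
                cf$T_, cf$G, dimnames = list(tfs, genes))
    S <- matrix(stats::rbinom(cf$M * cf$G, 1L, cf$edge_density) *
                  (1L + stats::rpois(cf$M * cf$G, 0.3)),
                cf$M, cf$G, dimnames = list(mirnas, genes))
    storage.mode(S) <- "integer"

    # miRNA expression has miRNA-specific positive means (log-RPM-like,
    # detected miRNAs sit well above zero); a zero-mean predictor would make
    # the seed-by-expression interaction orthogonal to the activity itself
    # and stage-2 edges unidentifiable, and near-zero expression makes the
    # per-sample activity coefficient (effect divided by expression)
    # arbitrarily ill-conditioned.
    mu_x <- stats::runif(cf$M, 2, 6)
    X <- matrix(mu_x + stats::rnorm(cf$M * cf$N), cf$M, cf$N,
                dimnames = list(mirnas, samples))
    C <- matrix(stats::rnorm(cf$G * cf$N), cf$G, cf$N,
                dimnames = list(genes, samples))
    D <- matrix(stats::rbeta(cf$G * cf$N, 2, 2), cf$G, cf$N,
                dimnames = list(genes, samples))

    # active regulators, split proportionally between kinds
    n_act_tf <- min(cf$T_, round(cf$n_active_regulators * cf$T_ / (cf$T_ + cf$M)))
    n_act_mir <- min(cf$M, cf$n_active_regulators - n_act_tf)
    active_tfs <- sort(sample(tfs, n_act_tf))
    active_mirs <- sort(sample(mirnas, n_act_mir))
    active_set <- c(active_tfs, active_mirs)

    groups <- sample(rep_len(seq_len(cf$risk_groups), cf$N))
    group_names <- c("favourable", "intermediate", "poor",
                     paste0("group", seq_len(max(0L, cf$risk_groups - 3L)) + 3L))
    risk_labels <- stats::setNames(group_names[groups], samples)

    draw_activities <- function(ids, all_ids, base_mean, center_rows) {
      A <- matrix(0, length(all_ids), cf$N, dimnames = list(all_ids, samples))
      for (r in ids) {
        gmeans <- base_mean + cf$activity_group_shift *
          stats::rnorm(cf$risk_groups)
        A[r, ] <- gmeans[groups] + stats::rnorm(cf$N)
        # TF activities are latent and only identified relative to the cohort
        # mean once expression is per-gene centred; plant them centred (the
        # usual zero-sum convention for motif/TF activity models). miRNA
        # activities keep their repressive (negative-mean) scale, which the
        # stage-2 average-activity weighting exploits.
        if (center_rows) A[r, ] <- A[r, ] - mean(A[r, ])
      }
      A
    }
    W_true <- draw_activities(active_tfs, tfs, base_mean = 0,
                              center_rows = cf$center)
    U_true <- draw_activities(active_mirs, mirnas, base_mean = -1,
                              center_rows = FALSE)

    alpha_true <- stats::rnorm(cf$N, 0, 0.5)
    phi_true <- stats::rnorm(cf$N, 1, 0.2)     # gains raise expression
    psi_true <- stats::rnorm(cf$N, -1, 0.2)    # methylation represses

    E <- sweep(C, 2L, phi_true, "*") + sweep(D, 2L, psi_true, "*") +
      t(B) %*% W_true + t(S) %*% (U_true * X)
    E <- sweep(E, 2L, alpha_true, "+") +
      matrix(stats::rnorm(cf$G * cf$N, 0, cf$noise_sd), cf$G, cf$N)
    if (cf$confounder_sd > 0)
      E <- E + cf$confounder_sd *
        outer(stats::rnorm(cf$G), stats::rnorm(cf$N))
    if (cf$center) E <- E - rowMeans(E)
    dimnames(E) <- list(genes, samples)

    edge_rows <- function(mat, ids, kind) {
      idx <- which(mat[ids, , drop = FALSE] > 0, arr.ind = TRUE)
      if (nrow(idx) == 0L)
        return(data.frame(regulator = character(), gene = character(),
                          kind = character(), stringsAsFactors = FALSE))
      data.frame(regulator = ids[idx[, 1L]], gene = colnames(mat)[idx[, 2L]],
                 kind = kind, stringsAsFactors = FALSE)
    }
    edges_true <- rbind(edge_rows(B, active_tfs, "TF"),
                        edge_rows(S, active_mirs, "miRNA"))
    edges_true <- edges_true[order(edges_true$regulator, edges_true$gene), ]
    rownames(edges_true) <- NULL

    # survival: exponential event times; hazard optionally tied to one
    # regulator's activity; independent exponential censoring at rate/3
    # gives P(censored) = 0.25 exactly.
    base_rate <- 1 / 500
    link <- cf$survival_link_feature
    rate <- if (!is.null(link)) {
      act <- if (link %in% tfs) W_true[link, ] else U_true[link, ]
      if (stats::sd(act) > 0) act <- (act - mean(act)) / stats::sd(act)
      base_rate * exp(0.8 * act)
    } else rep(base_rate, cf$N)
    t_event <- stats::rexp(cf$N, rate)
    t_cens <- stats::rexp(cf$N, rate / 3)
    clinical <- data.frame(sample_id = samples,
                           risk_group = unname(risk_labels),
                           time_to_event = pmin(t_event, t_cens),
                           event = as.integer(t_event <= t_cens),
                           stringsAsFactors = FALSE)

    list(bundle = omics_bundle(E = E, X = X, C = C, D = D, B = B, S = S),
         truth = list(W_true = W_true, U_true = U_true,
                      alpha_true = alpha_true, phi_true = phi_true,
                      psi_true = psi_true, edges_true = edges_true,
                      active_set = active_set, risk_labels = risk_labels,
                      clinical = clinical, config = cf))
  })
}

#' Sample a noisy validated-interaction set from the planted truth
#'
#' Emulates a curated interaction database: a fraction of the true edges,
#' plus contaminating non-edges at the stated rate.
#'
#' @param truth The `truth` component of [generate_bundle()]'s result.
#' @param fraction Fraction of true edges retained, in \[0, 1\].
#' @param fdr_contamination Expected contaminant fraction, in \[0, 1\]:
#'   `Binomial(n_kept, fdr_contamination)` non-edges are added.
#' @param seed Integer seed.
#' @return `data.frame` with columns `regulator`, `gene`.
#' @export
generate_validated_set <- function(truth, fraction = 1, fdr_contamination = 0,
                                   seed = 1L) {
  if (fraction < 0 || fraction > 1 || fdr_contamination < 0 || fdr_contamination > 1)
    stopf("fraction and fdr_contamination must lie in [0, 1]")
  edges <- truth$edges_true
  with_seed(seed, {
    n_keep <- round(fraction * nrow(edges))
    kept <- edges[sort(sample.int(nrow(edges), n_keep)), c("regulator", "gene")]
    n_cont <- if (n_keep > 0L) stats::rbinom(1L, n_keep, fdr_contamination) else 0L
    if (n_cont > 0L) {
      regs <- c(rownames(truth$W_true), rownames(truth$U_true))
      genes <- unique(edges$gene)
      all_keys <- pair_keys(edges$regulator, edges$gene)
      picked <- 0L
      rows <- list()
      while (picked < n_cont) {
        r <- sample(regs, 1L); g <- sample(genes, 1L)
        if (!pair_keys(r, g) %in% all_keys) {
          picked <- picked + 1L
          rows[[picked]] <- data.frame(regulator = r, gene = g,
                                       stringsAsFactors = FALSE)
          all_keys <- c(all_keys, pair_keys(r, g))
        }
      }
      kept <- rbind(kept, do.call(rbind, rows))
    }
    rownames(kept) <- NULL
    kept
  })
}
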