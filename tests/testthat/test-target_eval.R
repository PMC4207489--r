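test_that("interaction ranking follows direction and deterministic tie-breaks", {
  Theta <- matrix(0, 2, 2, dimnames = list(c("g1", "g2"), c("m1", "m2")))
  Theta["g1", "m1"] <- -2; Theta["g2", "m2"] <- -1; Theta["g2", "m1"] <- 3
  mask <- matrix(TRUE, 2, 2, dimnames = dimnames(Theta))
  r <- rank_interactions(Theta, mask, kind = "miRNA")
  expect_equal(paste(r$regulator, r$gene),
               c("m1 g1", "m2 g2", "m1 g2"))   # positive score ranks last
  # zero scores and unmasked candidates never appear
  expect_equal(nrow(rank_interactions(Theta * 0, mask, "miRNA")), 0L)
  mask2 <- mask; mask2["g1", "m1"] <- FALSE
  expect_equal(nrow(rank_interactions(Theta, mask2, "miRNA")), 2L)
  # TF ranking by magnitude; exact ties break lexicographically, stably
  Th2 <- matrix(c(2, -2, 2, 1), 2, 2,
                dimnames = list(c("g1", "g2"), c("tA", "tB")))
  r2 <- rank_interactions(Th2, Th2 != 0, kind = "TF")
  expect_equal(paste(r2$regulator, r2$gene),
               c("tA g1", "tA g2", "tB g1", "tB g2"))
  expect_identical(r2, rank_interactions(Th2, Th2 != 0, kind = "TF"))
})

test_that("validated-overlap curve counts by enumeration and is monotone", {
  ranked <- data.frame(regulator = "m", gene = c("a", "c", "b", "d"),
                       stringsAsFactors = FALSE)
  validated <- data.frame(regulator = "m", gene = c("a", "b"))
  expect_equal(unname(validated_overlap_curve(ranked, validated, ks = c(2, 4))),
               c(1L, 2L))
  expect_equal(unname(validated_overlap_curve(
    ranked, data.frame(regulator = character(), gene = character()),
    ks = c(2, 4))), c(0L, 0L))
  # validated superset of the list: counts equal the depths
  expect_equal(unname(validated_overlap_curve(
    ranked, data.frame(regulator = "m", gene = c("a", "b", "c", "d")),
    ks = c(1, 3))), c(1L, 3L))
  expect_warning(validated_overlap_curve(ranked, validated, ks = c(2, 10)),
                 "capped")
  # monotone on random inputs
  set.seed(9)
  for (i in 1:10) {
    rr <- data.frame(regulator = "m", gene = sample(letters, 20))
    vv <- data.frame(regulator = "m", gene = sample(letters, 7))
    counts <- validated_overlap_curve(rr, vv, ks = c(3, 8, 15, 20))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("precision-recall matches the enumeration oracle on small instances", {
  # perfect separation
  s <- c(a = 5, b = 4, c = 1, d = 0.5)
  pr <- precision_recall(s, positives = c("a", "b"))
  expect_equal(pr$auc, 1)
  expect_true(all(pr$precision == 1))
  # worked 4-item case: order a > c > b > d, points (0.5, 1), (1, 2/3)
  s2 <- c(a = 4, c = 3, b = 2, d = 1)
  pr2 <- precision_recall(s2, positives = c("a", "b"))
  expect_equal(pr2$recall, c(0.5, 1))
  expect_equal(pr2$precision, c(1, 2 / 3))
  expect_equal(pr2$auc, 0.5 + 0.5 * (1 + 2 / 3) / 2)
  expect_equal(pr2$auc, oracle_pr(s2, c("a", "b"), c("c", "d")))
  # random instances of <= 8 items, every direction
  set.seed(23)
  for (i in 1:60) {
    n <- sample(3:8, 1)
    sc <- stats::setNames(round(rnorm(n), 1), letters[1:n])  # ties likely
    pos <- sample(letters[1:n], sample(1:(n - 1), 1))
    neg <- setdiff(letters[1:n], pos)
    for (d in c("largest_first", "most_negative_first",
                "largest_magnitude_first")) {
      expect_equal(precision_recall(sc, pos, neg, direction = d)$auc,
                   oracle_pr(sc, pos, neg, d),
                   label = sprintf("instance %d dir %s", i, d))
    }
  }
  # recall never decreases along the curve
  expect_true(all(diff(pr2$recall) >= 0))
  expect_error(precision_recall(s, character(0)), "nonempty")
  expect_error(precision_recall(s, "a", c("a", "b")), "disjoint")
})

test_that("random scores give PR-AUC near the positive base rate", {
  set.seed(77)
  aucs <- replicate(50, {
    sc <- stats::setNames(runif(100), paste0("i", 1:100))
    precision_recall(sc, positives = paste0("i", 1:20))$auc
  })
  expect_lt(abs(mean(aucs) - 0.2), 0.05)
})

test_that("correlation baseline is symmetric, bounded, and flags constants", {
  set.seed(12)
  X <- matrix(rnorm(30), 3, 10, dimnames = list(paste0("m", 1:3), NULL))
  E <- matrix(rnorm(50), 5, 10, dimnames = list(paste0("g", 1:5), NULL))
  E["g1", ] <- -X["m1", ]
  P <- pcc_baseline(X, E)
  expect_equal(dim(P), c(3L, 5L))
  expect_equal(unname(P["m1", "g1"]), -1)
  expect_true(all(abs(P) <= 1 + 1e-12))
  expect_equal(unname(P["m2", "g3"]), unname(pcc_baseline(E, X)["g3", "m2"]))
  E["g2", ] <- 7
  P2 <- pcc_baseline(X, E)
  expect_equal(unname(P2[, "g2"]), c(0, 0, 0))
  expect_gt(attr(P2, "flagged_constant"), 0)
})

test_that("expression-only LASSO baseline recovers a planted repressive edge", {
  tiny <- make_tiny_bundle()
  b <- tiny$bundle
  g <- b$genes[1]
  b$S[, g] <- 0L
  b$S["m2", g] <- 2L
  b$E[g, ] <- -1.5 * b$X["m2", ] + rnorm(8, 0, 0.01)
  sc <- expression_lasso_baseline(b, lambda = 0.01, seed = 4)
  expect_lt(sc["m2", g], -1)
  # genes without seed-matched miRNAs score zero
  g0 <- b$genes[3]
  b$S[, g0] <- 0L
  sc0 <- expression_lasso_baseline(b, lambda = 0.01, seed = 4)
  expect_equal(unname(sc0[, g0]), rep(0, 3))
  expect_identical(sc0, expression_lasso_baseline(b, lambda = 0.01, seed = 4))
})

test_that("peak-score baseline is the definitional descending ranking", {
  B <- matrix(c(0, 3, 0, 0, 1, 2), 2, 3,
              dimnames = list(c("t1", "t2"), c("g1", "g2", "g3")))
  r <- peak_score_baseline(B)
  expect_equal(r$score, c(3, 2, 1))
  expect_identical(as.data.frame(r),
                   as.data.frame(rank_interactions(t(B), t(B) > 0, "TF",
                                                   direction = "largest_first")))
  # scale invariance of the ordering
  r2 <- peak_score_baseline(10 * B)
  expect_equal(paste(r2$regulator, r2$gene), paste(r$regulator, r$gene))
  B1 <- matrix(c(0, 5), 1, 2, dimnames = list("t", c("g1", "g2")))
  expect_equal(nrow(peak_score_baseline(B1)), 1L)
})

test_that("positive-set construction is a deduplicated intersection", {
  expect_equal(build_positive_set(c("a", "b", "c"), c("b", "c", "d")),
               c("b", "c"))
  expect_warning(out <- build_positive_set(c("a"), c("b")), "empty")
  expect_length(out, 0)
  expect_equal(build_positive_set(c("a", "b", "b"), c("a", "b", "b")),
               c("a", "b"))
})
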