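test_that("correlation-distance clustering recovers duplicate groups", {
  set.seed(3)
  base1 <- rnorm(20); base2 <- rnorm(20)
  f <- cbind(a1 = base1 + rnorm(20, 0, 1e-6), a2 = base1 + rnorm(20, 0, 1e-6),
             b1 = base2 + rnorm(20, 0, 1e-6), b2 = base2 + rnorm(20, 0, 1e-6))
  cl <- hierarchical_cluster(f, k = 2)
  expect_equal(cl$labels[["a1"]], cl$labels[["a2"]])
  expect_equal(cl$labels[["b1"]], cl$labels[["b2"]])
  expect_false(cl$labels[["a1"]] == cl$labels[["b1"]])
  # k = N gives singletons
  expect_equal(sort(unname(hierarchical_cluster(f, k = 4)$labels)), 1:4)
  expect_error(hierarchical_cluster(f, k = 5), "cannot cut")
})

test_that("average-linkage clustering agrees with the naive agglomeration oracle", {
  set.seed(8)
  for (i in 1:10) {
    n <- sample(5:8, 1)
    f <- matrix(rnorm(12 * n), 12, n,
                dimnames = list(NULL, paste0("s", 1:n)))
    k <- sample(2:(n - 1), 1)
    d <- 1 - stats::cor(f)
    ours <- hierarchical_cluster(f, k = k)$labels
    oracle <- oracle_average_linkage(d, k)
    # same partition up to label renaming
    expect_equal(oracle_rand(ours, oracle), 1,
                 label = sprintf("instance %d (n=%d, k=%d)", i, n, k))
  }
})

test_that("Rand index matches pair enumeration and is label-invariant", {
  expect_equal(rand_index(c(1, 1, 2), c(1, 2, 2))$rand, 1 / 3)
  expect_equal(rand_index(1:5, 1:5)$rand, 1)
  expect_equal(rand_index(c(1, 1, 2, 2), c(7, 7, 3, 3))$rand, 1)  # renamed
  expect_equal(rand_index(c(1, 1, 2, 2), c(7, 7, 3, 3))$adjusted_rand, 1)
  set.seed(15)
  for (i in 1:20) {
    n <- sample(4:6, 1)
    a <- sample(1:3, n, replace = TRUE)
    b <- sample(1:3, n, replace = TRUE)
    expect_equal(rand_index(a, b)$rand, oracle_rand(a, b))
  }
  # named vectors are matched by name
  a <- c(s1 = 1, s2 = 1, s3 = 2)
  b <- c(s3 = 2, s1 = 1, s2 = 1)
  expect_equal(rand_index(a, b)$rand, 1)
  expect_error(rand_index(a, c(sX = 1, s2 = 1, s3 = 2)), "different item")
})

test_that("log-rank mean-split test matches the hand 2x2-per-event oracle", {
  clinical <- data.frame(
    sample_id = paste0("s", 1:6),
    risk_group = "x",
    time_to_event = c(5, 8, 12, 20, 25, 30),
    event = c(1, 1, 0, 1, 1, 1), stringsAsFactors = FALSE)
  values <- stats::setNames(c(10, 9, 8, 1, 2, 3), clinical$sample_id)
  res <- logrank_split_test(values, clinical)
  grp <- ifelse(values > mean(values), "high", "low")
  expect_equal(res$statistic,
               oracle_logrank(clinical$time_to_event, clinical$event, grp),
               tolerance = 1e-10)
  expect_equal(res$p_value,
               stats::pchisq(res$statistic, 1, lower.tail = FALSE))
  # identical survival by construction: duplicated samples, split across groups
  cl2 <- data.frame(sample_id = paste0("s", 1:8), risk_group = "x",
                    time_to_event = rep(c(3, 9, 15, 21), 2),
                    event = rep(c(1, 1, 1, 0), 2), stringsAsFactors = FALSE)
  v2 <- stats::setNames(rep(c(10, 0), each = 4), cl2$sample_id)
  res2 <- logrank_split_test(v2, cl2)
  expect_equal(res2$statistic, 0, tolerance = 1e-10)
  # degenerate split is flagged with p = 1
  v3 <- stats::setNames(c(100, 1, 1, 1, 1, 1), clinical$sample_id)
  res3 <- logrank_split_test(v3, clinical)
  expect_true(res3$flagged)
  expect_equal(res3$p_value, 1)
})

test_that("log-rank p-values are roughly uniform under the null", {
  set.seed(19)
  ps <- replicate(200, {
    cl <- data.frame(sample_id = paste0("s", 1:40), risk_group = "x",
                     time_to_event = rexp(40, 0.01),
                     event = rbinom(40, 1, 0.8), stringsAsFactors = FALSE)
    logrank_split_test(stats::setNames(rnorm(40), cl$sample_id), cl)$p_value
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("activity clustering tracks risk groups better than expression under structured confounding", {
  # a strong rank-1 confounder (batch-like) dominates the expression
  # covariance but is orthogonal to the binding columns, so inferred
  # activities keep the risk-group structure that raw expression loses
  cf <- synthetic_config(G = 200, T_ = 8, M = 8, N = 60, edge_density = 0.15,
                         noise_sd = 0.5, confounder_sd = 10, risk_groups = 3,
                         activity_group_shift = 2, seed = 77)
  sim <- generate_bundle(cf)
  s1 <- fit_stage1(sim$bundle, lambda = "cv", seed = 5)
  act <- rbind(s1$W, s1$U)[sim$truth$active_set, , drop = FALSE]
  ra <- rand_index(hierarchical_cluster(act, k = 3)$labels,
                   sim$truth$risk_labels)$rand
  re <- rand_index(hierarchical_cluster(sim$bundle$E, k = 3)$labels,
                   sim$truth$risk_labels)$rand
  expect_gt(ra, re)
  expect_gt(ra, 0.9)
})

test_that("hypergeometric enrichment matches combinatorial identities", {
  background <- paste0("g", 1:100)
  sets <- list(SET10 = paste0("g", 1:10), TINY = paste0("g", 1:4),
               OTHER = paste0("g", 50:70))
  targets <- paste0("g", 1:5)
  res <- hypergeometric_enrichment(targets, sets, background, min_set = 5)
  expect_false("TINY" %in% res$set)         # below min_set
  p_exp <- choose(10, 5) / choose(100, 5)   # all five targets inside SET10
  expect_equal(res$p_value[res$set == "SET10"], p_exp, tolerance = 1e-12)
  expect_equal(res$p_value[res$set == "SET10"],
               oracle_hyper(5, 10, 100, 5), tolerance = 1e-12)
  expect_equal(res$p_value[res$set == "OTHER"], 1)  # disjoint -> upper tail 1
  expect_error(hypergeometric_enrichment(c("zz"), sets, background), "subset")
  expect_error(hypergeometric_enrichment(targets, sets, character(0)), "empty")
})

test_that("network layer assignment follows the regulator-edge definitions", {
  regs <- c("A", "B", "C")
  edges <- data.frame(source = c("A", "B", "C"),
                      target = c("B", "C", "gene7"),
                      score = c(1, -2, 0.5), stringsAsFactors = FALSE)
  expect_equal(assign_network_layers(edges, regs),
               c(A = "top", B = "middle", C = "bottom"))
  # no regulator-regulator edges: everyone is top
  e2 <- data.frame(source = regs, target = c("x", "y", "z"), score = 1)
  expect_equal(unname(assign_network_layers(e2, regs)), rep("top", 3))
  # 2-cycle members both regulate and are regulated: middle
  e3 <- data.frame(source = c("A", "B"), target = c("B", "A"), score = 1)
  expect_equal(assign_network_layers(e3, c("A", "B")),
               c(A = "middle", B = "middle"))
  # zero-score edges are ignored
  e4 <- data.frame(source = "A", target = "B", score = 0)
  expect_equal(unname(assign_network_layers(e4, c("A", "B"))), rep("top", 2))
})
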