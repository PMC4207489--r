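test_that("promoter windows are TSS +/- flank, half-open, clipped at zero", {
  genes <- list(
    gA = gene_model("gA", "chr1", "+", tss = 1000L,
                    exons = cbind(1000L, 2000L)),
    gB = gene_model("gB", "chr1", "-", tss = 20L, exons = cbind(0L, 21L)))
  pr <- promoter_regions(genes, flank = 50)
  expect_equal(pr$start[pr$gene_id == "gA"], 950L)
  expect_equal(pr$end[pr$gene_id == "gA"], 1051L)   # width 101 = 2*50+1
  expect_equal(pr$start[pr$gene_id == "gB"], 0L)    # clipped
  expect_equal(pr$end[pr$gene_id == "gB"], 71L)
  pr0 <- promoter_regions(genes, flank = 0)
  expect_equal(pr0$end - pr0$start, c(1L, 1L))
  expect_error(promoter_regions(genes, flank = -1), ">= 0")
})

test_that("TF binding matrix averages peak signals over promoters", {
  promoters <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                          start = c(100L, 500L), end = c(201L, 601L),
                          stringsAsFactors = FALSE)
  peaks <- data.frame(chrom = "chr1",
                      start = c(150L, 180L, 1000L),
                      end = c(160L, 190L, 1100L),
                      signal_value = c(5, 7, 3),
                      tf_name = "TF1", stringsAsFactors = FALSE)
  B <- build_tf_binding_matrix(peaks, promoters)
  expect_equal(B["TF1", "g1"], 6)   # mean of 5 and 7
  expect_equal(B["TF1", "g2"], 0)   # no overlapping peak
})

test_that("binding and CNV builders agree with brute-force overlap oracles", {
  set.seed(41)
  genes <- list()
  for (i in 1:10) {
    tss <- sample(200:5000, 1)
    genes[[sprintf("g%02d", i)]] <-
      gene_model(sprintf("g%02d", i), sample(c("c1", "c2"), 1),
                 "+", tss = tss,
                 exons = cbind(tss + c(0L, 600L), tss + c(300L, 900L)))
  }
  promoters <- promoter_regions(genes, flank = 50)
  peaks <- data.frame(
    chrom = sample(c("c1", "c2"), 60, replace = TRUE),
    start = sample(100:5500, 60), stringsAsFactors = FALSE)
  peaks$end <- peaks$start + sample(20:400, 60, replace = TRUE)
  peaks$signal_value <- round(runif(60, 0.5, 9), 3)
  peaks$tf_name <- sample(c("t1", "t2", "t3"), 60, replace = TRUE)
  expect_equal(build_tf_binding_matrix(peaks, promoters),
               oracle_binding_matrix(peaks, promoters))

  segments <- data.frame(
    sample_id = sample(c("sA", "sB"), 40, replace = TRUE),
    chrom = sample(c("c1", "c2"), 40, replace = TRUE),
    start = sample(100:5500, 40), stringsAsFactors = FALSE)
  segments$end <- segments$start + sample(50:800, 40, replace = TRUE)
  segments$segment_mean <- round(rnorm(40), 3)
  expect_equal(suppressMessages(build_cnv_matrix(segments, genes)),
               oracle_cnv_matrix(segments, genes))

  # record-order invariance
  expect_equal(build_tf_binding_matrix(peaks[sample(60), ], promoters),
               build_tf_binding_matrix(peaks, promoters))
  expect_equal(suppressMessages(build_cnv_matrix(segments[sample(40), ], genes)),
               suppressMessages(build_cnv_matrix(segments, genes)))
})

test_that("CNV matrix averages overlapping segments and defaults to neutral 0", {
  genes <- list(g1 = gene_model("g1", "c1", "+", 100L,
                                exons = cbind(100L, 400L)),
                g2 = gene_model("g2", "c1", "+", 9000L,
                                exons = cbind(9000L, 9400L)))
  segments <- data.frame(sample_id = "s1", chrom = "c1",
                         start = c(50L, 300L, 2000L), end = c(200L, 500L, 2100L),
                         segment_mean = c(0.2, 0.4, 9))
  expect_message(C <- build_cnv_matrix(segments, genes), "without any")
  expect_equal(unname(C["g1", "s1"]), 0.3)
  expect_equal(unname(C["g2", "s1"]), 0)   # no segment -> neutral copy number
})

test_that("methylation matrix averages probes and validates betas", {
  probes <- data.frame(sample_id = c("s1", "s1", "s2"),
                       gene_id = c("g1", "g1", "g1"),
                       beta = c(0.1, 0.3, 0.7))
  D <- build_methylation_matrix(probes)
  expect_equal(unname(D["g1", ]), c(0.2, 0.7))
  probes$beta[1] <- 1.2
  expect_error(build_methylation_matrix(probes), "\\[0, 1\\]")
})

test_that("expression normalisation is log2 + per-gene centring, monotone", {
  raw <- matrix(c(1, 1, 0, 3), 2, 2, byrow = TRUE,
                dimnames = list(c("g1", "g2"), c("s1", "s2")))
  out <- normalize_expression(raw, pseudo = 0.05)
  expect_equal(unname(out["g1", ]), c(0, 0))         # equal values centre to 0
  expect_equal(rowSums(out), c(g1 = 0, g2 = 0), tolerance = 1e-12)
  out2 <- normalize_expression(raw, pseudo = 0.05, center = "none")
  expect_equal(unname(out2["g2", 1]), log2(0.05))
  # monotone within a row
  expect_true(all(diff(out2["g2", order(raw["g2", ])]) >= 0))
  expect_error(normalize_expression(raw - 2), "nonnegative")
})

test_that("seed matrix uses the longest-3'UTR transcript with lexicographic ties", {
  sites <- data.frame(
    mirna = c("m1", "m1", "m2", "m2"),
    transcript = c("tx_short", "tx_long", "tB", "tA"),
    gene = c("g1", "g1", "g2", "g2"),
    utr3_length = c(100L, 200L, 150L, 150L),
    count = c(2L, 1L, 2L, 3L))
  S <- build_seed_matrix(sites, mirnas = c("m1", "m2", "m3"))
  expect_equal(S["m1", "g1"], 1L)   # longest UTR wins
  expect_equal(S["m2", "g2"], 3L)   # tie -> lexicographically smaller tA
  expect_equal(unname(S["m3", ]), c(0L, 0L))  # absent miRNA -> zero row
  expect_equal(S, build_seed_matrix(sites[sample(4), ],
                                    mirnas = c("m1", "m2", "m3")))
  sites$count[1] <- -1L
  expect_error(build_seed_matrix(sites), "nonnegative")
})
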