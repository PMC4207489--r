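# Writing a synthetic study to disk in the exact dialects the readers
# consume (GTF, narrowPeak, segment/probe/site TSVs, raw expression
# matrices), so end-to-end command-line runs touch only generated files.

# Deterministic genome layout for synthetic genes: gene i sits on chrS1 at
# [i*10000, i*10000 + 2000), '+' strand, one transcript whose last 300 bp
# form the 3'UTR. TSS (0-based) = i*10000.
synthetic_gene_layout <- function(genes) {
  i <- seq_along(genes)
  data.frame(gene_id = genes, chrom = "chrS1",
             start0 = i * 10000L, end0 = i * 10000L + 2000L,
             tss = i * 10000L, utr3_length = 300L,
             transcript = paste0(genes, ".t1"), stringsAsFactors = FALSE)
}

#' Write a synthetic study as an on-disk fixture directory
#'
#' Materialises the generated bundle in the raw formats the preprocessing
#' readers expect: `annotation.gtf`, `peaks.narrowPeak`, `cnv_segments.tsv`,
#' `methylation.tsv`, `seed_sites.tsv`, raw expression matrices
#' (`mrna_raw.tsv` = 2^E, `mirna_raw.tsv` = 2^X, so that log2 with a zero
#' pseudo-count recovers the bundle), `clinical.tsv`, and the planted truth
#' (`truth_edges.tsv`, `truth_tf_activities.tsv`, `truth_mir_activities.tsv`).
#'
#' @param sim Result of [generate_bundle()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle_dir <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  b <- sim$bundle
  lay <- synthetic_gene_layout(b$genes)
  fp <- function(x) file.path(dir, x)

  # GTF (1-based inclusive): gene, transcript, exon, three_prime_utr
  attr_of <- function(g, tx = NULL) {
    a <- sprintf('gene_id "%s";', g)
    if (!is.null(tx)) a <- paste(a, sprintf('transcript_id "%s";', tx))
    a
  }
  gtf_row <- function(type, s0, e0, g, tx = NULL)
    paste(c("chrS1", "synth", type, s0 + 1L, e0, ".", "+", ".",
            attr_of(g, tx)), collapse = "\t")
  lines <- unlist(lapply(seq_len(nrow(lay)), function(i) {
    r <- lay[i, ]
    c(gtf_row("gene", r$start0, r$end0, r$gene_id),
      gtf_row("transcript", r$start0, r$end0, r$gene_id, r$transcript),
      gtf_row("exon", r$start0, r$end0, r$gene_id, r$transcript),
      gtf_row("three_prime_utr", r$end0 - r$utr3_length, r$end0,
              r$gene_id, r$transcript))
  }))
  writeLines(lines, fp("annotation.gtf"))

  # narrowPeak: one peak per nonzero binding entry, spanning the promoter
  idx <- which(b$B > 0, arr.ind = TRUE)
  if (nrow(idx)) {
    tss <- lay$tss[match(colnames(b$B)[idx[, 2L]], lay$gene_id)]
    pk <- sprintf("chrS1\t%d\t%d\t%s_peak%d\t%d\t.\t%.17g\t-1\t-1\t-1",
                  pmax(0L, tss - 50L), tss + 51L,
                  rownames(b$B)[idx[, 1L]], seq_len(nrow(idx)),
                  pmin(1000L, as.integer(round(100 * b$B[idx]))),
                  b$B[idx])
    writeLines(pk, fp("peaks.narrowPeak"))
  } else writeLines(character(0), fp("peaks.narrowPeak"))

  # CNV segments: one per gene x sample covering the gene body
  gi <- match(b$genes, lay$gene_id)
  seg <- data.frame(
    sample_id = rep(b$samples, each = length(b$genes)),
    chrom = "chrS1",
    start = rep(lay$start0[gi], length(b$samples)),
    end = rep(lay$end0[gi], length(b$samples)),
    segment_mean = sprintf("%.17g", as.vector(b$C)))
  utils::write.table(seg, fp("cnv_segments.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # methylation probes: one per gene x sample
  pr <- data.frame(sample_id = rep(b$samples, each = length(b$genes)),
                   gene_id = rep(b$genes, length(b$samples)),
                   beta = sprintf("%.17g", as.vector(b$D)))
  utils::write.table(pr, fp("methylation.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # seed sites on the longest (only) transcript
  sidx <- which(b$S > 0, arr.ind = TRUE)
  st <- data.frame(
    mirna = rownames(b$S)[sidx[, 1L]],
    transcript = lay$transcript[match(colnames(b$S)[sidx[, 2L]], lay$gene_id)],
    gene = colnames(b$S)[sidx[, 2L]],
    utr3_length = 300L,
    count = b$S[sidx], stringsAsFactors = FALSE)
  st <- st[order(st$mirna, st$gene), ]
  utils::write.table(st, fp("seed_sites.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  write_matrix_tsv(2^b$E, fp("mrna_raw.tsv"))
  write_matrix_tsv(2^b$X, fp("mirna_raw.tsv"))

  cl <- sim$truth$clinical
  utils::write.table(
    data.frame(sample_id = cl$sample_id, risk_group = cl$risk_group,
               days_to_death_or_censor = sprintf("%.17g", cl$time_to_event),
               event = cl$event),
    fp("clinical.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  utils::write.table(sim$truth$edges_true, fp("truth_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_matrix_tsv(sim$truth$W_true, fp("truth_tf_activities.tsv"))
  write_matrix_tsv(sim$truth$U_true, fp("truth_mir_activities.tsv"))
  invisible(dir)
}
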