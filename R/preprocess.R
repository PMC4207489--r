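# Building the five regression input matrices from genomic inputs.
#
# Conventions: promoters are TSS +/- flank (inclusive on both sides, hence a
# half-open window of width 2*flank + 1); any >= 1 bp overlap counts; multiple
# scores per gene are averaged.

#' Promoter windows around each TSS
#'
#' For every gene the window `[tss - flank, tss + flank + 1)` (0-based
#' half-open, clipped at 0), i.e. TSS +/- `flank` bases inclusive. Strand
#' affects only which coordinate is the TSS (resolved at annotation parse
#' time).
#'
#' @param genes Named list of gene models from [read_gene_annotation()].
#' @param flank Nonnegative flank in bases (default 50).
#' @return `data.frame` with columns `gene_id`, `chrom`, `start`, `end`.
#' @export
promoter_regions <- function(genes, flank = 50L) {
  if (flank < 0) stopf("flank must be >= 0")
  tss <- vapply(genes, `[[`, integer(1L), "tss")
  data.frame(gene_id = vapply(genes, `[[`, character(1L), "gene_id"),
             chrom = vapply(genes, `[[`, character(1L), "chrom"),
             start = pmax(0L, tss - as.integer(flank)),
             end = tss + as.integer(flank) + 1L,
             row.names = NULL, stringsAsFactors = FALSE)
}

# 0-based half-open intervals -> GRanges (1-based closed internally).
as_granges0 <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
}

#' TF binding matrix from peaks over promoters
#'
#' `B[t, g]` is the mean binding score of TF `t`'s peaks overlapping gene
#' `g`'s promoter by at least 1 bp (averaging collapses multiple peaks to a
#' single binding site per TF-gene pair); 0 where no peak overlaps.
#'
#' @param peaks Peak table from [read_narrowpeak()].
#' @param promoters Promoter table from [promoter_regions()].
#' @return Nonnegative T x G matrix (TFs x genes), rows and columns sorted.
#' @export
build_tf_binding_matrix <- function(peaks, promoters) {
  tfs <- sort(unique(peaks$tf_name))
  genes <- sort(promoters$gene_id)
  B <- matrix(0, length(tfs), length(genes), dimnames = list(tfs, genes))
  if (nrow(peaks) == 0L || length(genes) == 0L) return(B)
  gp <- as_granges0(promoters$chrom, promoters$start, promoters$end)
  pk <- as_granges0(peaks$chrom, peaks$start, peaks$end)
  hits <- GenomicRanges::findOverlaps(pk, gp)
  if (length(hits)) {
    df <- data.frame(tf = peaks$tf_name[S4Vectors::queryHits(hits)],
                     gene = promoters$gene_id[S4Vectors::subjectHits(hits)],
                     sig = peaks$signal_value[S4Vectors::queryHits(hits)])
    agg <- stats::aggregate(sig ~ tf + gene, data = df, FUN = mean)
    B[cbind(agg$tf, agg$gene)] <- agg$sig
  }
  B
}

#' Copy-number matrix from segmented SNP-array calls
#'
#' `C[g, s]` is the mean `segment_mean` over segments of sample `s`
#' overlapping any exon of gene `g` (each segment counted once per gene).
#' Genes with no overlapping segment in a sample get 0, interpreted as
#' neutral copy number on the log segment-mean scale, and are reported.
#'
#' @param segments `data.frame` with columns `sample_id`, `chrom`, `start`,
#'   `end` (0-based half-open), `segment_mean`.
#' @param genes Named list of gene models.
#' @return G x N matrix (genes x samples), sorted ids.
#' @export
build_cnv_matrix <- function(segments, genes) {
  if (any(segments$start >= segments$end))
    stopf("segment table: start must be < end")
  gids <- sort(vapply(genes, `[[`, character(1L), "gene_id"))
  samples <- sort(unique(segments$sample_id))
  C <- matrix(0, length(gids), length(samples), dimnames = list(gids, samples))
  ex <- do.call(rbind, lapply(genes, function(g)
    data.frame(gene = g$gene_id, chrom = g$chrom,
               start = g$exons[, 1L], end = g$exons[, 2L])))
  exr <- as_granges0(ex$chrom, ex$start, ex$end)
  segr <- as_granges0(segments$chrom, segments$start, segments$end)
  hits <- GenomicRanges::findOverlaps(segr, exr)
  n_missing <- 0L
  if (length(hits)) {
    df <- unique(data.frame(seg = S4Vectors::queryHits(hits),
                            gene = ex$gene[S4Vectors::subjectHits(hits)]))
    df$sample <- segments$sample_id[df$seg]
    df$score <- segments$segment_mean[df$seg]
    agg <- stats::aggregate(score ~ gene + sample, data = df, FUN = mean)
    C[cbind(agg$gene, agg$sample)] <- agg$score
    covered <- unique(agg$gene)
    n_missing <- length(setdiff(gids, covered))
  } else n_missing <- length(gids)
  if (n_missing > 0L)
    message(sprintf("build_cnv_matrix: %d gene(s) without any overlapping segment set to 0",
                    n_missing))
  C
}

#' Methylation matrix from probe-level beta values
#'
#' `D[g, s]` is the mean beta over probes assigned to gene `g` in sample `s`.
#'
#' @param probes `data.frame` with columns `sample_id`, `gene_id`, `beta`.
#' @return G x N matrix (genes x samples), sorted ids.
#' @export
build_methylation_matrix <- function(probes) {
  if (any(probes$beta < 0 | probes$beta > 1))
    stopf("methylation beta values must lie in [0, 1]")
  agg <- stats::aggregate(beta ~ gene_id + sample_id, data = probes, FUN = mean)
  gids <- sort(unique(probes$gene_id))
  samples <- sort(unique(probes$sample_id))
  D <- matrix(NA_real_, length(gids), length(samples),
              dimnames = list(gids, samples))
  D[cbind(agg$gene_id, agg$sample_id)] <- agg$beta
  D
}

#' Log-transform and centre an expression matrix
#'
#' `log2(raw + pseudo)`, then per-gene (per-row, across samples) mean
#' subtraction when `center = "gene"`, so every centred row sums to zero.
#'
#' @param raw Nonnegative matrix (RPKM/RPM-like units).
#' @param pseudo Pseudo-count added before the log (default 0.05).
#' @param center `"gene"` (default) or `"none"`.
#' @return Matrix of the same shape.
#' @export
normalize_expression <- function(raw, pseudo = 0.05, center = c("gene", "none")) {
  center <- match.arg(center)
  if (any(raw < 0)) stopf("expression input must be nonnegative")
  out <- log2(raw + pseudo)
  if (center == "gene") out <- out - rowMeans(out)
  out
}

#' Seed-match count matrix from a TargetScan-style site table
#'
#' For genes with several transcripts, counts come from the transcript with
#' the longest 3'UTR (ties broken by the lexicographically smallest
#' transcript id). miRNAs absent from the table get all-zero rows.
#'
#' @param sites `data.frame` with columns `mirna`, `transcript`, `gene`,
#'   `utr3_length`, `count` (nonnegative integers).
#' @param mirnas,genes Optional identifier universes for the matrix
#'   dimensions; default to the ids present in the table.
#' @return M x G integer matrix (miRNAs x genes).
#' @export
build_seed_matrix <- function(sites, mirnas = NULL, genes = NULL) {
  if (any(sites$count < 0) || any(sites$count != round(sites$count)))
    stopf("seed-site counts must be nonnegative integers")
  if (is.null(mirnas)) mirnas <- sort(unique(sites$mirna))
  if (is.null(genes)) genes <- sort(unique(sites$gene))
  S <- matrix(0L, length(mirnas), length(genes), dimnames = list(mirnas, genes))
  if (nrow(sites) == 0L) return(S)
  # pick the longest-3'UTR transcript per gene (tie -> smallest transcript id)
  tx <- unique(sites[, c("gene", "transcript", "utr3_length")])
  tx <- tx[order(tx$gene, -tx$utr3_length, tx$transcript), ]
  chosen <- tx[!duplicated(tx$gene), c("gene", "transcript")]
  keep <- merge(sites, chosen, by = c("gene", "transcript"))
  keep <- keep[keep$mirna %in% mirnas & keep$gene %in% genes, ]
  if (nrow(keep)) S[cbind(keep$mirna, keep$gene)] <- as.integer(keep$count)
  S
}

#' Read a CNV segment table
#'
#' Tab-separated columns `sample_id`, `chrom`, `start`, `end` (0-based
#' half-open), `segment_mean`.
#' @param path TSV path.
#' @return `data.frame` with those columns.
#' @export
read_segment_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "chrom", "start", "end", "segment_mean")
  if (!all(need %in% names(tab)))
    stopf("segment table %s must have columns: %s", path, paste(need, collapse = ", "))
  tab[need]
}

#' Read a methylation probe table
#'
#' Tab-separated columns `sample_id`, `gene_id`, `beta`.
#' @param path TSV path.
#' @return `data.frame` with those columns.
#' @export
read_probe_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "gene_id", "beta")
  if (!all(need %in% names(tab)))
    stopf("probe table %s must have columns: %s", path, paste(need, collapse = ", "))
  tab[need]
}

#' Read a TargetScan-style seed-site table
#'
#' Tab-separated columns `mirna`, `transcript`, `gene`, `utr3_length`, `count`.
#' @param path TSV path.
#' @return `data.frame` with those columns.
#' @export
read_site_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("mirna", "transcript", "gene", "utr3_length", "count")
  if (!all(need %in% names(tab)))
    stopf("site table %s must have columns: %s", path, paste(need, collapse = ", "))
  tab[need]
}
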