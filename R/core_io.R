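# Readers, writers and identifier alignment for the formats the tool touches.
# All genomic coordinates are 0-based half-open internally; conversions happen
# only at parse time.

#' Read ENCODE narrowPeak files
#'
#' Parses a (BED6+4) narrowPeak file into a peak table. The binding score used
#' downstream is the `signalValue` column (column 7) by default; column 5
#' (the capped display score) can be selected instead.
#'
#' @param path Path to a narrowPeak file.
#' @param tf Transcription-factor label to attach to every peak. When `NULL`
#'   (default) the label is derived from the peak name column by stripping a
#'   trailing `_peak<digits>` suffix, so a single file can carry several TFs.
#' @param score_column Which column provides the binding score downstream:
#'   `"signalValue"` (column 7, default) or `"score"` (column 5).
#' @return A `data.frame` with columns `chrom`, `start`, `end` (0-based
#'   half-open), `name`, `score_col5`, `strand`, `signal_value`, `tf_name`.
#'   The `signal_value` column always holds the selected binding score.
#' @export
read_narrowpeak <- function(path, tf = NULL,
                            score_column = c("signalValue", "score")) {
  score_column <- match.arg(score_column)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score_col5 = numeric(),
                      strand = character(), signal_value = numeric(),
                      tf_name = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf < 10L)
  if (length(bad))
    stopf("narrowPeak parse error at line %d of %s: expected >= 10 columns, found %d",
          bad[1L], path, nf[bad[1L]])
  get_col <- function(i) vapply(fields, `[[`, character(1L), i)
  start <- suppressWarnings(as.numeric(get_col(2L)))
  end <- suppressWarnings(as.numeric(get_col(3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stopf("narrowPeak parse error at line %d of %s: non-numeric coordinates",
          bad[1L], path)
  bad <- which(start >= end)
  if (length(bad))
    stopf("narrowPeak parse error at line %d of %s: start >= end", bad[1L], path)
  score5 <- suppressWarnings(as.numeric(get_col(5L)))
  signal <- suppressWarnings(as.numeric(get_col(7L)))
  bad <- which(is.na(signal) | signal < 0)
  if (length(bad))
    stopf("narrowPeak parse error at line %d of %s: signalValue must be a nonnegative number",
          bad[1L], path)
  name <- get_col(4L)
  tf_name <- if (is.null(tf)) sub("_peak[0-9]*$", "", name) else rep(tf, length(name))
  value <- if (score_column == "signalValue") signal else score5
  if (any(is.na(value) | value < 0))
    stopf("narrowPeak parse error in %s: selected score column has negative or non-numeric values", path)
  data.frame(chrom = get_col(1L), start = as.integer(start), end = as.integer(end),
             name = name, score_col5 = score5, strand = get_col(6L),
             signal_value = value, tf_name = tf_name, stringsAsFactors = FALSE)
}

#' Read gene annotation (GTF or BED) into gene models
#'
#' GTF input (1-based inclusive) is converted to the internal 0-based
#' half-open convention; BED input is already 0-based half-open. The TSS is
#' the interval start for `+` genes and `end - 1` for `-` genes. For GTF
#' input, 3'UTR lengths are summed per transcript from `three_prime_utr`
#' features when present.
#'
#' @param path Annotation file path.
#' @param dialect `"gtf"` or `"bed"`.
#' @return A named list of gene models; each element has fields `gene_id`,
#'   `chrom`, `strand`, `tss` (0-based), `exons` (2-column matrix of 0-based
#'   half-open intervals) and `utr3` (named numeric vector of per-transcript
#'   3'UTR lengths, possibly empty).
#' @export
read_gene_annotation <- function(path, dialect = c("gtf", "bed")) {
  dialect <- match.arg(dialect)
  if (dialect == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    type <- as.character(gr$type)
    strand <- as.character(GenomicRanges::strand(gr))
    if (any(!strand %in% c("+", "-")))
      stopf("gene annotation parse error in %s: unknown strand character", path)
    genes <- gr[type == "gene"]
    if (length(genes) == 0L) { # derive gene extents from exons
      ex_all <- gr[type == "exon"]
      genes <- unlist(range(GenomicRanges::split(ex_all, ex_all$gene_id)))
      genes$gene_id <- names(genes)
    }
    out <- list()
    for (i in seq_along(genes)) {
      gid <- genes$gene_id[i]
      g_strand <- as.character(GenomicRanges::strand(genes))[i]
      start0 <- GenomicRanges::start(genes)[i] - 1L
      end0 <- GenomicRanges::end(genes)[i]
      ex <- gr[type == "exon" & gr$gene_id == gid]
      exons <- if (length(ex)) {
        cbind(start = GenomicRanges::start(ex) - 1L, end = GenomicRanges::end(ex))
      } else cbind(start = start0, end = end0)
      utr <- gr[type %in% c("three_prime_utr", "three_prime_UTR") & gr$gene_id == gid]
      utr3 <- numeric(0)
      if (length(utr)) {
        utr3 <- tapply(GenomicRanges::width(utr), utr$transcript_id, sum)
        utr3 <- stats::setNames(as.numeric(utr3), names(utr3))
      }
      out[[gid]] <- gene_model(gid, as.character(GenomicRanges::seqnames(genes))[i],
                               g_strand,
                               tss = if (g_strand == "+") start0 else end0 - 1L,
                               exons = exons, utr3 = utr3)
    }
    return(out)
  }
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 6L)
    stopf("BED gene annotation in %s needs 6 columns (strand required)", path)
  if (any(!bed[[6L]] %in% c("+", "-")))
    stopf("gene annotation parse error in %s: unknown strand character", path)
  out <- list()
  for (i in seq_len(nrow(bed))) {
    s <- bed[i, 6L]
    out[[bed[i, 4L]]] <- gene_model(
      bed[i, 4L], bed[i, 1L], s,
      tss = if (s == "+") bed[i, 2L] else bed[i, 3L] - 1L,
      exons = cbind(start = bed[i, 2L], end = bed[i, 3L]), utr3 = numeric(0))
  }
  out
}

# Validating constructor for a single gene model.
gene_model <- function(gene_id, chrom, strand, tss, exons, utr3 = numeric(0)) {
  if (!strand %in% c("+", "-")) stopf("gene %s: strand must be '+' or '-'", gene_id)
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (any(exons[, 1L] >= exons[, 2L]))
    stopf("gene %s: exon intervals must have start < end", gene_id)
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 tss = as.integer(tss), exons = exons, utr3 = utr3),
            class = "gene_model")
}

#' Read a GMT gene-set file
#'
#' Tab-separated lines: set name, description, then genes. Genes are
#' deduplicated within a set; a repeated set name is an error (a silent merge
#' would hide file corruption).
#'
#' @param path Path to a `.gmt` file.
#' @return Named list mapping set name to a character vector of genes.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stopf("GMT parse error at line %d of %s: expected >= 3 tab-separated fields", i, path)
    if (f[1L] %in% names(out))
      stopf("GMT parse error at line %d of %s: duplicate set name '%s'", i, path, f[1L])
    out[[f[1L]]] <- unique(f[-(1:2)])
  }
  out
}

#' Read a clinical table
#'
#' Expects tab-separated columns `sample_id`, `risk_group`,
#' `days_to_death_or_censor`, `event` (0 = censored, 1 = death).
#'
#' @param path Path to the clinical TSV.
#' @return A `data.frame` with columns `sample_id`, `risk_group`,
#'   `time_to_event`, `event`.
#' @export
read_clinical <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "risk_group", "days_to_death_or_censor", "event")
  if (!all(need %in% names(tab)))
    stopf("clinical table %s must have columns: %s", path, paste(need, collapse = ", "))
  if (anyDuplicated(tab$sample_id)) stopf("clinical table %s: duplicate sample ids", path)
  if (any(tab$days_to_death_or_censor < 0)) stopf("clinical table %s: negative times", path)
  if (any(!tab$event %in% c(0, 1))) stopf("clinical table %s: event must be 0/1", path)
  data.frame(sample_id = as.character(tab$sample_id),
             risk_group = as.character(tab$risk_group),
             time_to_event = as.numeric(tab$days_to_death_or_censor),
             event = as.integer(tab$event), stringsAsFactors = FALSE)
}

#' Read / write labelled matrices as TSV
#'
#' Matrices travel as TSV with a header row of sample (column) ids and the
#' feature id in the first column. Values are written with 17 significant
#' digits so a write/read round trip preserves doubles exactly.
#'
#' @param x Numeric matrix with dimnames.
#' @param path File path.
#' @param comment Optional comment lines (written prefixed with `#`).
#' @return `read_matrix_tsv` returns a numeric matrix with dimnames;
#'   `write_matrix_tsv` returns `path` invisibly.
#' @export
write_matrix_tsv <- function(x, path, comment = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste(c("feature", colnames(x)), collapse = "\t"), con)
  body <- apply(x, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(paste(rownames(x), body, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- as.character(tab[[1L]])
  m
}

#' Construct an aligned multi-omics bundle
#'
#' The container for everything the two regression stages consume: log2
#' mean-centred mRNA expression `E` (genes x samples), miRNA expression `X`
#' (miRNAs x samples), copy-number `C` and methylation `D` (genes x samples),
#' nonnegative TF binding scores `B` (TFs x genes) and nonnegative integer
#' seed-match counts `S` (miRNAs x genes). All matrices must be fully aligned
#' and free of missing values.
#'
#' @param E,X,C,D,B,S Matrices as described above, with dimnames.
#' @return An object of class `omics_bundle`.
#' @export
omics_bundle <- function(E, X, C, D, B, S) {
  genes <- rownames(E); samples <- colnames(E)
  mirnas <- rownames(X); tfs <- rownames(B)
  chk <- function(m, nm, rows, cols) {
    if (!identical(rownames(m), rows) || !identical(colnames(m), cols))
      stopf("bundle matrix %s is not aligned", nm)
    if (anyNA(m)) stopf("bundle matrix %s contains missing values", nm)
  }
  chk(E, "E", genes, samples); chk(X, "X", mirnas, samples)
  chk(C, "C", genes, samples); chk(D, "D", genes, samples)
  chk(B, "B", tfs, genes); chk(S, "S", mirnas, genes)
  if (any(B < 0)) stopf("binding matrix B must be nonnegative")
  if (any(S < 0) || any(S != round(S)))
    stopf("seed-count matrix S must hold nonnegative integers")
  structure(list(genes = genes, mirnas = mirnas, tfs = tfs, samples = samples,
                 E = E, X = X, C = C, D = D, B = B, S = S),
            class = "omics_bundle")
}

#' @export
print.omics_bundle <- function(x, ...) {
  cat(sprintf("omics_bundle: %d genes x %d samples; %d TFs, %d miRNAs\n",
              length(x$genes), length(x$samples), length(x$tfs), length(x$mirnas)))
  cat(sprintf("  B support: %.1f%%; S support: %.1f%%\n",
              100 * mean(x$B > 0), 100 * mean(x$S > 0)))
  invisible(x)
}

#' Align raw labelled matrices into an omics bundle
#'
#' Samples are restricted to the intersection across `E`, `X`, `C`, `D`;
#' genes to those present in `E`, `C`, `D` and in at least one of `B`'s or
#' `S`'s columns (a gene without ChIP evidence keeps an all-zero binding
#' column provided it has seed-site information, and vice versa). Identifier
#' order is deterministic (sorted), so the result is invariant to input
#' row/column permutations. Dropped identifiers are reported via `message()`.
#'
#' @param E,X,C,D,B,S Labelled matrices (dimnames required) in the
#'   orientations described in [omics_bundle()].
#' @return An [omics_bundle()].
#' @export
align_bundle <- function(E, X, C, D, B, S) {
  samples <- sort(Reduce(intersect, list(colnames(E), colnames(X),
                                         colnames(C), colnames(D))))
  if (length(samples) == 0L) stopf("no samples shared across E, X, C and D")
  genes <- sort(intersect(intersect(rownames(E), rownames(C)),
                          intersect(rownames(D),
                                    union(colnames(B), colnames(S)))))
  if (length(genes) == 0L) stopf("no genes shared across E, C, D and B/S")
  dropped <- setdiff(rownames(E), genes)
  if (length(dropped))
    message(sprintf("align_bundle: dropped %d gene(s) absent from C, D or B/S",
                    length(dropped)))
  dropped_s <- setdiff(unique(c(colnames(E), colnames(X), colnames(C), colnames(D))),
                       samples)
  if (length(dropped_s))
    message(sprintf("align_bundle: dropped %d sample(s) not shared by all matrices",
                    length(dropped_s)))
  mirnas <- sort(rownames(X))
  tfs <- sort(rownames(B))
  B2 <- {
    out <- matrix(0, length(tfs), length(genes), dimnames = list(tfs, genes))
    keep <- intersect(genes, colnames(B))
    out[, keep] <- B[tfs, keep, drop = FALSE]
    out
  }
  S2 <- {
    out <- matrix(0L, length(mirnas), length(genes), dimnames = list(mirnas, genes))
    keep <- intersect(genes, colnames(S))
    out[, keep] <- S[mirnas, keep, drop = FALSE]
    out
  }
  bun <- omics_bundle(E = E[genes, samples, drop = FALSE],
                      X = X[mirnas, samples, drop = FALSE],
                      C = C[genes, samples, drop = FALSE],
                      D = D[genes, samples, drop = FALSE],
                      B = B2, S = S2)
  bun
}
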