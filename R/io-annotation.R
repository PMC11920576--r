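#' Read a gene annotation table
#'
#' Loads a tabular gene annotation with columns `gene_id`, `chrom`, `strand`,
#' `txStart`, `txEnd` (0-based half-open) and `is_tf` (0/1), and derives the
#' transcription start site at load time: `tss = txStart` on the `+` strand
#' and `tss = txEnd - 1` (the last transcribed base) on the `-` strand.  The
#' returned `tss` column is 0-based.
#'
#' @param path annotation file path (TSV with header).
#' @return a `data.frame` with columns `geneId`, `chrom`, `strand`, `txStart`,
#'   `txEnd`, `tss`, `isTF`.
#' @export
#' @examples
#' tf <- tempfile()
#' writeLines(c("gene_id\tchrom\tstrand\ttxStart\ttxEnd\tis_tf",
#'              "g1\tchr1\t+\t1000\t2000\t0",
#'              "g2\tchr1\t-\t1000\t2000\t1"), tf)
#' readGeneAnnotation(tf)$tss  # 1000, 1999
readGeneAnnotation <- function(path) {
  df <- readHeaderTable(path,
    required = c("gene_id", "chrom", "strand", "txStart", "txEnd", "is_tf"))
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id in annotation: ",
         df$gene_id[duplicated(df$gene_id)][1L])
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (any(df$txStart < 0) || any(df$txStart >= df$txEnd))
    stop("gene coordinates must satisfy 0 <= txStart < txEnd")
  out <- data.frame(geneId = df$gene_id, chrom = df$chrom,
                    strand = df$strand,
                    txStart = as.integer(df$txStart),
                    txEnd = as.integer(df$txEnd),
                    tss = ifelse(df$strand == "+",
                                 as.integer(df$txStart),
                                 as.integer(df$txEnd) - 1L),
                    isTF = as.logical(df$is_tf),
                    stringsAsFactors = FALSE)
  if (any(out$tss < 0)) stop("derived TSS must be >= 0")
  out
}

#' Write a gene annotation table
#'
#' Inverse of [readGeneAnnotation()] (the derived `tss` column is not
#' written; it is recomputed at load time).
#'
#' @param genes a gene annotation `data.frame` as from [readGeneAnnotation()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeGeneAnnotation <- function(genes, path) {
  df <- data.frame(gene_id = genes$geneId, chrom = genes$chrom,
                   strand = genes$strand, txStart = genes$txStart,
                   txEnd = genes$txEnd, is_tf = as.integer(genes$isTF))
  writeTable(df, path)
}

#' Read a differential expression table
#'
#' Header-driven loader for DEG tables with columns `gene_id`, `log2fc`,
#' `pvalue`, `qvalue` (the adjusted p).  Common alternative headers from
#' differential-expression output (`log2FoldChange`, `padj`, `FDR`) are
#' mapped automatically.
#'
#' @param path DEG table path (TSV with header).
#' @return a `data.frame` with columns `geneId`, `log2fc`, `pvalue`,
#'   `qvalue`.
#' @export
readDegTable <- function(path) {
  df <- readHeaderTable(path,
    required = c("gene_id", "log2fc", "pvalue", "qvalue"),
    aliases = list(gene_id = c("gene", "geneId"),
                   log2fc = c("log2FoldChange", "logFC"),
                   pvalue = c("p_value", "PValue"),
                   qvalue = c("padj", "FDR", "q_value")))
  p <- df$pvalue; q <- df$qvalue
  if (any(p < 0 | p > 1, na.rm = TRUE) || any(q < 0 | q > 1, na.rm = TRUE))
    stop("pvalue and qvalue must lie in [0, 1]")
  data.frame(geneId = df$gene_id, log2fc = as.numeric(df$log2fc),
             pvalue = as.numeric(p), qvalue = as.numeric(q),
             stringsAsFactors = FALSE)
}

#' Write a differential expression table
#'
#' @param deg a `data.frame` as returned by [readDegTable()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeDegTable <- function(deg, path) {
  df <- data.frame(gene_id = deg$geneId, log2fc = deg$log2fc,
                   pvalue = deg$pvalue, qvalue = deg$qvalue)
  writeTable(df, path)
}

#' Read gene sets in GMT format
#'
#' Each line is `name <TAB> description <TAB> member1 <TAB> member2 ...`.
#' Set names must be unique and member lists non-empty.
#'
#' @param path GMT file path.
#' @return a named list of character vectors; descriptions are kept in the
#'   `"descriptions"` attribute.
#' @export
readGeneSets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("GMT line ", bad[1L], " has no members")
  nm <- vapply(fields, `[`, character(1L), 1L)
  if (anyDuplicated(nm))
    stop("duplicate gene set name: ", nm[duplicated(nm)][1L])
  sets <- lapply(fields, function(f) unique(f[-c(1L, 2L)]))
  names(sets) <- nm
  attr(sets, "descriptions") <-
    stats::setNames(vapply(fields, `[`, character(1L), 2L), nm)
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors (a `"descriptions"` attribute
#'   is honoured when present).
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeGeneSets <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- stats::setNames(rep("", length(sets)),
                                             names(sets))
  nm <- sort(names(sets), method = "radix")
  lines <- vapply(nm, function(n)
    paste(c(n, desc[[n]], sets[[n]]), collapse = "\t"), character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression matrix
#'
#' Loads a genes-by-samples matrix of FPKM values from a TSV whose first
#' column is the gene identifier.
#'
#' @param path TSV path.
#' @return a numeric matrix with gene rownames.
#' @export
readExpressionMatrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  if (any(m < 0)) stop("expression values must be >= 0")
  m
}
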