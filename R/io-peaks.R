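#' Read enhancer peaks from narrowPeak or BED6+signal files
#'
#' Parses H3K27ac enhancer peaks with their sample and (optionally) matched
#' input signal.  Input files use BED semantics: 0-based half-open
#' coordinates.  Peaks are returned as a `GRanges` (1-based closed, the
#' Bioconductor convention) sorted by `(chrom, start)` with metadata columns
#' `name`, `sampleSignal` and `inputSignal`.
#'
#' Dialects:
#' \describe{
#'   \item{`narrowPeak`}{ENCODE narrowPeak (BED6+4); column 7 (`signalValue`)
#'     becomes `sampleSignal`.  `inputSignal` is 0 unless `inputPath` names a
#'     same-shape file of matched input signal, matched row-wise by peak name.}
#'   \item{`bed`}{BED6+2: columns 7 and 8 are the sample and input signal.}
#' }
#'
#' @param path peak file path.
#' @param dialect `"narrowPeak"` or `"bed"`.
#' @param inputPath optional narrowPeak-format file whose `signalValue`
#'   supplies the matched input signal (narrowPeak dialect only).
#' @return a sorted `GRanges` of validated peaks.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t100\t200\tp1\t0\t.\t5\t1",
#'              "chr1\t50\t80\tp2\t0\t.\t2\t0"), tf)
#' readPeaks(tf, dialect = "bed")
readPeaks <- function(path, dialect = c("narrowPeak", "bed"),
                      inputPath = NULL) {
  dialect <- match.arg(dialect)
  raw <- readPeakLines(path, dialect)
  if (nrow(raw) == 0L) {
    warning("empty peak file: ", path)
    return(GRanges(name = character(), sampleSignal = numeric(),
                   inputSignal = numeric()))
  }
  if (dialect == "narrowPeak" && !is.null(inputPath)) {
    inp <- readPeakLines(inputPath, "narrowPeak")
    idx <- match(raw$name, inp$name)
    if (anyNA(idx))
      stop("input peak file does not cover all peaks; first missing: ",
           raw$name[which(is.na(idx))[1L]])
    raw$inputSignal <- inp$sampleSignal[idx]
  }
  key <- paste(raw$chrom, raw$start, raw$end, raw$name)
  if (anyDuplicated(key))
    stop("duplicate peak (chrom,start,end,name): ",
         key[duplicated(key)][1L])
  gr <- GRanges(raw$chrom, IRanges(raw$start + 1L, raw$end),
                name = raw$name, sampleSignal = raw$sampleSignal,
                inputSignal = raw$inputSignal)
  sortPeaks(gr)
}

# Sort peaks by (chrom, start) with chromosome names in lexicographic order.
sortPeaks <- function(gr) {
  gr <- gr[order(as.character(seqnames(gr)), start(gr), end(gr),
                 method = "radix")]
  GenomeInfoDb::seqlevels(gr) <-
    sort(GenomeInfoDb::seqlevels(gr), method = "radix")
  gr
}

readPeakLines <- function(path, dialect) {
  if (!file.exists(path)) stop("peak file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      sampleSignal = numeric(), inputSignal = numeric()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  minCols <- 4L
  bad <- which(ncol < minCols)
  if (length(bad))
    stop("malformed peak line ", bad[1L], " in ", path,
         ": fewer than ", minCols, " columns")
  getCol <- function(i) vapply(fields, `[`, character(1L), i)
  chrom <- getCol(1L)
  start <- suppressWarnings(as.numeric(getCol(2L)))
  end <- suppressWarnings(as.numeric(getCol(3L)))
  name <- getCol(4L)
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed peak line ", bad[1L], " in ", path,
         ": unparseable coordinates")
  bad <- which(start >= end | start < 0)
  if (length(bad))
    stop("invalid interval at line ", bad[1L], " in ", path,
         ": start must satisfy 0 <= start < end")
  sig <- function(i, default = 0) {
    out <- rep(default, length(fields))
    has <- ncol >= i
    if (any(has)) {
      v <- suppressWarnings(as.numeric(vapply(fields[has], `[`,
                                              character(1L), i)))
      if (anyNA(v)) stop("non-numeric signal column ", i, " in ", path)
      out[has] <- v
    }
    out
  }
  samp <- sig(7L)
  inpt <- if (identical(dialect, "bed")) sig(8L) else rep(0, length(fields))
  if (any(samp < 0) || any(inpt < 0))
    stop("negative signal values in ", path)
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             name = name, sampleSignal = samp, inputSignal = inpt,
             stringsAsFactors = FALSE)
}

#' Write peaks as BED6+2
#'
#' Inverse of `readPeaks(dialect = "bed")`: emits 0-based half-open intervals
#' with sample and input signal in columns 7-8, sorted by `(chrom, start)`.
#'
#' @param peaks a `GRanges` with `name`, `sampleSignal`, `inputSignal`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writePeaks <- function(peaks, path) {
  peaks <- sortPeaks(peaks)
  df <- data.frame(chrom = as.character(seqnames(peaks)),
                   start = start(peaks) - 1L, end = end(peaks),
                   name = mcols(peaks)$name, score = 0L, strand = ".",
                   sampleSignal = mcols(peaks)$sampleSignal,
                   inputSignal = mcols(peaks)$inputSignal)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}
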