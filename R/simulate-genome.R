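#' Simulate the synthetic genome and gene annotation
#'
#' Places `nGenes` genes on a regular per-chromosome grid (round-robin
#' across chromosomes, even spacing, at least 30 kb apart -- an error is
#' raised when the chromosome is too small), flags
#' `floor(tfFraction * nGenes)` evenly spread genes as transcription
#' factors, and draws an i.i.d. background sequence with the configured GC
#' content when `sequenceScope = "genome"`.  Deterministic given the
#' configuration seed.
#'
#' @param config a [simulationConfig()].
#' @return a list with `genes` (annotation `data.frame` as from
#'   [readGeneAnnotation()]), `chromLengths` (named integer) and `seqs`
#'   (`DNAStringSet` or `NULL` outside genome scope).
#' @export
simulateGenome <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  chroms <- sprintf("chr%d", seq_len(config$nChroms))
  chromLengths <- stats::setNames(rep(config$chromLength, config$nChroms),
                                  chroms)
  margin <- 50000L
  genesPerChrom <- ceiling(config$nGenes / config$nChroms)
  span <- config$chromLength - 2L * margin - config$geneLength - 25000L
  spacing <- if (genesPerChrom > 1L)
    floor(span / (genesPerChrom - 1L)) else span
  if (span <= 0L || spacing < 30000L)
    stop("genes do not fit the chromosome: grid spacing would be ",
         max(spacing, 0L), " bp (< 30 kb)")
  i <- seq_len(config$nGenes)
  chromOf <- chroms[(i - 1L) %% config$nChroms + 1L]
  slot <- (i - 1L) %/% config$nChroms
  txStart <- margin + slot * spacing
  set.seed(stageSeed(config$seed, "genome"))
  strand <- sample(c("+", "-"), config$nGenes, replace = TRUE)
  nTF <- floor(config$tfFraction * config$nGenes)
  isTF <- rep(FALSE, config$nGenes)
  if (nTF > 0L)
    isTF[unique(round(seq(1L, config$nGenes, length.out = nTF)))] <- TRUE
  genes <- data.frame(
    geneId = sprintf("G%04d", i), chrom = chromOf, strand = strand,
    txStart = as.integer(txStart),
    txEnd = as.integer(txStart + config$geneLength),
    tss = ifelse(strand == "+", as.integer(txStart),
                 as.integer(txStart + config$geneLength) - 1L),
    isTF = isTF, stringsAsFactors = FALSE)
  seqs <- NULL
  if (config$sequenceScope == "genome") {
    set.seed(stageSeed(config$seed, "sequence"))
    seqs <- Biostrings::DNAStringSet(vapply(chroms, function(ch)
      randomDNA(config$chromLength, config$gc), character(1L)))
    names(seqs) <- chroms
  }
  list(genes = genes, chromLengths = chromLengths, seqs = seqs)
}

# i.i.d. DNA with the given GC content, as a single string.
randomDNA <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  idx <- sample.int(4L, n, replace = TRUE, prob = p)
  rawToChar(charToRaw("ACGT")[idx])
}
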