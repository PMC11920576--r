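#' Stitch constituent enhancers into candidate regions
#'
#' ROSE-style stitching: peaks lying within `tssExclusion` bp of an annotated
#' transcription start site are omitted from stitching and kept as standalone
#' single-constituent regions; the remaining peaks are merged transitively
#' whenever the gap between consecutive peaks (next start minus previous end)
#' is at most `stitchDistance` bp.  Overlapping peaks always merge.
#'
#' @param peaks `GRanges` of enhancer peaks as returned by [readPeaks()].
#' @param genes gene annotation `data.frame` from [readGeneAnnotation()] (its
#'   0-based `tss` column defines the exclusion windows); may be `NULL` for
#'   no exclusion.
#' @param stitchDistance maximum stitched gap in bp (default 12500).
#' @param tssExclusion half-width of the TSS window in bp (default 2500); a
#'   peak intersecting `[tss - tssExclusion, tss + tssExclusion]` is
#'   excluded from stitching.
#' @return a `GRanges` of stitched regions sorted by position, with metadata
#'   columns `regionId`, `excluded`, `nConstituents`, `sampleSignal`,
#'   `inputSignal`, and a `GRangesList` of constituents in
#'   `metadata(...)$constituents`.
#' @export
stitchEnhancers <- function(peaks, genes, stitchDistance = 12500,
                            tssExclusion = 2500) {
  if (stitchDistance < 0) stop("stitchDistance must be >= 0")
  if (tssExclusion < 0) stop("tssExclusion must be >= 0")
  stopifnot(is(peaks, "GRanges"))
  peaks <- sortPeaks(peaks)
  n <- length(peaks)
  excluded <- rep(FALSE, n)
  if (!is.null(genes) && nrow(genes) && n) {
    # tss is 0-based; the window [tss - e, tss + e] is closed in 0-based
    # base coordinates, i.e. 1-based [tss - e + 1, tss + e + 1].
    win <- GRanges(genes$chrom,
                   IRanges(pmax(genes$tss - tssExclusion, 0L) + 1L,
                           genes$tss + tssExclusion + 1L))
    # peaks and annotation may legitimately cover different chromosomes
    excluded <- suppressWarnings(overlapsAny(peaks, win))
  }
  keep <- peaks[!excluded]
  merged <- reduce(keep, min.gapwidth = stitchDistance + 1L,
                   ignore.strand = TRUE)
  regions <- suppressWarnings(c(merged, granges(peaks[excluded])))
  isExcl <- rep(c(FALSE, TRUE), c(length(merged), sum(excluded)))
  ord <- order(as.character(seqnames(regions)), start(regions),
               end(regions), isExcl, method = "radix")
  regions <- regions[ord]
  isExcl <- isExcl[ord]

  # map constituents back onto their regions (within exclusion class)
  constIdx <- vector("list", length(regions))
  hitsM <- findOverlaps(peaks[!excluded], regions[!isExcl])
  mIdx <- which(!isExcl)
  for (k in seq_along(mIdx)) constIdx[[mIdx[k]]] <- integer()
  pkIdx <- which(!excluded)
  byRegion <- split(pkIdx[S4Vectors::queryHits(hitsM)],
                    S4Vectors::subjectHits(hitsM))
  for (nm in names(byRegion)) {
    constIdx[[mIdx[as.integer(nm)]]] <- sort(byRegion[[nm]])
  }
  exIdx <- which(isExcl)
  exPk <- which(excluded)
  # excluded regions were appended in peak order, then re-sorted jointly;
  # match them back by coordinates + order of equal keys
  if (length(exIdx)) {
    keyR <- paste(as.character(seqnames(regions[exIdx])),
                  start(regions[exIdx]), end(regions[exIdx]))
    keyP <- paste(as.character(seqnames(peaks[exPk])),
                  start(peaks[exPk]), end(peaks[exPk]))
    used <- logical(length(exPk))
    for (k in seq_along(exIdx)) {
      j <- which(keyP == keyR[k] & !used)[1L]
      used[j] <- TRUE
      constIdx[[exIdx[k]]] <- exPk[j]
    }
  }
  constituents <- GRangesList(lapply(constIdx, function(i) peaks[i]))
  mcols(regions) <- DataFrame(
    regionId = sprintf("region_%05d", seq_along(regions)),
    excluded = isExcl,
    nConstituents = lengths(constIdx),
    sampleSignal = vapply(constIdx, function(i)
      sum(mcols(peaks)$sampleSignal[i]), numeric(1L)),
    inputSignal = vapply(constIdx, function(i)
      sum(mcols(peaks)$inputSignal[i]), numeric(1L)))
  S4Vectors::metadata(regions)$constituents <- constituents
  S4Vectors::metadata(regions)$stitchDistance <- stitchDistance
  S4Vectors::metadata(regions)$tssExclusion <- tssExclusion
  regions
}

#' @importFrom IRanges overlapsAny
NULL

#' Rank stitched enhancers by input-subtracted signal
#'
#' Scores each stitched region as
#' `max(0, sum(sampleSignal) - sum(inputSignal))` over its constituents
#' (negative totals are noise and clamp to zero) and ranks regions by
#' descending score; ties are broken by `(chrom, start)` so the ranking is
#' stable and deterministic.
#'
#' @param stitched output of [stitchEnhancers()].
#' @return a [RankedEnhancerTable].
#' @export
rankEnhancers <- function(stitched) {
  stopifnot(is(stitched, "GRanges"))
  md <- S4Vectors::metadata(stitched)
  score <- pmax(0, mcols(stitched)$sampleSignal -
                     mcols(stitched)$inputSignal)
  ord <- order(-score, as.character(seqnames(stitched)), start(stitched),
               method = "radix")
  rank <- integer(length(score))
  rank[ord] <- seq_along(ord)
  mcols(stitched)$score <- score
  mcols(stitched)$rank <- rank
  new("RankedEnhancerTable", regions = stitched,
      constituents = if (!is.null(md$constituents)) md$constituents
                     else GRangesList(lapply(seq_along(stitched),
                                             function(i) stitched[i])),
      stitchDistance = md$stitchDistance %||% NA_real_,
      tssExclusion = md$tssExclusion %||% NA_real_,
      tableId = tableDigest(score))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Locate the super-enhancer cutoff at the rank-curve inflection point
#'
#' With scores in ascending order `s_1 <= ... <= s_n`, both axes are scaled
#' to the unit square (`x_i = (i-1)/(n-1)`, `y_i = (s_i - s_1)/(s_n - s_1)`)
#' and the cutoff index is `argmin_i (y_i - x_i)`, ties resolved to the
#' largest index (fewest super-enhancers).  This is the discrete point where
#' a slope-1 tangent touches the scaled convex curve; entries scoring
#' strictly above the cutoff score are super-enhancers.  Degenerate inputs
#' (fewer than 3 entries, or constant scores) yield a cutoff with
#' `nSuper = 0` and a warning.
#'
#' @param ranked a [RankedEnhancerTable] (or bare numeric score vector).
#' @return a [SECutoff].
#' @export
findSECutoff <- function(ranked) {
  scores <- if (is(ranked, "RankedEnhancerTable")) enhancerScores(ranked)
            else as.numeric(ranked)
  id <- tableDigest(scores)
  n <- length(scores)
  s <- sort(scores)
  if (n < 3L || s[n] == s[1L]) {
    warning("degenerate score vector (n < 3 or constant): no ",
            "super-enhancers called")
    return(new("SECutoff", cutoffScore = if (n) s[n] else NA_real_,
               cutoffIndex = n, nSuper = 0L, degenerate = TRUE,
               tableId = id))
  }
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s - s[1L]) / (s[n] - s[1L])
  d <- y - x
  i <- max(which(d == min(d)))
  cut <- s[i]
  new("SECutoff", cutoffScore = cut, cutoffIndex = i,
      nSuper = sum(scores > cut), degenerate = FALSE, tableId = id)
}

#' Classify super-enhancers against a cutoff
#'
#' Flags every entry of the ranked table with `isSuper = score > cutoff`.
#' The cutoff must have been computed from the same table (provenance is
#' checked); the flagged count always equals `nSuper(cutoff)` and flagged
#' rows outrank all unflagged rows.
#'
#' @param ranked a [RankedEnhancerTable].
#' @param cutoff the matching [SECutoff].
#' @return the [RankedEnhancerTable] with an `isSuper` metadata column; the
#'   super-enhancer regions are available via [superEnhancers()].
#' @export
classifySuperEnhancers <- function(ranked, cutoff) {
  stopifnot(is(ranked, "RankedEnhancerTable"), is(cutoff, "SECutoff"))
  if (!identical(ranked@tableId, cutoff@tableId))
    stop("cutoff was not computed from this ranked table")
  flag <- if (cutoff@degenerate) rep(FALSE, length(ranked))
          else enhancerScores(ranked) > cutoff@cutoffScore
  mcols(ranked@regions)$isSuper <- flag
  stopifnot(sum(flag) == cutoff@nSuper)
  ranked
}

#' Assign each super-enhancer to its nearest gene
#'
#' Links every region to the gene minimising the absolute distance between
#' the region midpoint (`floor((start + end) / 2)` in 0-based half-open
#' coordinates) and the gene TSS, considering genes on the same chromosome
#' only.  Ties go to the smaller TSS coordinate, then to the
#' lexicographically smaller gene identifier.  Regions on chromosomes absent
#' from the annotation are reported unassigned (`NA`).
#'
#' @param se a `GRanges` of regions (e.g. [superEnhancers()] output) with a
#'   `regionId` metadata column, or a [RankedEnhancerTable] whose classified
#'   super-enhancers are then used.
#' @param genes gene annotation `data.frame` from [readGeneAnnotation()].
#' @return a `data.frame` with columns `seId`, `geneId`, `distance` (signed,
#'   `tss - midpoint`, in bp).
#' @export
assignNearestGene <- function(se, genes) {
  if (is(se, "RankedEnhancerTable")) se <- superEnhancers(se)
  stopifnot(is(se, "GRanges"))
  n <- length(se)
  seId <- mcols(se)$regionId %||% sprintf("region_%05d", seq_len(n))
  out <- data.frame(seId = seId, geneId = NA_character_,
                    distance = NA_integer_, stringsAsFactors = FALSE)
  if (!n || is.null(genes) || !nrow(genes)) return(out)
  # 0-based midpoint: floor((start0 + end0)/2) = floor((start-1 + end)/2)
  mid <- floor((start(se) - 1 + end(se)) / 2)
  chr <- as.character(seqnames(se))
  for (i in seq_len(n)) {
    g <- genes[genes$chrom == chr[i], , drop = FALSE]
    if (!nrow(g)) next
    d <- g$tss - mid[i]
    best <- which(abs(d) == min(abs(d)))
    if (length(best) > 1L) {
      best <- best[order(g$tss[best], g$geneId[best], method = "radix")][1L]
    }
    out$geneId[i] <- g$geneId[best]
    out$distance[i] <- as.integer(d[best])
  }
  out
}

#' Run the full super-enhancer caller
#'
#' Convenience wrapper chaining [stitchEnhancers()], [rankEnhancers()],
#' [findSECutoff()], [classifySuperEnhancers()] and [assignNearestGene()].
#'
#' @inheritParams stitchEnhancers
#' @return a list with elements `ranked` ([RankedEnhancerTable], classified),
#'   `cutoff` ([SECutoff]) and `assignment` (`data.frame`).
#' @export
callSuperEnhancers <- function(peaks, genes, stitchDistance = 12500,
                               tssExclusion = 2500) {
  stitched <- stitchEnhancers(peaks, genes, stitchDistance, tssExclusion)
  ranked <- rankEnhancers(stitched)
  cutoff <- suppressWarnings(findSECutoff(ranked))
  ranked <- classifySuperEnhancers(ranked, cutoff)
  assignment <- assignNearestGene(ranked, genes)
  list(ranked = ranked, cutoff = cutoff, assignment = assignment)
}
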