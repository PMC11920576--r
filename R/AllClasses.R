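#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges GRangesList seqnames start end width
#'   findOverlaps reduce granges
#' @importFrom IRanges IRanges
NULL

#' Position weight matrix for a transcription factor motif
#'
#' A `PWMotif` holds per-position base probabilities over A/C/G/T for one
#' transcription factor.  Columns are motif positions; each column sums to 1
#' after pseudocount regularisation, so log-odds scores against any strictly
#' positive background are finite.
#'
#' @slot tfName single character, the transcription factor the motif belongs to.
#' @slot matrix numeric matrix, 4 x L with rownames `c("A","C","G","T")`,
#'   columns summing to 1.
#' @slot pseudocount the pseudocount used during normalisation.
#'
#' @seealso [pwMotif()], [readMotifLibrary()], [pwmThresholdScore()]
#' @export
setClass("PWMotif",
  representation(tfName = "character", matrix = "matrix",
                 pseudocount = "numeric"))

setValidity("PWMotif", function(object) {
  m <- object@matrix
  if (length(object@tfName) != 1L || is.na(object@tfName) ||
      !nzchar(object@tfName))
    return("tfName must be a single non-empty string")
  if (!is.numeric(m) || nrow(m) != 4L || ncol(m) < 1L)
    return("matrix must be numeric with 4 rows (A,C,G,T) and >= 1 column")
  if (!identical(rownames(m), c("A", "C", "G", "T")))
    return("matrix rownames must be A, C, G, T")
  if (any(m < 0)) return("matrix entries must be non-negative")
  if (any(abs(colSums(m) - 1) > 1e-9))
    return("each matrix column must sum to 1 (within 1e-9)")
  TRUE
})

#' Ranked table of stitched enhancers
#'
#' Container for the output of [stitchEnhancers()] after scoring and ranking
#' with [rankEnhancers()].  Regions carry the input-subtracted H3K27ac score
#' (clamped at zero), their rank (1 = highest score), the TSS-exclusion flag,
#' and, once [classifySuperEnhancers()] has been applied, the `isSuper` flag.
#'
#' @slot regions `GRanges` of stitched regions with metadata columns
#'   `regionId`, `excluded`, `nConstituents`, `sampleSignal`, `inputSignal`,
#'   `score`, `rank` and (after classification) `isSuper`.
#' @slot constituents `GRangesList` parallel to `regions`, the constituent
#'   peaks of each region.
#' @slot stitchDistance maximum gap (bp) merged during stitching.
#' @slot tssExclusion half-width (bp) of the TSS window excluded from
#'   stitching.
#' @slot tableId opaque identifier tying a [SECutoff] to the table it was
#'   computed from.
#' @export
setClass("RankedEnhancerTable",
  representation(regions = "GRanges", constituents = "GRangesList",
                 stitchDistance = "numeric", tssExclusion = "numeric",
                 tableId = "character"))

setValidity("RankedEnhancerTable", function(object) {
  mc <- mcols(object@regions)
  need <- c("regionId", "excluded", "nConstituents", "sampleSignal",
            "inputSignal", "score", "rank")
  if (!all(need %in% colnames(mc)))
    return(paste("regions must carry metadata columns:",
                 paste(need, collapse = ", ")))
  if (length(object@constituents) != length(object@regions))
    return("constituents must be parallel to regions")
  if (length(object@regions)) {
    if (any(mc$score < 0)) return("scores must be >= 0")
    if (!setequal(mc$rank, seq_along(object@regions)))
      return("ranks must be a permutation of 1..n")
    s <- mc$score[order(mc$rank)]
    if (is.unsorted(rev(s))) return("scores must be non-increasing in rank")
  }
  TRUE
})

#' Super-enhancer cutoff at the rank-curve inflection point
#'
#' The discrete slope-1 tangent point of the 0-1 scaled rank-vs-signal curve,
#' as located by [findSECutoff()].  Entries with score strictly greater than
#' `cutoffScore` are super-enhancers.
#'
#' @slot cutoffScore score at the inflection point.
#' @slot cutoffIndex index of the inflection point with scores in ascending
#'   order.
#' @slot nSuper number of entries with score > `cutoffScore`.
#' @slot degenerate `TRUE` when the input was degenerate (fewer than 3 entries
#'   or constant scores); then `nSuper` is 0.
#' @slot tableId identifier of the [RankedEnhancerTable] the cutoff was
#'   computed from.
#' @export
setClass("SECutoff",
  representation(cutoffScore = "numeric", cutoffIndex = "integer",
                 nSuper = "integer", degenerate = "logical",
                 tableId = "character"))

setValidity("SECutoff", function(object) {
  if (object@nSuper < 0L) return("nSuper must be >= 0")
  if (object@degenerate && object@nSuper != 0L)
    return("degenerate cutoffs must have nSuper == 0")
  TRUE
})

#' Directed binding graph of self-regulating transcription factors
#'
#' Nodes are self-regulating TFs; a directed edge A -> B records that A's
#' motif passes the instance rule in B's super-enhancer constituents.  Every
#' node carries its implied self-loop.  Degree accessors exclude self-loops,
#' which is also how the degree table is reported.
#'
#' @slot nodes character vector of TF names.
#' @slot edges `data.frame` with columns `from`, `to`, `nHits`.
#' @slot minInstances the instance threshold used to admit edges.
#' @export
setClass("CircuitGraph",
  representation(nodes = "character", edges = "data.frame",
                 minInstances = "numeric"))

setValidity("CircuitGraph", function(object) {
  e <- object@edges
  if (!all(c("from", "to", "nHits") %in% colnames(e)))
    return("edges must have columns from, to, nHits")
  if (length(object@nodes) &&
      !all(c(e$from, e$to) %in% object@nodes))
    return("edge endpoints must be graph nodes")
  if (length(object@nodes) &&
      !all(object@nodes %in% e$from[e$from == e$to]))
    return("every node must carry its self-loop")
  TRUE
})
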