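# Accessors and show methods for the S4 containers.

#' @rdname secircuit-generics
#' @export
setMethod("tfName", "PWMotif", function(object, ...) object@tfName)

#' @rdname secircuit-generics
#' @export
setMethod("motifMatrix", "PWMotif", function(object, ...) object@matrix)

#' @describeIn PWMotif motif width (number of positions).
#' @param x a `PWMotif`.
#' @export
setMethod("length", "PWMotif", function(x) ncol(x@matrix))

setMethod("show", "PWMotif", function(object) {
  cat("PWMotif for", object@tfName, "- width", ncol(object@matrix), "\n")
  cat("consensus:", pwmConsensus(object), "\n")
})

#' @rdname secircuit-generics
#' @export
setMethod("enhancerRegions", "RankedEnhancerTable",
          function(object, ...) object@regions)

#' @rdname secircuit-generics
#' @export
setMethod("constituents", "RankedEnhancerTable",
          function(object, ...) object@constituents)

#' @rdname secircuit-generics
#' @export
setMethod("enhancerScores", "RankedEnhancerTable",
          function(object, ...) mcols(object@regions)$score)

#' @describeIn RankedEnhancerTable number of stitched regions.
#' @param x a `RankedEnhancerTable`.
#' @export
setMethod("length", "RankedEnhancerTable", function(x) length(x@regions))

#' @describeIn RankedEnhancerTable export the ranked table as a
#'   `data.frame` with 0-based half-open coordinates, sorted by rank.
#' @param row.names,optional,... as for [base::as.data.frame()].
#' @export
setMethod("as.data.frame", "RankedEnhancerTable",
  function(x, row.names = NULL, optional = FALSE, ...) {
    gr <- x@regions
    df <- data.frame(
      regionId = mcols(gr)$regionId,
      chrom = as.character(seqnames(gr)),
      start = start(gr) - 1L,
      end = end(gr),
      nConstituents = mcols(gr)$nConstituents,
      excluded = mcols(gr)$excluded,
      sampleSignal = mcols(gr)$sampleSignal,
      inputSignal = mcols(gr)$inputSignal,
      score = mcols(gr)$score,
      rank = mcols(gr)$rank,
      stringsAsFactors = FALSE)
    if (!is.null(mcols(gr)$isSuper)) df$isSuper <- mcols(gr)$isSuper
    df[order(df$rank), , drop = FALSE]
  })

#' @rdname secircuit-generics
#' @export
setMethod("superEnhancers", "RankedEnhancerTable", function(object, ...) {
  if (is.null(mcols(object@regions)$isSuper))
    stop("table has not been classified; run classifySuperEnhancers() first")
  object@regions[mcols(object@regions)$isSuper]
})

setMethod("show", "RankedEnhancerTable", function(object) {
  cat("RankedEnhancerTable with", length(object@regions),
      "stitched regions\n")
  cat("  stitch distance:", object@stitchDistance,
      "bp; TSS exclusion: +/-", object@tssExclusion, "bp\n")
  if (!is.null(mcols(object@regions)$isSuper))
    cat("  classified:", sum(mcols(object@regions)$isSuper),
        "super-enhancers\n")
})

#' @rdname secircuit-generics
#' @export
setMethod("cutoffScore", "SECutoff", function(object, ...) object@cutoffScore)

#' @rdname secircuit-generics
#' @export
setMethod("nSuper", "SECutoff", function(object, ...) object@nSuper)

#' @rdname secircuit-generics
#' @export
setMethod("isDegenerate", "SECutoff",
          function(object, ...) object@degenerate)

setMethod("show", "SECutoff", function(object) {
  if (object@degenerate) {
    cat("SECutoff (degenerate input): 0 super-enhancers\n")
  } else {
    cat("SECutoff: score", format(object@cutoffScore),
        "at ascending index", object@cutoffIndex, "->",
        object@nSuper, "super-enhancers\n")
  }
})

#' @rdname secircuit-generics
#' @export
setMethod("graphNodes", "CircuitGraph", function(object, ...) object@nodes)

#' @rdname secircuit-generics
#' @export
setMethod("graphEdges", "CircuitGraph", function(object, ...) object@edges)

#' @rdname secircuit-generics
#' @export
setMethod("inDegree", "CircuitGraph", function(object, ...) {
  e <- object@edges[object@edges$from != object@edges$to, , drop = FALSE]
  tab <- table(factor(e$to, levels = object@nodes))
  stats::setNames(as.integer(tab), object@nodes)
})

#' @rdname secircuit-generics
#' @export
setMethod("outDegree", "CircuitGraph", function(object, ...) {
  e <- object@edges[object@edges$from != object@edges$to, , drop = FALSE]
  tab <- table(factor(e$from, levels = object@nodes))
  stats::setNames(as.integer(tab), object@nodes)
})

setMethod("show", "CircuitGraph", function(object) {
  nself <- sum(object@edges$from == object@edges$to)
  cat("CircuitGraph:", length(object@nodes), "self-regulating TFs,",
      nrow(object@edges) - nself, "cross-regulatory edges\n")
})
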