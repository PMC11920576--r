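#' Compare super-enhancer gene sets between conditions
#'
#' Set logic between the SE-associated gene sets of two conditions (the
#' pre-treatment "model" condition and the treated "ea" condition):
#' `lost = model \\ ea` (SEs lost after treatment), `gained = ea \\ model`,
#' `shared = model` intersect `ea`.  The three sets are pairwise disjoint and
#' partition the two inputs (`lost + shared = model`,
#' `gained + shared = ea`).
#'
#' @param modelGenes character vector of SE-associated gene ids in the model
#'   condition (or an [assignNearestGene()] result, whose non-`NA` `geneId`
#'   column is used).
#' @param eaGenes same for the treated condition.
#' @return an object of class `DiffSESets`: a list with sorted character
#'   vectors `gained`, `lost`, `shared` and a `counts` element.
#' @export
#' @examples
#' diffSEGenes(c("a", "b", "c"), c("c", "d"))
diffSEGenes <- function(modelGenes, eaGenes) {
  asGenes <- function(x) {
    if (is.data.frame(x)) x <- x$geneId
    sort(unique(x[!is.na(x)]), method = "radix")
  }
  m <- asGenes(modelGenes)
  e <- asGenes(eaGenes)
  out <- list(gained = setdiff(e, m), lost = setdiff(m, e),
              shared = intersect(m, e))
  out$counts <- c(model = length(m), ea = length(e),
                  gained = length(out$gained), lost = length(out$lost),
                  shared = length(out$shared))
  class(out) <- "DiffSESets"
  out
}

#' @export
print.DiffSESets <- function(x, ...) {
  cat("Differential SE gene sets: lost", x$counts[["lost"]],
      "| gained", x$counts[["gained"]],
      "| shared", x$counts[["shared"]], "\n")
  invisible(x)
}

#' Split a DEG table into direction sets
#'
#' Applies the significance contract `qvalue <= qMax` with a strict
#' fold-change direction: `up` requires `log2fc > lfcMin`, `down` requires
#' `log2fc < -lfcMin`.  With the default `lfcMin = 0`, direction is by sign
#' only and genes with `log2fc == 0` fall in neither set.  Records with
#' non-finite `log2fc` are skipped with a warning.
#'
#' @param deg DEG `data.frame` from [readDegTable()].
#' @param qMax adjusted-p cutoff (default 0.05).
#' @param lfcMin minimum absolute log2 fold change, strict (default 0).
#' @return a list with sorted character vectors `up` and `down`.
#' @export
filterDEGs <- function(deg, qMax = 0.05, lfcMin = 0) {
  checkScalar(qMax, "qMax", 0, 1)
  checkScalar(lfcMin, "lfcMin", 0)
  bad <- !is.finite(deg$log2fc)
  if (any(bad)) {
    warning(sum(bad), " DEG record(s) with non-finite log2fc skipped")
    deg <- deg[!bad, , drop = FALSE]
  }
  sig <- !is.na(deg$qvalue) & deg$qvalue <= qMax
  list(up = sort(unique(deg$geneId[sig & deg$log2fc > lfcMin]),
                 method = "radix"),
       down = sort(unique(deg$geneId[sig & deg$log2fc < -lfcMin]),
                   method = "radix"))
}

#' Intersect differential SE gene sets with DEG direction sets
#'
#' The candidate-gene step: intersects a differential SE gene set with a DEG
#' direction set under one of two rules.  The DEG table is interpreted as the
#' model-vs-treatment contrast, so `up` genes are up-regulated in the model
#' condition and `down` genes are up-regulated after treatment.
#' \describe{
#'   \item{`lost_up_model`}{genes of SEs lost after treatment that are
#'     up-regulated in the model condition (`lost` x `up`).}
#'   \item{`gained_up_ea`}{genes of SEs gained after treatment that are
#'     up-regulated after treatment (`gained` x `down`).}
#' }
#' An empty intersection is a valid result.
#'
#' @param diff a `DiffSESets` from [diffSEGenes()].
#' @param degSets DEG direction sets from [filterDEGs()].
#' @param rule `"lost_up_model"` or `"gained_up_ea"`.
#' @return a character vector of candidate gene ids (sorted) with a
#'   `provenance` attribute recording the rule and parent set sizes.
#' @export
intersectCandidates <- function(diff, degSets,
                                rule = c("lost_up_model", "gained_up_ea")) {
  rule <- match.arg(rule)
  stopifnot(inherits(diff, "DiffSESets"),
            is.list(degSets), all(c("up", "down") %in% names(degSets)))
  se <- if (rule == "lost_up_model") diff$lost else diff$gained
  dg <- if (rule == "lost_up_model") degSets$up else degSets$down
  out <- sort(intersect(se, dg), method = "radix")
  attr(out, "provenance") <- list(rule = rule, nSE = length(se),
                                  nDEG = length(dg))
  out
}
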