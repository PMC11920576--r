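#' Over-representation analysis of a gene list against gene sets
#'
#' One-sided hypergeometric upper-tail test per gene set: with a universe of
#' `N` genes, a set of `K`, a query of `n` and an overlap of `k`, the
#' p-value is `P[X >= k]` for `X ~ Hypergeom(N, K, n)`.  Gene sets are
#' intersected with the universe before testing; p-values are adjusted
#' across the tested sets by Benjamini-Hochberg.  The raw-p rule
#' (`p <= alpha`) provides the default significance flag; the BH flag is
#' reported alongside.
#'
#' @param queryGenes character vector of query gene ids (must be a subset of
#'   the universe).
#' @param geneSets named list of character vectors (e.g. from
#'   [readGeneSets()]).
#' @param universe character vector of background gene ids.
#' @param alpha significance level on the raw p (default 0.05).
#' @return a `data.frame` with columns `set`, `k`, `K`, `n`, `N`, `pvalue`,
#'   `qvalue`, `significant`, `significantBH`, sorted by p then set name.
#' @export
#' @examples
#' oraTest(c("g1", "g2"), list(s = paste0("g", 1:5)), paste0("g", 1:10))
oraTest <- function(queryGenes, geneSets, universe, alpha = 0.05) {
  checkScalar(alpha, "alpha", 0, 1)
  universe <- unique(universe)
  queryGenes <- unique(queryGenes)
  if (!length(universe)) stop("empty universe")
  if (!length(queryGenes)) stop("empty query")
  if (!all(queryGenes %in% universe))
    stop("query genes outside the universe: ",
         paste(utils::head(setdiff(queryGenes, universe), 3L),
               collapse = ", "))
  N <- length(universe)
  n <- length(queryGenes)
  rows <- lapply(names(geneSets), function(nm) {
    set <- intersect(unique(geneSets[[nm]]), universe)
    K <- length(set)
    k <- length(intersect(set, queryGenes))
    p <- if (k == 0L) 1 else
      stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = N, pvalue = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$qvalue <- stats::p.adjust(out$pvalue, method = "BH")
  out$significant <- out$pvalue <= alpha
  out$significantBH <- out$qvalue <= alpha
  out[order(out$pvalue, out$set, method = "radix"), , drop = FALSE]
}
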