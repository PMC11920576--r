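#' Select the forest size from the out-of-bag error curve
#'
#' Grows a single classification forest of `maxTrees` trees (features =
#' genes, classes = sample group labels) with a fixed seed and records the
#' cumulative out-of-bag error of the forests of size 1..`maxTrees`.  The
#' chosen size is the smallest tree count attaining the minimum error (the
#' cheapest adequate forest).
#'
#' @param expr genes x samples expression matrix (FPKM).
#' @param labels group label per sample (character or factor, length =
#'   `ncol(expr)`); every class needs at least 2 samples.
#' @param maxTrees error curve length (default 500).
#' @param seed integer seed.
#' @return a list of class `NtreeSelection` with `errorByNtree` (numeric,
#'   length `maxTrees`) and `chosenNtree`.
#' @export
selectNtree <- function(expr, labels, maxTrees = 500, seed = 1) {
  checkExpr(expr, labels)
  checkScalar(maxTrees, "maxTrees", min = 1)
  set.seed(seed)
  rf <- randomForest::randomForest(x = t(expr), y = factor(labels),
                                   ntree = maxTrees)
  err <- as.numeric(rf$err.rate[, "OOB"])
  chosen <- which(err == min(err))[1L]
  structure(list(errorByNtree = err, chosenNtree = as.integer(chosen)),
            class = "NtreeSelection")
}

#' @export
print.NtreeSelection <- function(x, ...) {
  cat("NtreeSelection: minimum OOB error",
      format(min(x$errorByNtree), digits = 4), "first attained at",
      x$chosenNtree, "trees\n")
  invisible(x)
}

checkExpr <- function(expr, labels) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("expr must be a numeric genes x samples matrix")
  if (any(expr < 0)) stop("expression values must be >= 0")
  if (length(labels) != ncol(expr))
    stop("labels must have one entry per sample (column)")
  tab <- table(labels)
  if (length(tab) < 2L) stop("at least two groups are required")
  if (any(tab < 2L))
    stop("every class needs >= 2 samples; offending class: ",
         names(tab)[which(tab < 2L)[1L]])
  invisible(TRUE)
}

#' Rank genes by mean decrease in Gini importance
#'
#' Fits a Gini-impurity random-forest classifier (features per split =
#' `floor(sqrt(p))`, unlimited depth — the conventional classifier defaults)
#' and ranks genes by descending mean decrease in Gini (MDG).  Ties are
#' broken lexicographically.  Constant features get MDG 0 and are retained.
#'
#' @param expr genes x samples expression matrix.
#' @param labels group label per sample.
#' @param ntree forest size, typically `chosenNtree` from [selectNtree()].
#' @param seed integer seed.
#' @return a `data.frame` with columns `geneId`, `mdg`, `rank`, sorted by
#'   rank.
#' @export
rankGenesGini <- function(expr, labels, ntree = 500, seed = 1) {
  checkExpr(expr, labels)
  set.seed(seed)
  rf <- randomForest::randomForest(x = t(expr), y = factor(labels),
                                   ntree = ntree)
  mdg <- rf$importance[, "MeanDecreaseGini"]
  ord <- order(-mdg, rownames(expr), method = "radix")
  data.frame(geneId = rownames(expr)[ord], mdg = as.numeric(mdg[ord]),
             rank = seq_along(ord), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Wang graph-based similarity between two ontology terms
#'
#' Wang's measure: each term's semantic value spreads to its ancestors with
#' multiplicative edge weights (`is_a` 0.8, `part_of` 0.6, the conventional
#' defaults), keeping the best path (`S_A(A) = 1`,
#' `S_A(t) = max over child edges w_e * S_A(child)`), and two terms are
#' compared through their shared ancestors:
#' `sim = sum over shared (S_A + S_B) / (SV(A) + SV(B))`.
#'
#' @param termA,termB term identifiers.
#' @param dag ontology edge table: `data.frame` with columns `term`
#'   (child), `parent`, `type` (`"is_a"` or `"part_of"`).
#' @param weights named edge weights (default `c(is_a = 0.8, part_of =
#'   0.6)`).
#' @return similarity in \\[0, 1\\].
#' @export
termSimWang <- function(termA, termB, dag,
                        weights = c(is_a = 0.8, part_of = 0.6)) {
  sa <- wangSValues(termA, dag, weights)
  sb <- wangSValues(termB, dag, weights)
  shared <- intersect(names(sa), names(sb))
  if (!length(shared)) return(0)
  (sum(sa[shared]) + sum(sb[shared])) / (sum(sa) + sum(sb))
}

# S-values of a term over its ancestor closure (including itself).
wangSValues <- function(term, dag, weights) {
  s <- stats::setNames(1, term)
  frontier <- term
  while (length(frontier)) {
    hit <- dag[dag$term %in% frontier, , drop = FALSE]
    if (!nrow(hit)) break
    cand <- weights[hit$type] * s[hit$term]
    nxt <- character()
    for (k in seq_len(nrow(hit))) {
      p <- hit$parent[k]
      if (is.na(s[p]) || cand[k] > s[p]) {
        s[p] <- cand[k]
        nxt <- c(nxt, p)
      }
    }
    frontier <- unique(nxt)
  }
  s
}

#' Gene-gene semantic similarity by best-match average
#'
#' Combines term-term Wang similarities over two genes' annotation sets with
#' the best-match average: every term of each gene is matched to its best
#' counterpart and the matches are averaged over both directions.
#'
#' @param termsA,termsB character vectors of term ids annotating each gene.
#' @param dag ontology edge table (see [termSimWang()]).
#' @param weights edge weights.
#' @return similarity in \\[0, 1\\].
#' @export
geneSimBMA <- function(termsA, termsB, dag,
                       weights = c(is_a = 0.8, part_of = 0.6)) {
  termsA <- unique(termsA); termsB <- unique(termsB)
  if (!length(termsA) || !length(termsB)) return(NA_real_)
  m <- outer(termsA, termsB,
             Vectorize(function(a, b) termSimWang(a, b, dag, weights)))
  (sum(apply(m, 1L, max)) + sum(apply(m, 2L, max))) /
    (length(termsA) + length(termsB))
}

#' Rank genes by mean semantic similarity (Friends analysis)
#'
#' Computes the pairwise gene-gene similarity matrix (Wang term similarity
#' combined by best-match average) over the candidate genes and ranks each
#' gene by its mean similarity to all the others (self excluded); the genes
#' most functionally similar to the rest of the candidate set rank first.
#' Unannotated genes are excluded with a warning.
#'
#' @param annotations named list: gene id -> character vector of term ids.
#' @param dag ontology edge table (see [termSimWang()]).
#' @param weights edge weights.
#' @return a list of class `FriendsRanking` with `simMatrix` (symmetric,
#'   unit diagonal), `score` (named mean similarities) and `ranking`
#'   (`data.frame` with `geneId`, `meanSim`, `rank`).
#' @export
friendsRank <- function(annotations, dag,
                        weights = c(is_a = 0.8, part_of = 0.6)) {
  ann <- annotations[order(names(annotations), method = "radix")]
  empty <- lengths(ann) == 0L
  if (any(empty)) {
    warning("unannotated gene(s) excluded: ",
            paste(names(ann)[empty], collapse = ", "))
    ann <- ann[!empty]
  }
  genes <- names(ann)
  n <- length(genes)
  if (n < 2L) stop("need at least two annotated genes")
  badTerms <- setdiff(unique(unlist(ann)), unique(c(dag$term, dag$parent)))
  if (length(badTerms))
    stop("annotation uses term(s) absent from the DAG: ",
         paste(badTerms, collapse = ", "))
  m <- diag(1, n)
  dimnames(m) <- list(genes, genes)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    m[i, j] <- m[j, i] <- geneSimBMA(ann[[i]], ann[[j]], dag, weights)
  }
  score <- (rowSums(m) - 1) / (n - 1)  # mean over others; diagonal is 1
  ord <- order(-score, genes, method = "radix")
  structure(list(simMatrix = m,
                 score = score,
                 ranking = data.frame(geneId = genes[ord],
                                      meanSim = as.numeric(score[ord]),
                                      rank = seq_len(n),
                                      stringsAsFactors = FALSE)),
            class = "FriendsRanking")
}

#' @export
print.FriendsRanking <- function(x, ...) {
  cat("FriendsRanking over", nrow(x$ranking), "genes; top:",
      x$ranking$geneId[1L],
      sprintf("(mean similarity %.3f)\n", x$ranking$meanSim[1L]))
  invisible(x)
}

#' Intersect the top-k genes of both rankings
#'
#' The core-gene step: intersection of the top `k` genes by random-forest
#' Gini importance with the top `k` genes of the Friends ranking.  An empty
#' intersection is reported with a warning, not an error.
#'
#' @param rfRanking `data.frame` from [rankGenesGini()].
#' @param friendsRanking a `FriendsRanking` (or its `ranking`
#'   `data.frame`).
#' @param k list depth (default 3).
#' @return sorted character vector of core genes (possibly empty).
#' @export
coreGeneIntersection <- function(rfRanking, friendsRanking, k = 3) {
  if (inherits(friendsRanking, "FriendsRanking"))
    friendsRanking <- friendsRanking$ranking
  checkScalar(k, "k", min = 1)
  if (k > nrow(rfRanking) || k > nrow(friendsRanking))
    stop("k exceeds the number of ranked genes")
  topRF <- rfRanking$geneId[rfRanking$rank <= k]
  topFR <- friendsRanking$geneId[friendsRanking$rank <= k]
  out <- sort(intersect(topRF, topFR), method = "radix")
  if (!length(out)) warning("top-", k, " lists are disjoint")
  out
}
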