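#' Identify super-enhancer-assigned transcription factors
#'
#' Step one of the core regulatory circuitry (CRC) procedure: from the
#' SE-to-gene assignment, keep the assigned genes that are transcription
#' factors and have a motif available in the library.  A TF assigned to
#' several super-enhancers keeps all of them (flagged `multiSE`) and later
#' pools hits across them.  TFs without a motif are excluded with a warning
#' naming them.
#'
#' @param assignment `data.frame` from [assignNearestGene()].
#' @param genes gene annotation with `geneId` and `isTF` columns.
#' @param pwms named list of [PWMotif] objects keyed by TF name.
#' @return a `data.frame` with columns `tf`, `seId`, `multiSE`.
#' @export
identifySETFs <- function(assignment, genes, pwms) {
  stopifnot(is.data.frame(assignment), is.data.frame(genes))
  tfs <- genes$geneId[genes$isTF]
  hit <- assignment[!is.na(assignment$geneId) &
                      assignment$geneId %in% tfs, , drop = FALSE]
  noPWM <- setdiff(unique(hit$geneId), names(pwms))
  if (length(noPWM))
    warning("TF(s) without a motif excluded: ",
            paste(sort(noPWM), collapse = ", "))
  hit <- hit[hit$geneId %in% names(pwms), , drop = FALSE]
  if (!nrow(hit))
    return(data.frame(tf = character(), seId = character(),
                      multiSE = logical(), stringsAsFactors = FALSE))
  out <- data.frame(tf = hit$geneId, seId = hit$seId,
                    stringsAsFactors = FALSE)
  out$multiSE <- out$tf %in% out$tf[duplicated(out$tf)]
  out[order(out$tf, out$seId, method = "radix"), , drop = FALSE]
}

#' Detect self-regulating transcription factors
#'
#' A TF whose own super-enhancer constituents contain at least
#' `minInstances` instances of its own binding motif (pooled across all its
#' SEs) is self-regulating.
#'
#' @param candidates `data.frame` from [identifySETFs()].
#' @param hits motif hit table from [scanMotifs()].
#' @param minInstances minimum own-motif instance count (default 3).
#' @return a `data.frame` with columns `tf`, `seIds` (comma-joined),
#'   `ownMotifCount`, restricted to self-regulating TFs.
#' @export
detectSelfRegulating <- function(candidates, hits, minInstances = 3) {
  checkScalar(minInstances, "minInstances", min = 1)
  tfs <- unique(candidates$tf)
  rows <- lapply(tfs, function(tf) {
    ses <- candidates$seId[candidates$tf == tf]
    n <- sum(hits$tf == tf & hits$seId %in% ses)
    data.frame(tf = tf, seIds = paste(sort(ses), collapse = ","),
               ownMotifCount = n, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(tf = character(), seIds = character(),
                         ownMotifCount = integer(), stringsAsFactors = FALSE)
  out <- out[out$ownMotifCount >= minInstances, , drop = FALSE]
  out[order(out$tf, method = "radix"), , drop = FALSE]
}

#' Build the TF-to-SE binding digraph
#'
#' Directed edge `A -> B` when A's motif has at least `minInstances` hits in
#' B's super-enhancer constituents (the same instance criterion that defines
#' self-regulation; self-loops are present by construction).  Degrees
#' reported by [inDegree()] / [outDegree()] exclude self-loops.
#'
#' @param selfreg `data.frame` from [detectSelfRegulating()].
#' @param hits motif hit table from [scanMotifs()].
#' @param candidates `data.frame` from [identifySETFs()] giving each TF's
#'   SEs (needed to pool hits per target TF).
#' @param minInstances edge criterion (default 3).
#' @return a [CircuitGraph].
#' @export
buildTFGraph <- function(selfreg, hits, candidates, minInstances = 3) {
  checkScalar(minInstances, "minInstances", min = 1)
  nodes <- sort(selfreg$tf, method = "radix")
  seOf <- lapply(stats::setNames(nodes, nodes), function(tf)
    candidates$seId[candidates$tf == tf])
  edges <- list()
  for (a in nodes) for (b in nodes) {
    n <- sum(hits$tf == a & hits$seId %in% seOf[[b]])
    if (n >= minInstances)
      edges[[length(edges) + 1L]] <-
        data.frame(from = a, to = b, nHits = n, stringsAsFactors = FALSE)
  }
  e <- if (length(edges)) do.call(rbind, edges)
       else data.frame(from = character(), to = character(),
                       nHits = integer(), stringsAsFactors = FALSE)
  # self-loops are implied by the self-regulation rule with the same
  # criterion, so they are always present for the node set
  new("CircuitGraph", nodes = nodes, edges = e,
      minInstances = minInstances)
}

#' Degree table of a circuit graph
#'
#' In-degree (TFs binding a node's SE) and out-degree (SEs a node's TF
#' binds), self-loops excluded, sorted by descending total degree.
#'
#' @param graph a [CircuitGraph].
#' @return a `data.frame` with columns `tf`, `inDegree`, `outDegree`,
#'   `totalDegree`.
#' @export
degreeTable <- function(graph) {
  stopifnot(is(graph, "CircuitGraph"))
  ind <- inDegree(graph); outd <- outDegree(graph)
  df <- data.frame(tf = graphNodes(graph), inDegree = ind,
                   outDegree = outd, totalDegree = ind + outd,
                   stringsAsFactors = FALSE, row.names = NULL)
  df[order(-df$totalDegree, df$tf, method = "radix"), , drop = FALSE]
}

#' Enumerate fully interconnected self-regulating circuits
#'
#' A circuit is a set of at least two self-regulating TFs in which every
#' ordered pair is connected (`A -> B` and `B -> A` for all members).
#' All maximal such sets are the maximal cliques of the underlying graph
#' restricted to bidirectional edges, found by recursive Bron-Kerbosch
#' search with pivoting.  Output order is deterministic (members sorted
#' within a circuit; circuits sorted lexicographically).
#'
#' @param graph a [CircuitGraph].
#' @return a list of character vectors (circuit member sets).
#' @export
enumerateCircuits <- function(graph) {
  stopifnot(is(graph, "CircuitGraph"))
  nodes <- graphNodes(graph)
  n <- length(nodes)
  if (n < 2L) return(list())
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  e <- graphEdges(graph)
  e <- e[e$from != e$to, , drop = FALSE]
  adj[cbind(match(e$from, nodes), match(e$to, nodes))] <- TRUE
  und <- adj & t(adj)  # bidirectional pairs only
  cliques <- bronKerbosch(und)
  cliques <- Filter(function(cl) length(cl) >= 2L, cliques)
  out <- lapply(cliques, function(cl) sort(nodes[cl], method = "radix"))
  out[order(vapply(out, paste, character(1L), collapse = "\r"),
            method = "radix")]
}

# Bron-Kerbosch maximal clique enumeration with pivoting on a logical
# adjacency matrix (no self edges).  Returns integer index vectors.
bronKerbosch <- function(adj) {
  n <- nrow(adj)
  out <- list()
  recurse <- function(R, P, X) {
    if (!length(P) && !length(X)) {
      out[[length(out) + 1L]] <<- R
      return(invisible())
    }
    # pivot: vertex of P u X with most neighbours in P
    PX <- c(P, X)
    nb <- vapply(PX, function(u) sum(adj[u, P]), integer(1L))
    pivot <- PX[which.max(nb)]
    for (v in P[!adj[pivot, P]]) {
      Nv <- which(adj[v, ])
      recurse(c(R, v), intersect(P, Nv), intersect(X, Nv))
      P <- setdiff(P, v)
      X <- c(X, v)
    }
  }
  recurse(integer(), seq_len(n), integer())
  out
}

#' Score circuits and select the representative CRC
#'
#' Scores each circuit by the mean membership frequency of its members: with
#' `f(t)` the fraction of enumerated circuits containing TF `t`, a circuit's
#' score is `mean(f(member))`.  Circuits are ranked by descending score, ties
#' resolved to the larger circuit then lexicographically; the top circuit is
#' the representative core regulatory circuitry.
#'
#' @param circuits list of member sets from [enumerateCircuits()].
#' @return a list with `table` (a `data.frame` of members, size, score,
#'   rank) and `representative` (character vector of the top circuit's
#'   members), or empty results with a warning when no circuit exists.
#' @export
scoreCircuits <- function(circuits) {
  if (!length(circuits)) {
    warning("no fully interconnected circuits to score")
    return(list(table = data.frame(members = character(), size = integer(),
                                   score = numeric(), rank = integer(),
                                   stringsAsFactors = FALSE),
                representative = character()))
  }
  members <- unlist(circuits)
  freq <- table(members) / length(circuits)
  score <- vapply(circuits, function(cl) mean(freq[cl]), numeric(1L))
  size <- lengths(circuits)
  key <- vapply(circuits, paste, character(1L), collapse = ",")
  ord <- order(-score, -size, key, method = "radix")
  tab <- data.frame(members = key[ord], size = size[ord],
                    score = score[ord], rank = seq_along(ord),
                    stringsAsFactors = FALSE)
  list(table = tab, representative = circuits[[ord[1L]]])
}

#' Map the core regulatory circuitry from caller output
#'
#' Convenience wrapper for the five-step CRC procedure: SE-assigned TF
#' identification, motif scanning at an exact p-value threshold,
#' self-regulation detection, graph construction, circuit enumeration and
#' scoring.
#'
#' @param assignment SE-to-gene assignment (`data.frame`).
#' @param genes gene annotation `data.frame`.
#' @param pwms named list of [PWMotif].
#' @param sequences named `DNAStringSet` of SE constituent sequences.
#' @param seMap `data.frame` mapping sequence names to `(seId,
#'   constituent)`; see [scanMotifs()].
#' @param pThreshold motif p-value threshold (default `1e-4`).
#' @param minInstances instance rule for self-regulation and edges
#'   (default 3).
#' @param background background base frequencies.
#' @return a list with `candidates`, `hits`, `selfreg`, `graph`, `degrees`,
#'   `circuits`, `scores` (see the step functions).
#' @export
mapCRC <- function(assignment, genes, pwms, sequences, seMap = NULL,
                   pThreshold = 1e-4, minInstances = 3,
                   background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  candidates <- identifySETFs(assignment, genes, pwms)
  useSeqs <- sequences
  if (!is.null(seMap) && nrow(candidates)) {
    keep <- seMap$seId %in% candidates$seId
    useSeqs <- sequences[seMap$seqName[keep]]
    seMap <- seMap[keep, , drop = FALSE]
  }
  hits <- if (nrow(candidates) && length(useSeqs))
    scanMotifs(useSeqs, pwms[unique(candidates$tf)],
               pThreshold = pThreshold, background = background,
               seMap = seMap)
  else
    scanMotifs(Biostrings::DNAStringSet(), pwms[character()],
               pThreshold = pThreshold, background = background)
  selfreg <- detectSelfRegulating(candidates, hits, minInstances)
  graph <- buildTFGraph(selfreg, hits, candidates, minInstances)
  circuits <- enumerateCircuits(graph)
  scores <- if (length(circuits)) scoreCircuits(circuits)
            else suppressWarnings(scoreCircuits(circuits))
  list(candidates = candidates, hits = hits, selfreg = selfreg,
       graph = graph, degrees = degreeTable(graph), circuits = circuits,
       scores = scores)
}
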