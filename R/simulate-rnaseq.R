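#' Simulate the differential expression table
#'
#' One table over the full gene universe under the model-vs-treatment
#' contrast: planted up-in-model genes get `log2fc ~ N(2, 0.25^2)` and
#' `q ~ U(0, 0.01)`; planted up-after-treatment genes the mirrored negative
#' fold change; null genes `log2fc ~ N(0, 0.25^2)` and `q ~ U(0.2, 1)`.
#' Exactly `candidateOverlap` of the up-in-model genes are lost-SE genes
#' (enforced by [simulateTruth()]).
#'
#' @param config a [simulationConfig()].
#' @param truth output of [simulateTruth()].
#' @return a DEG `data.frame` (`geneId`, `log2fc`, `pvalue`, `qvalue`).
#' @export
simulateDegTable <- function(config, truth) {
  set.seed(stageSeed(config$seed, "deg"))
  ids <- sort(truth$universe, method = "radix")
  n <- length(ids)
  lfc <- stats::rnorm(n, 0, 0.25)
  q <- stats::runif(n, 0.2, 1)
  up <- ids %in% truth$upModel
  dn <- ids %in% truth$upEa
  lfc[up] <- abs(stats::rnorm(sum(up), 2, 0.25))
  lfc[dn] <- -abs(stats::rnorm(sum(dn), 2, 0.25))
  q[up | dn] <- stats::runif(sum(up | dn), 0, 0.01)
  data.frame(geneId = ids, log2fc = lfc,
             pvalue = q * stats::runif(n, 0.05, 1), qvalue = q,
             stringsAsFactors = FALSE)
}

#' Simulate the candidate-gene expression matrix
#'
#' FPKM matrix over the planted candidate genes for three groups (sham,
#' model, ea) with `nSamplesPerGroup` samples each.  Every gene draws a
#' baseline and i.i.d. within-group noise (SD = 15% of baseline); the
#' planted key gene's model-group mean is shifted by
#' `expressionEffectSD` within-group SDs, and the two expression decoys
#' (`rfDecoys`) carry a weaker 2-SD shift so the importance ranking has
#' deterministic runners-up that are distinct from the annotation-driven
#' Friends runners-up.  With `expressionEffectSD = 0` the key gene is
#' exchangeable with the nulls.
#'
#' @param config a [simulationConfig()].
#' @param truth output of [simulateTruth()].
#' @return a list with `matrix` (genes x samples FPKM) and `labels`
#'   (character vector of group labels per sample).
#' @export
simulateExpression <- function(config, truth) {
  set.seed(stageSeed(config$seed, "expression"))
  genes <- truth$candidates
  groups <- c("sham", "model", "ea")
  nS <- config$nSamplesPerGroup
  labels <- rep(groups, each = nS)
  m <- matrix(0, nrow = length(genes), ncol = length(labels),
              dimnames = list(genes,
                              sprintf("%s_%02d", labels,
                                      sequence(rep(nS, 3L)))))
  for (i in seq_along(genes)) {
    base <- stats::runif(1L, 5, 50)
    sdv <- 0.15 * base
    vals <- stats::rnorm(length(labels), base, sdv)
    shift <- 0
    if (genes[i] == truth$keyGene) shift <- config$expressionEffectSD * sdv
    if (genes[i] %in% truth$rfDecoys) shift <- 2 * sdv
    vals[labels == "model"] <- vals[labels == "model"] + shift
    m[i, ] <- pmax(vals, 0)
  }
  list(matrix = m, labels = labels)
}

#' Simulate the ontology DAG, gene annotations and gene set collection
#'
#' Builds a small two-root ontology (>= 30 terms, `is_a` / `part_of`
#' edges), annotates the candidate genes so that the planted key gene's
#' term set is a strict superset of every other candidate's and tops the
#' Friends ranking (the layout is redrawn until that planted claim holds;
#' the annotation decoys get large subsets and become the runners-up, the
#' expression decoys minimal ones), and derives a GMT gene-set
#' collection for the over-representation stage, including one set enriched
#' for the candidate genes.
#'
#' @param config a [simulationConfig()].
#' @param truth output of [simulateTruth()].
#' @return a list with `dag` (`data.frame`: `term`, `parent`, `type`),
#'   `annotations` (gene -> term character vectors) and `geneSets` (named
#'   list, GMT semantics).
#' @export
simulateOntology <- function(config, truth) {
  set.seed(stageSeed(config$seed, "ontology"))
  keyTerms <- sprintf("K%02d", 1:12)
  extraTerms <- sprintf("T%02d", 1:16)
  types <- c("is_a", "part_of")
  # key terms hang under root R1 in two levels; extra terms under R2
  dag <- rbind(
    data.frame(term = keyTerms[1:4], parent = "R1", type = "is_a",
               stringsAsFactors = FALSE),
    data.frame(term = keyTerms[5:12],
               parent = keyTerms[((5:12) %% 4L) + 1L],
               type = sample(types, 8L, replace = TRUE),
               stringsAsFactors = FALSE),
    data.frame(term = extraTerms[1:4], parent = "R2", type = "is_a",
               stringsAsFactors = FALSE),
    data.frame(term = extraTerms[5:16],
               parent = extraTerms[((5:16) %% 4L) + 1L],
               type = sample(types, 12L, replace = TRUE),
               stringsAsFactors = FALSE))
  # annotation layout: redrawn until the planted claim holds (the key
  # gene tops the Friends ranking and the annotation decoys are its
  # runners-up), mirroring the redraw-until-valid placement of planted
  # SEs; the best-match-average does not guarantee that a superset
  # annotation maximises the mean similarity for every random layout
  ann <- NULL
  for (attempt in seq_len(50L)) {
    set.seed(stageSeed(config$seed, paste0("ontology_", attempt)))
    cand <- list()
    for (g in truth$candidates) {
      cand[[g]] <- if (g == truth$keyGene) keyTerms
        else if (g %in% truth$friendsDecoys) sample(keyTerms, 8L)
        else if (g %in% truth$rfDecoys) sample(keyTerms, 2L)
        else sample(keyTerms, sample(4:6, 1L))
    }
    fr <- friendsRank(cand, dag)
    top <- fr$ranking$geneId[seq_len(min(3L, nrow(fr$ranking)))]
    okTop <- top[1L] == truth$keyGene
    okDecoys <- length(truth$friendsDecoys) < 2L ||
      setequal(top[-1L], truth$friendsDecoys)
    if (okTop && okDecoys) {
      ann <- cand
      break
    }
  }
  if (is.null(ann))
    stop("could not realise the planted Friends ranking in 50 draws")
  set.seed(stageSeed(config$seed, "ontology_sets"))
  # gene sets: one per term (annotated candidates plus background genes),
  # plus a set enriched for the candidate gene list
  bgPool <- setdiff(truth$universe, truth$candidates)
  sets <- lapply(stats::setNames(keyTerms, paste0("SET_", keyTerms)),
                 function(t) {
    members <- names(ann)[vapply(ann, function(a) t %in% a, logical(1L))]
    sort(c(members, sample(bgPool, sample(30:60, 1L))), method = "radix")
  })
  sets$SET_CANDIDATE_PATHWAY <-
    sort(c(sample(truth$candidates,
                  max(2L, floor(length(truth$candidates) * 2 / 3))),
           sample(bgPool, 40L)), method = "radix")
  for (k in seq_along(extraTerms)) {
    sets[[paste0("SET_", extraTerms[k])]] <-
      sort(sample(bgPool, sample(30:60, 1L)), method = "radix")
  }
  attr(sets, "descriptions") <-
    stats::setNames(rep("synthetic gene set", length(sets)), names(sets))
  list(dag = dag, annotations = ann, geneSets = sets)
}
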