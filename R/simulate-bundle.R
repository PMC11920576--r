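#' Simulate the motif library
#'
#' One high-information PWM per transcription-factor gene: a random
#' `motifWidth`-mer consensus (distinct across TFs) with probability 0.997
#' on the consensus base and 0.001 elsewhere.  The planted clique is
#' realised by inserting exact consensus sites (see [simulateBundle()]).
#'
#' @param config a [simulationConfig()].
#' @param truth output of [simulateTruth()].
#' @return a list with `pwms` (named list of [PWMotif]) and `consensus`
#'   (named character).
#' @export
simulateMotifLibrary <- function(config, truth) {
  set.seed(stageSeed(config$seed, "motifs"))
  tfs <- sort(truth$tfGenes, method = "radix")
  seen <- character()
  consensus <- vapply(tfs, function(tf) {
    repeat {
      s <- paste(sample(c("A", "C", "G", "T"), config$motifWidth,
                        replace = TRUE), collapse = "")
      if (!s %in% seen) break
    }
    seen <<- c(seen, s)
    s
  }, character(1L))
  pwms <- lapply(tfs, function(tf) {
    bases <- strsplit(consensus[[tf]], "")[[1L]]
    m <- matrix(0.001, nrow = 4L, ncol = config$motifWidth,
                dimnames = list(c("A", "C", "G", "T"), NULL))
    m[cbind(match(bases, rownames(m)), seq_along(bases))] <- 0.997
    pwMotif(tf, m)
  })
  names(pwms) <- tfs
  list(pwms = pwms, consensus = consensus)
}

#' Extract constituent sequences from a genome
#'
#' @param gr `GRanges` of constituent peaks with a `name` metadata column.
#' @param seqs a `DNAStringSet`: either chromosomes (sequences are then
#'   extracted by coordinates) or per-peak sequences keyed by peak name
#'   (sequences are then looked up; peaks without a sequence are dropped).
#' @return a named `DNAStringSet` keyed by peak name.
#' @export
getConstituentSequences <- function(gr, seqs) {
  stopifnot(is(gr, "GRanges"))
  nm <- mcols(gr)$name
  chr <- as.character(seqnames(gr))
  if (all(chr %in% names(seqs))) {
    out <- Biostrings::DNAStringSet(vapply(seq_along(gr), function(i)
      as.character(Biostrings::subseq(seqs[[chr[i]]], start(gr)[i],
                                      end(gr)[i])), character(1L)))
    names(out) <- nm
    return(out)
  }
  keep <- nm %in% names(seqs)
  out <- seqs[nm[keep]]
  out
}

#' Simulate the full two-condition synthetic bundle
#'
#' Runs every generator stage from one seed: genome and annotation, planted
#' truth sets, per-condition ChIP-seq peaks, motif library with the planted
#' fully interconnected TF clique (each clique member's SE sequence receives
#' `ownMotifCopies` exact consensus sites of every member's motif, in the
#' model condition), DEG table, expression matrix, ontology and gene sets.
#' Before returning, a self-audit re-verifies every manifest claim against
#' the emitted objects (planted gaps below the stitching distance, motif
#' copies present, set sizes and overlaps exact); a failed audit is an
#' error.  When `outdir` is given all artefacts are written as plain-text
#' files (BED6+2 peaks, FASTA, TSV, GMT, JASPAR motifs, JSON manifest).
#'
#' @param config a [simulationConfig()].
#' @param outdir optional output directory.
#' @return a list (the bundle) with elements `config`, `genome`, `truth`,
#'   `peaks` (per condition), `plantedSE` (per condition), `motifs`,
#'   `seSequences` (named by constituent peak name; `NULL` when
#'   `sequenceScope = "none"`), `deg`, `expression`, `ontology` and
#'   `manifest`.
#' @export
simulateBundle <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  genome <- simulateGenome(config)
  truth <- simulateTruth(config, genome$genes)
  pkModel <- simulateChipseqPeaks(config, genome, truth, "model")
  pkEa <- simulateChipseqPeaks(config, genome, truth, "ea")
  motifs <- simulateMotifLibrary(config, truth)

  planted <- plantCliqueMotifs(config, genome, truth, motifs,
                               pkModel, pkEa)
  genome$seqs <- planted$genomeSeqs
  seSequences <- planted$seSequences

  deg <- simulateDegTable(config, truth)
  expr <- simulateExpression(config, truth)
  onto <- simulateOntology(config, truth)

  manifest <- list(
    seed = config$seed,
    nSuperPlanted = as.list(config$nPlantedSE),
    genomicOwners = truth$genomicOwners,
    plantedSE = list(model = pkModel$plantedSE, ea = pkEa$plantedSE),
    seGenes = truth$seGenes,
    upModel = truth$upModel, upEa = truth$upEa,
    candidates = truth$candidates, keyGene = truth$keyGene,
    rfDecoys = truth$rfDecoys, friendsDecoys = truth$friendsDecoys,
    clique = truth$clique,
    motifConsensus = as.list(motifs$consensus[truth$clique]),
    motifPlacements = planted$placements)

  bundle <- list(config = config, genome = genome, truth = truth,
                 peaks = list(model = pkModel$peaks, ea = pkEa$peaks),
                 plantedSE = list(model = pkModel$plantedSE,
                                  ea = pkEa$plantedSE),
                 motifs = motifs, seSequences = seSequences,
                 deg = deg, expression = expr, ontology = onto,
                 manifest = manifest)
  auditBundle(bundle)
  if (!is.null(outdir)) writeBundle(bundle, outdir)
  bundle
}

# Insert the planted clique consensus sites into the sequences.  In genome
# scope the insertions edit the chromosome sequences; in SE scope each
# planted constituent gets its own background sequence (owner-keyed
# stream) and the insertions edit those.  Placement is deterministic:
# (member x copy) sites are dealt round-robin across the owner's
# constituents at fixed slot offsets.
plantCliqueMotifs <- function(config, genome, truth, motifs, pkModel,
                              pkEa) {
  scope <- config$sequenceScope
  w <- config$motifWidth
  seSequences <- NULL
  if (scope == "se") {
    allPk <- c(pkModel$peaks, pkEa$peaks)
    allPk <- allPk[!duplicated(mcols(allPk)$name)]
    isPlanted <- startsWith(mcols(allPk)$name, "se_")
    pl <- allPk[isPlanted]
    seqsList <- lapply(seq_along(pl), function(i) {
      set.seed(stageSeed(config$seed,
                         paste0("seseq_", mcols(pl)$name[i])))
      randomDNA(width(pl)[i], config$gc)
    })
    seSequences <- Biostrings::DNAStringSet(unlist(seqsList))
    names(seSequences) <- mcols(pl)$name
  }
  placements <- list()
  if (length(truth$clique)) {
    members <- sort(truth$clique, method = "radix")
    sites <- expand.grid(copy = seq_len(config$ownMotifCopies),
                         motifOf = members, stringsAsFactors = FALSE)
    pk <- pkModel$peaks
    for (owner in members) {
      own <- pk[startsWith(mcols(pk)$name, paste0("se_", owner, "_"))]
      own <- own[order(mcols(own)$name, method = "radix")]
      k <- length(own)
      slotCount <- integer(k)
      for (s in seq_len(nrow(sites))) {
        ci <- (s - 1L) %% k + 1L
        # advance to a constituent with room
        tries <- 0L
        repeat {
          off <- 20L + slotCount[ci] * (w + 7L)
          if (off + w <= width(own)[ci] - 20L) break
          ci <- ci %% k + 1L
          tries <- tries + 1L
          if (tries > k) stop("planted SE of ", owner,
                              " too small for the motif insertions")
        }
        slotCount[ci] <- slotCount[ci] + 1L
        cons <- motifs$consensus[[sites$motifOf[s]]]
        pkName <- mcols(own)$name[ci]
        if (scope == "genome") {
          chr <- as.character(seqnames(own))[ci]
          absStart <- start(own)[ci] + off  # 1-based
          Biostrings::subseq(genome$seqs[[chr]], absStart,
                             absStart + w - 1L) <- Biostrings::DNAString(cons)
        } else if (scope == "se") {
          Biostrings::subseq(seSequences[[pkName]], off + 1L,
                             off + w) <- Biostrings::DNAString(cons)
        }
        placements[[length(placements) + 1L]] <- data.frame(
          motifOf = sites$motifOf[s], seOwner = owner, peak = pkName,
          offset = off, stringsAsFactors = FALSE)
      }
    }
  }
  placements <- if (length(placements)) do.call(rbind, placements)
    else data.frame(motifOf = character(), seOwner = character(),
                    peak = character(), offset = integer(),
                    stringsAsFactors = FALSE)
  if (scope == "genome" && !is.null(genome$seqs)) {
    # extract planted constituent sequences for convenience
    allPk <- c(pkModel$peaks, pkEa$peaks)
    allPk <- allPk[!duplicated(mcols(allPk)$name)]
    pl <- allPk[startsWith(mcols(allPk)$name, "se_")]
    seSequences <- getConstituentSequences(pl, genome$seqs)
  }
  list(genomeSeqs = genome$seqs, seSequences = seSequences,
       placements = placements)
}

# Self-audit: every manifest claim is re-verified against the emitted
# objects before the generator returns.
auditBundle <- function(bundle) {
  cfg <- bundle$config
  tr <- bundle$truth
  fail <- function(...) stop("generator self-audit failed: ", ...)

  sg <- tr$seGenes
  if (length(sg$model) != cfg$seGenesModel ||
      length(sg$ea) != cfg$seGenesEa ||
      length(sg$shared) != cfg$sharedSEGeneOverlap)
    fail("cohort SE gene set sizes")
  if (!setequal(sg$lost, setdiff(sg$model, sg$ea)) ||
      !setequal(sg$gained, setdiff(sg$ea, sg$model)) ||
      !setequal(sg$shared, intersect(sg$model, sg$ea)))
    fail("cohort set arithmetic")
  if (!identical(sort(intersect(sg$lost, tr$upModel)), tr$candidates) ||
      length(tr$candidates) != cfg$candidateOverlap)
    fail("candidate overlap is not exactly the planted set")
  if (length(intersect(sg$gained, tr$upEa)))
    fail("gained x up-after-treatment must be empty")
  for (cond in c("model", "ea")) {
    owners <- tr$genomicOwners[[cond]]
    if (!all(owners %in% sg[[cond]])) fail("genomic owners outside cohort")
    pl <- bundle$plantedSE[[cond]]
    if (!setequal(pl$geneId, owners)) fail("planted SE owner mismatch")
    pk <- bundle$peaks[[cond]]
    for (g in owners) {
      cpk <- pk[startsWith(mcols(pk)$name, paste0("se_", g, "_"))]
      if (length(cpk) < 2L) fail("planted SE with < 2 constituents")
      gaps <- start(cpk)[-1L] - end(cpk)[-length(cpk)] - 1L
      if (any(gaps >= 12500L)) fail("planted SE gap >= 12,500 bp")
    }
  }
  if (!is.null(bundle$seSequences) && length(tr$clique)) {
    for (a in tr$clique) {
      nm <- names(bundle$seSequences)
      ownSeqs <- bundle$seSequences[startsWith(nm, paste0("se_", a, "_"))]
      for (b in tr$clique) {
        cons <- bundle$motifs$consensus[[b]]
        nFound <- sum(vapply(seq_along(ownSeqs), function(i)
          Biostrings::countPattern(cons, ownSeqs[[i]]), integer(1L)))
        if (nFound < cfg$ownMotifCopies)
          fail("planted motif copies of ", b, " missing in SE of ", a)
      }
    }
  }
  ann <- bundle$ontology$annotations
  keySet <- ann[[tr$keyGene]]
  for (g in setdiff(names(ann), tr$keyGene))
    if (!all(ann[[g]] %in% keySet))
      fail("key gene annotation is not a superset of ", g)
  if (any(bundle$expression$matrix < 0)) fail("negative FPKM")
  invisible(TRUE)
}

#' Write a simulated bundle to disk
#'
#' Emits every artefact of [simulateBundle()] as deterministic plain-text
#' files: `peaks_model.bed` / `peaks_ea.bed` (BED6+2), `annotation.tsv`,
#' `deg.tsv`, `expression.tsv`, `sample_labels.tsv`, `motifs.jaspar`,
#' `ontology_dag.tsv`, `gene_annotations.tsv`, `gene_sets.gmt`,
#' `se_genes_model.txt` / `se_genes_ea.txt` (cohort SE gene lists),
#' `genome.fasta` and/or `se_sequences.fasta` (per `sequenceScope`), and
#' `manifest.json`.
#'
#' @param bundle output of [simulateBundle()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
writeBundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  writePeaks(bundle$peaks$model, p("peaks_model.bed"))
  writePeaks(bundle$peaks$ea, p("peaks_ea.bed"))
  writeGeneAnnotation(bundle$genome$genes, p("annotation.tsv"))
  writeDegTable(bundle$deg, p("deg.tsv"))
  em <- bundle$expression$matrix
  writeTable(data.frame(gene_id = rownames(em), em, check.names = FALSE),
             p("expression.tsv"))
  writeTable(data.frame(sample = colnames(em),
                        group = bundle$expression$labels),
             p("sample_labels.tsv"), sort = FALSE)
  writeMotifLibrary(bundle$motifs$pwms, p("motifs.jaspar"))
  writeTable(bundle$ontology$dag, p("ontology_dag.tsv"))
  ann <- bundle$ontology$annotations
  writeTable(data.frame(gene_id = rep(names(ann), lengths(ann)),
                        term = unlist(ann, use.names = FALSE)),
             p("gene_annotations.tsv"))
  writeGeneSets(bundle$ontology$geneSets, p("gene_sets.gmt"))
  writeLines(bundle$truth$seGenes$model, p("se_genes_model.txt"))
  writeLines(bundle$truth$seGenes$ea, p("se_genes_ea.txt"))
  if (!is.null(bundle$genome$seqs))
    Biostrings::writeXStringSet(bundle$genome$seqs, p("genome.fasta"))
  if (!is.null(bundle$seSequences))
    Biostrings::writeXStringSet(bundle$seSequences,
                                p("se_sequences.fasta"))
  jsonlite::write_json(bundle$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
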