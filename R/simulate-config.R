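#' Configuration for the synthetic two-condition study
#'
#' Builds and validates the configuration of the synthetic data generator.
#' The generator plants ground truth at two coupled layers:
#'
#' \describe{
#'   \item{genomic layer}{an explicit synthetic genome with annotated genes,
#'     typical H3K27ac enhancer peaks, and `nPlantedSE` planted
#'     super-enhancer clusters per condition placed near their owner genes'
#'     TSS.  This layer exercises the SE caller and the CRC mapper (the
#'     planted TF clique lives here).}
#'   \item{cohort layer}{SE-associated gene sets of the sizes observed in a
#'     full two-condition ChIP-seq landscape (`seGenesModel`, `seGenesEa`,
#'     with `sharedSEGeneOverlap` genes in common) and a DEG table with
#'     `nUpModel` / `nUpEa` up-regulated genes, of which exactly
#'     `candidateOverlap` up-in-model genes are lost-SE genes.  The genomic
#'     owners are drawn from the cohort sets, so the two layers are
#'     consistent.  This layer exercises the integration, prioritisation and
#'     enrichment stages at realistic set sizes without a full-size genome.}
#' }
#'
#' Typical enhancer signal follows a log-normal law winsorised at
#' `exp(signalMeanlog + signalSdlog)` (about the 84th percentile): the
#' winsorised bulk keeps the convex rank curve while bounding the extreme
#' order statistics, which is what makes the planted super-enhancers occupy
#' the top signal ranks by construction.
#'
#' @param seed integer seed fixing every emitted byte.
#' @param nChroms,chromLength number and length (bp) of chromosomes.
#' @param nGenes genomically placed genes (on a grid with >= 30 kb spacing;
#'   an error is raised when they do not fit).
#' @param geneLength gene body length in bp.
#' @param tfFraction fraction of genomic genes flagged as transcription
#'   factors (`floor(tfFraction * nGenes)` TFs).
#' @param nTranscriptome total gene universe for the expression layer
#'   (genomic genes plus unplaced transcripts).
#' @param nTypicalPeaks typical enhancer peaks per condition.
#' @param typicalPeakLength,seConstituentLength,seConstituentGap integer
#'   ranges (length-2) for peak lengths and planted constituent layout (bp).
#' @param signalMeanlog,signalSdlog log-normal parameters of typical signal.
#' @param seSignalMultiplier planted constituent signal as a multiple of the
#'   typical median (>= 5).
#' @param seConstituents range of constituents per planted SE.
#' @param nPlantedSE named vector `c(model = , ea = )` of planted SEs.
#' @param plantedShared planted owner genes common to both conditions.
#' @param seGenesModel,seGenesEa,sharedSEGeneOverlap cohort-level SE gene
#'   set sizes and overlap.
#' @param nUpModel,nUpEa up-regulated gene counts (model-vs-treatment
#'   contrast: `nUpModel` with positive, `nUpEa` with negative log2FC).
#' @param candidateOverlap planted count of lost-SE genes that are also
#'   up-regulated in the model condition.
#' @param nClique planted fully interconnected TF clique size.
#' @param ownMotifCopies planted copies of each member's motif in each
#'   member's SE (default 3).
#' @param motifWidth motif width in bp.
#' @param expressionEffectSD group-mean shift of the planted key gene in
#'   within-group standard deviations.
#' @param nSamplesPerGroup expression samples per group (sham, model, ea).
#' @param inputFraction input signal as a fraction of sample signal.
#' @param sequenceScope `"genome"` (emit the full genome sequence), `"se"`
#'   (sequence only for planted SE constituents) or `"none"`; coordinates
#'   and signals are identical across scopes.
#' @param gc background GC content (0.5 gives exact PWM p-values under the
#'   default uniform background).
#' @return a validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(seed = 1,
                             nChroms = 4, chromLength = 6e6,
                             nGenes = 160, geneLength = 2000,
                             tfFraction = 0.2,
                             nTranscriptome = 3200,
                             nTypicalPeaks = 500,
                             typicalPeakLength = c(400, 900),
                             signalMeanlog = 1, signalSdlog = 1,
                             seSignalMultiplier = 10,
                             seConstituents = c(2, 6),
                             seConstituentLength = c(600, 1000),
                             seConstituentGap = c(300, 1500),
                             nPlantedSE = c(model = 12, ea = 12),
                             plantedShared = 4,
                             seGenesModel = 403, seGenesEa = 77,
                             sharedSEGeneOverlap = 36,
                             nUpModel = 2702, nUpEa = 53,
                             candidateOverlap = 18,
                             nClique = 4,
                             ownMotifCopies = 3, motifWidth = 10,
                             expressionEffectSD = 3,
                             nSamplesPerGroup = 20,
                             inputFraction = 0.1,
                             sequenceScope = c("genome", "se", "none"),
                             gc = 0.5) {
  cfg <- list(seed = as.integer(seed), nChroms = as.integer(nChroms),
              chromLength = as.integer(chromLength),
              nGenes = as.integer(nGenes),
              geneLength = as.integer(geneLength),
              tfFraction = tfFraction,
              nTranscriptome = as.integer(nTranscriptome),
              nTypicalPeaks = as.integer(nTypicalPeaks),
              typicalPeakLength = as.integer(typicalPeakLength),
              signalMeanlog = signalMeanlog, signalSdlog = signalSdlog,
              seSignalMultiplier = seSignalMultiplier,
              seConstituents = as.integer(seConstituents),
              seConstituentLength = as.integer(seConstituentLength),
              seConstituentGap = as.integer(seConstituentGap),
              nPlantedSE = c(model = as.integer(nPlantedSE[["model"]]),
                             ea = as.integer(nPlantedSE[["ea"]])),
              plantedShared = as.integer(plantedShared),
              seGenesModel = as.integer(seGenesModel),
              seGenesEa = as.integer(seGenesEa),
              sharedSEGeneOverlap = as.integer(sharedSEGeneOverlap),
              nUpModel = as.integer(nUpModel), nUpEa = as.integer(nUpEa),
              candidateOverlap = as.integer(candidateOverlap),
              nClique = as.integer(nClique),
              ownMotifCopies = as.integer(ownMotifCopies),
              motifWidth = as.integer(motifWidth),
              expressionEffectSD = expressionEffectSD,
              nSamplesPerGroup = as.integer(nSamplesPerGroup),
              inputFraction = inputFraction,
              sequenceScope = match.arg(sequenceScope),
              gc = gc)
  class(cfg) <- "SimulationConfig"
  validateSimulationConfig(cfg)
  cfg
}

validateSimulationConfig <- function(cfg) {
  with(cfg, {
    counts <- c(nChroms, chromLength, nGenes, nTranscriptome,
                nTypicalPeaks, nPlantedSE, plantedShared, seGenesModel,
                seGenesEa, sharedSEGeneOverlap, nUpModel, nUpEa,
                candidateOverlap, nClique, ownMotifCopies, motifWidth,
                nSamplesPerGroup)
    if (any(is.na(counts)) || any(counts < 0))
      stop("all counts must be non-negative")
    if (seSignalMultiplier < 5)
      stop("seSignalMultiplier must be >= 5")
    if (tfFraction < 0 || tfFraction > 1)
      stop("tfFraction must lie in [0, 1]")
    if (gc <= 0 || gc >= 1) stop("gc must lie in (0, 1)")
    if (seConstituents[1L] < 2L || seConstituents[2L] > 6L ||
        seConstituents[1L] > seConstituents[2L])
      stop("seConstituents must be a range within [2, 6]")
    if (sharedSEGeneOverlap > min(seGenesModel, seGenesEa))
      stop("sharedSEGeneOverlap exceeds an SE gene set size")
    lostCohort <- seGenesModel - sharedSEGeneOverlap
    if (candidateOverlap > min(nUpModel, lostCohort))
      stop("candidate_overlap infeasible: exceeds min(n_up_model, ",
           "lost-SE genes)")
    if (plantedShared > min(nPlantedSE))
      stop("plantedShared exceeds a planted SE count")
    if (nPlantedSE[["model"]] - plantedShared > lostCohort ||
        nPlantedSE[["ea"]] - plantedShared > seGenesEa - sharedSEGeneOverlap ||
        plantedShared > sharedSEGeneOverlap)
      stop("genomic planted owners do not fit inside the cohort sets")
    if (sum(nPlantedSE) - plantedShared > nGenes)
      stop("more planted owner genes than genomic genes")
    if (nClique > floor(tfFraction * nGenes))
      stop("clique larger than the number of TF genes")
    if (nClique > nPlantedSE[["model"]] - plantedShared)
      stop("clique members must be model-only planted owners")
    if (nTranscriptome < nGenes)
      stop("nTranscriptome must be >= nGenes")
    need <- seGenesModel + seGenesEa - sharedSEGeneOverlap + nUpModel +
      nUpEa
    if (nTranscriptome < need)
      stop("nTranscriptome too small for the requested gene sets (need >= ",
           need, ")")
    invisible(TRUE)
  })
}

#' @export
print.SimulationConfig <- function(x, ...) {
  cat("SimulationConfig (seed ", x$seed, "): ", x$nChroms, " chromosomes x ",
      x$chromLength, " bp, ", x$nGenes, " genomic genes (universe ",
      x$nTranscriptome, ")\n", sep = "")
  cat("  planted SEs model/ea: ", x$nPlantedSE[["model"]], "/",
      x$nPlantedSE[["ea"]], " (shared ", x$plantedShared,
      "); cohort SE genes ", x$seGenesModel, "/", x$seGenesEa,
      " (shared ", x$sharedSEGeneOverlap, ")\n", sep = "")
  cat("  up-regulated model/ea: ", x$nUpModel, "/", x$nUpEa,
      "; candidate overlap ", x$candidateOverlap, "; clique of ",
      x$nClique, " TFs\n", sep = "")
  invisible(x)
}
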