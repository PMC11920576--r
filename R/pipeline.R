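#' Pipeline configuration
#'
#' Bundles every stage parameter of the end-to-end pipeline with a single
#' global seed.  The global seed fans out to per-stage seeds through
#' [stageSeed()], so each stage is individually reproducible.  Unknown
#' parameters are rejected.
#'
#' @param simulation a [simulationConfig()] for the synthetic input stage
#'   (its seed is overridden by the pipeline seed's `"simulate"` stream).
#' @param stitchDistance,tssExclusion SE caller parameters (bp; defaults
#'   12500 and 2500).
#' @param qMax,lfcMin DEG filter parameters (defaults 0.05 and 0).
#' @param k top-list depth for the core-gene intersection (default 3).
#' @param pThreshold motif scan p-value threshold (default `1e-4`).
#' @param minInstances motif instance rule (default 3).
#' @param ntreeMax random-forest error-curve length (default 500).
#' @param seed global integer seed.
#' @return a validated list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(simulation = simulationConfig(),
                           stitchDistance = 12500, tssExclusion = 2500,
                           qMax = 0.05, lfcMin = 0, k = 3,
                           pThreshold = 1e-4, minInstances = 3,
                           ntreeMax = 500, seed = 1) {
  stopifnot(inherits(simulation, "SimulationConfig"))
  checkScalar(stitchDistance, "stitchDistance", min = 0)
  checkScalar(tssExclusion, "tssExclusion", min = 0)
  checkScalar(qMax, "qMax", 0, 1)
  checkScalar(lfcMin, "lfcMin", min = 0)
  checkScalar(k, "k", min = 1)
  if (pThreshold <= 0 || pThreshold > 1)
    stop("pThreshold must lie in (0, 1]")
  checkScalar(minInstances, "minInstances", min = 1)
  checkScalar(ntreeMax, "ntreeMax", min = 1)
  structure(list(simulation = simulation,
                 stitchDistance = stitchDistance,
                 tssExclusion = tssExclusion, qMax = qMax,
                 lfcMin = lfcMin, k = as.integer(k),
                 pThreshold = pThreshold,
                 minInstances = minInstances,
                 ntreeMax = as.integer(ntreeMax),
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Build a pipeline configuration from a named list
#'
#' Used by the command-line wrapper to construct a [pipelineConfig()] from a
#' parsed YAML document; unknown keys are rejected before any stage runs.
#'
#' @param params named list; the `simulation` element (if present) is itself
#'   a named list of [simulationConfig()] arguments.
#' @return a `PipelineConfig`.
#' @export
pipelineConfigFromList <- function(params) {
  stopifnot(is.list(params))
  simArgs <- params$simulation %||% list()
  params$simulation <- NULL
  badSim <- setdiff(names(simArgs), names(formals(simulationConfig)))
  bad <- setdiff(names(params), names(formals(pipelineConfig)))
  if (length(c(bad, badSim)))
    stop("unknown configuration key(s): ",
         paste(c(bad, badSim), collapse = ", "))
  if (!is.null(simArgs$nPlantedSE))
    simArgs$nPlantedSE <- unlist(simArgs$nPlantedSE)
  sim <- do.call(simulationConfig, simArgs)
  do.call(pipelineConfig, c(list(simulation = sim), params))
}

#' Run the full pipeline
#'
#' Orchestrates simulate, call-se (both conditions), diff-se, prioritize,
#' crc and enrich from one configuration, with per-stage output directories
#' under `outdir`, structured logging and a run manifest.  Stages
#' communicate through their emitted files, so with `resume = TRUE` any
#' stage whose outputs already exist is skipped and only downstream stages
#' are regenerated.  A failure aborts with the stage name and leaves prior
#' outputs intact.
#'
#' The integration stages run on the generator's cohort-level SE gene lists
#' (the full-landscape layer), while the caller and CRC stages run on the
#' genomically explicit layer; see the package vignette for the two-layer
#' design.
#'
#' @param config a [pipelineConfig()].
#' @param outdir output directory.
#' @param resume skip stages whose outputs exist (default `FALSE`).
#' @param quiet suppress progress logging.
#' @return the run manifest (named list), invisibly; also written as
#'   `run_manifest.json`.
#' @export
runPipeline <- function(config, outdir, resume = FALSE, quiet = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log <- function(...) if (!quiet) message("[secircuit] ", ...)
  dirty <- FALSE  # once a stage re-runs, every downstream stage re-runs
  runStage <- function(name, fun) {
    dir <- file.path(outdir, name)
    marker <- file.path(dir, ".done")
    if (resume && !dirty && file.exists(marker)) {
      log("stage ", name, ": outputs present, skipped (resume)")
      return(invisible(NULL))
    }
    dirty <<- TRUE
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    log("stage ", name, " (seed ", stageSeed(config$seed, name), ")")
    tryCatch(fun(dir), error = function(e)
      stop("stage ", name, " failed: ", conditionMessage(e),
           call. = FALSE))
    writeLines(name, marker)
    invisible(NULL)
  }
  simDir <- file.path(outdir, "simulate")

  runStage("simulate", function(dir) {
    sim <- config$simulation
    sim$seed <- stageSeed(config$seed, "simulate")
    validateSimulationConfig(sim)
    simulateBundle(sim, outdir = dir)
  })

  callStage <- function(cond) function(dir) {
    peaks <- readPeaks(file.path(simDir, sprintf("peaks_%s.bed", cond)),
                       dialect = "bed")
    genes <- readGeneAnnotation(file.path(simDir, "annotation.tsv"))
    res <- callSuperEnhancers(peaks, genes, config$stitchDistance,
                              config$tssExclusion)
    writeTable(as.data.frame(res$ranked), file.path(dir, "ranked.tsv"),
               sort = FALSE)
    se <- superEnhancers(res$ranked)
    seDf <- data.frame(chrom = as.character(seqnames(se)),
                       start = start(se) - 1L, end = end(se),
                       name = mcols(se)$regionId,
                       score = mcols(se)$score, strand = ".")
    utils::write.table(seDf, file.path(dir, "se.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE,
                       col.names = FALSE, eol = "\n")
    assign <- res$assignment[res$assignment$seId %in%
                               mcols(se)$regionId, , drop = FALSE]
    writeTable(assign, file.path(dir, "assignment.tsv"))
    consts <- constituents(res$ranked)
    regIds <- mcols(enhancerRegions(res$ranked))$regionId
    constDf <- do.call(rbind, lapply(seq_along(consts), function(i) {
      cgr <- consts[[i]]
      if (!length(cgr)) return(NULL)
      data.frame(seId = regIds[i], peak = mcols(cgr)$name,
                 chrom = as.character(seqnames(cgr)),
                 start = start(cgr) - 1L, end = end(cgr),
                 constituent = seq_along(cgr), stringsAsFactors = FALSE)
    }))
    writeTable(constDf, file.path(dir, "constituents.tsv"))
    jsonlite::write_json(
      list(cutoffScore = cutoffScore(res$cutoff),
           cutoffIndex = res$cutoff@cutoffIndex,
           nSuper = nSuper(res$cutoff),
           degenerate = isDegenerate(res$cutoff)),
      file.path(dir, "cutoff.json"), auto_unbox = TRUE, digits = NA)
  }
  runStage("callse_model", callStage("model"))
  runStage("callse_ea", callStage("ea"))

  runStage("diffse", function(dir) {
    modelGenes <- readLines(file.path(simDir, "se_genes_model.txt"))
    eaGenes <- readLines(file.path(simDir, "se_genes_ea.txt"))
    deg <- readDegTable(file.path(simDir, "deg.tsv"))
    diff <- diffSEGenes(modelGenes, eaGenes)
    sets <- filterDEGs(deg, config$qMax, config$lfcMin)
    lostUp <- intersectCandidates(diff, sets, "lost_up_model")
    gainedUp <- intersectCandidates(diff, sets, "gained_up_ea")
    jsonlite::write_json(
      c(as.list(diff$counts),
        list(upModel = length(sets$up), upEa = length(sets$down),
             candidatesLostUpModel = length(lostUp),
             candidatesGainedUpEa = length(gainedUp))),
      file.path(dir, "venn.json"), auto_unbox = TRUE, digits = NA)
    writeTable(data.frame(gene_id = lostUp),
               file.path(dir, "candidates.tsv"))
    writeTable(data.frame(gene_id = as.character(gainedUp)),
               file.path(dir, "candidates_gained.tsv"))
  })

  runStage("prioritize", function(dir) {
    expr <- readExpressionMatrix(file.path(simDir, "expression.tsv"))
    labels <- utils::read.table(file.path(simDir, "sample_labels.tsv"),
                                sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
    labels <- labels$group[match(colnames(expr), labels$sample)]
    cand <- utils::read.table(file.path(outdir, "diffse",
                                        "candidates.tsv"),
                              sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)$gene_id
    expr <- expr[rownames(expr) %in% cand, , drop = FALSE]
    seed <- stageSeed(config$seed, "prioritize")
    sel <- selectNtree(expr, labels, config$ntreeMax, seed = seed)
    # the importance forest is never smaller than 100 trees: the error
    # curve can bottom out after a handful of trees, but Gini importance
    # from a near-empty forest is statistically meaningless
    imp <- rankGenesGini(expr, labels,
                         ntree = max(sel$chosenNtree, 100L),
                         seed = seed)
    dag <- utils::read.table(file.path(simDir, "ontology_dag.tsv"),
                             sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    annDf <- utils::read.table(file.path(simDir, "gene_annotations.tsv"),
                               sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
    ann <- split(annDf$term, annDf$gene_id)
    ann <- ann[names(ann) %in% rownames(expr)]
    fr <- friendsRank(ann, dag)
    core <- suppressWarnings(
      coreGeneIntersection(imp, fr, k = config$k))
    writeTable(data.frame(ntree = seq_along(sel$errorByNtree),
                          oobError = sel$errorByNtree),
               file.path(dir, "error_curve.tsv"), sort = FALSE)
    writeTable(imp, file.path(dir, "importance.tsv"), sort = FALSE)
    writeTable(data.frame(gene_id = rownames(fr$simMatrix),
                          fr$simMatrix, check.names = FALSE),
               file.path(dir, "similarity.tsv"))
    writeTable(fr$ranking, file.path(dir, "friends.tsv"), sort = FALSE)
    jsonlite::write_json(
      list(coreGenes = core,
           rfTop = imp$geneId[imp$rank <= config$k],
           friendsTop = fr$ranking$geneId[fr$ranking$rank <= config$k],
           chosenNtree = sel$chosenNtree, seed = seed),
      file.path(dir, "core_genes.json"), auto_unbox = TRUE, digits = NA)
  })

  runStage("crc", function(dir) {
    genes <- readGeneAnnotation(file.path(simDir, "annotation.tsv"))
    pwms <- readMotifLibrary(file.path(simDir, "motifs.jaspar"),
                             format = "jaspar")
    mdlDir <- file.path(outdir, "callse_model")
    assign <- utils::read.table(file.path(mdlDir, "assignment.tsv"),
                                sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
    constDf <- utils::read.table(file.path(mdlDir, "constituents.tsv"),
                                 sep = "\t", header = TRUE,
                                 stringsAsFactors = FALSE)
    constDf <- constDf[constDf$seId %in% assign$seId, , drop = FALSE]
    cgr <- GRanges(constDf$chrom,
                   IRanges(constDf$start + 1L, constDf$end),
                   name = constDf$peak)
    genomeFa <- file.path(simDir, "genome.fasta")
    seFa <- file.path(simDir, "se_sequences.fasta")
    seqs <- if (file.exists(genomeFa)) {
      gseqs <- Biostrings::readDNAStringSet(genomeFa)
      names(gseqs) <- sub("\\s.*", "", names(gseqs))
      getConstituentSequences(cgr, gseqs)
    } else if (file.exists(seFa)) {
      getConstituentSequences(cgr, Biostrings::readDNAStringSet(seFa))
    } else stop("no sequence artefact available for motif scanning")
    seMap <- constDf[match(names(seqs), constDf$peak), , drop = FALSE]
    seMap <- data.frame(seqName = seMap$peak, seId = seMap$seId,
                        constituent = seMap$constituent,
                        stringsAsFactors = FALSE)
    crc <- mapCRC(assign, genes, pwms, seqs, seMap = seMap,
                  pThreshold = config$pThreshold,
                  minInstances = config$minInstances)
    writeTable(crc$hits, file.path(dir, "hits.tsv"))
    writeTable(crc$selfreg, file.path(dir, "selfreg.tsv"))
    writeTable(graphEdges(crc$graph), file.path(dir, "edges.tsv"))
    writeTable(crc$degrees, file.path(dir, "degrees.tsv"), sort = FALSE)
    writeTable(crc$scores$table, file.path(dir, "circuits.tsv"),
               sort = FALSE)
    jsonlite::write_json(
      list(representative = crc$scores$representative,
           nCircuits = length(crc$circuits),
           nSelfRegulating = nrow(crc$selfreg)),
      file.path(dir, "crc.json"), auto_unbox = TRUE, digits = NA)
  })

  runStage("enrich", function(dir) {
    cand <- utils::read.table(file.path(outdir, "diffse",
                                        "candidates.tsv"),
                              sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)$gene_id
    sets <- readGeneSets(file.path(simDir, "gene_sets.gmt"))
    deg <- readDegTable(file.path(simDir, "deg.tsv"))
    res <- oraTest(cand, sets, universe = deg$geneId)
    writeTable(res, file.path(dir, "ora.tsv"), sort = FALSE)
  })

  manifest <- buildRunManifest(config, outdir)
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log("pipeline complete: ", outdir)
  invisible(manifest)
}

# Assemble the run manifest from stage outputs.
buildRunManifest <- function(config, outdir) {
  readJson <- function(...) jsonlite::read_json(file.path(outdir, ...))
  venn <- readJson("diffse", "venn.json")
  core <- readJson("prioritize", "core_genes.json")
  crc <- readJson("crc", "crc.json")
  cutM <- readJson("callse_model", "cutoff.json")
  cutE <- readJson("callse_ea", "cutoff.json")
  list(
    seed = config$seed,
    parameters = list(stitchDistance = config$stitchDistance,
                      tssExclusion = config$tssExclusion,
                      qMax = config$qMax, lfcMin = config$lfcMin,
                      k = config$k, pThreshold = config$pThreshold,
                      minInstances = config$minInstances,
                      ntreeMax = config$ntreeMax),
    summary = list(
      nSuperModel = cutM$nSuper, nSuperEa = cutE$nSuper,
      seGenesModel = venn$model, seGenesEa = venn$ea,
      lost = venn$lost, gained = venn$gained, shared = venn$shared,
      upModel = venn$upModel, upEa = venn$upEa,
      nCandidates = venn$candidatesLostUpModel,
      nCandidatesGained = venn$candidatesGainedUpEa,
      coreGenes = unlist(core$coreGenes),
      chosenNtree = core$chosenNtree,
      nCircuits = crc$nCircuits,
      representativeCRC = unlist(crc$representative)))
}
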