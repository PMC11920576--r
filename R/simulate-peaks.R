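#' Draw the planted ground-truth gene sets
#'
#' Chooses, deterministically given the seed, every planted gene set of the
#' two-layer design: the genomically planted SE owner genes per condition
#' (with `plantedShared` in common, the TF clique among the model-only
#' owners), the cohort-level SE gene sets (`seGenesModel` / `seGenesEa`
#' with `sharedSEGeneOverlap` shared, containing the genomic owners), the
#' up-regulated DEG sets, and the candidate set (exactly
#' `candidateOverlap` lost-SE genes that are up-regulated in the model
#' condition), including the planted key gene and the expression /
#' annotation decoys used by the prioritisation stage.
#'
#' @param config a [simulationConfig()].
#' @param genes genomic gene annotation from [simulateGenome()].
#' @return a list of planted sets (see [simulateBundle()] for the manifest
#'   layout).
#' @export
simulateTruth <- function(config, genes) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(stageSeed(config$seed, "truth"))
  universe <- c(genes$geneId,
                sprintf("X%04d",
                        seq_len(config$nTranscriptome - nrow(genes))))
  tfGenes <- genes$geneId[genes$isTF]

  # genomic owners: clique TFs are model-only owners
  clique <- sort(sample(tfGenes, config$nClique), method = "radix")
  pool <- setdiff(genes$geneId, clique)
  nModelOnly <- config$nPlantedSE[["model"]] - config$plantedShared
  nEaOnly <- config$nPlantedSE[["ea"]] - config$plantedShared
  modelOnlyG <- c(clique, sample(pool, nModelOnly - config$nClique))
  pool <- setdiff(pool, modelOnlyG)
  sharedG <- sample(pool, config$plantedShared)
  pool <- setdiff(pool, sharedG)
  eaOnlyG <- sample(pool, nEaOnly)

  # cohort sets extend the genomic owners to the configured sizes with
  # unplaced transcripts
  extra <- setdiff(universe, genes$geneId)
  take <- function(n) {
    picked <- sample(extra, n)
    extra <<- setdiff(extra, picked)
    picked
  }
  sharedC <- c(sharedG, take(config$sharedSEGeneOverlap -
                               config$plantedShared))
  lostC <- c(modelOnlyG, take(config$seGenesModel -
                                config$sharedSEGeneOverlap -
                                length(modelOnlyG)))
  gainedC <- c(eaOnlyG, take(config$seGenesEa -
                               config$sharedSEGeneOverlap -
                               length(eaOnlyG)))

  # candidates: exactly candidateOverlap lost-SE genes are up in the model;
  # clique TFs are kept out so the CRC and key-gene stories stay separate
  candPool <- setdiff(lostC, clique)
  if (length(candPool) < config$candidateOverlap)
    stop("candidate_overlap infeasible for the planted lost-SE set")
  candidates <- sort(sample(candPool, config$candidateOverlap),
                     method = "radix")
  keyGene <- candidates[1L]
  others <- setdiff(candidates, keyGene)
  rfDecoys <- others[seq_len(min(2L, length(others)))]
  others <- setdiff(others, rfDecoys)
  friendsDecoys <- others[seq_len(min(2L, length(others)))]

  upPool <- setdiff(universe, c(lostC, gainedC))
  upModel <- sort(c(candidates, sample(upPool, config$nUpModel -
                                         config$candidateOverlap)),
                  method = "radix")
  upPool <- setdiff(upPool, upModel)
  upEa <- sort(sample(upPool, config$nUpEa), method = "radix")

  list(universe = universe, tfGenes = tfGenes,
       clique = clique,
       genomicOwners = list(model = sort(c(modelOnlyG, sharedG),
                                         method = "radix"),
                            ea = sort(c(eaOnlyG, sharedG),
                                      method = "radix"),
                            shared = sort(sharedG, method = "radix")),
       seGenes = list(model = sort(c(lostC, sharedC), method = "radix"),
                      ea = sort(c(gainedC, sharedC), method = "radix"),
                      lost = sort(lostC, method = "radix"),
                      gained = sort(gainedC, method = "radix"),
                      shared = sort(sharedC, method = "radix")),
       upModel = upModel, upEa = upEa,
       candidates = candidates, keyGene = keyGene,
       rfDecoys = rfDecoys, friendsDecoys = friendsDecoys)
}

#' Simulate H3K27ac enhancer peaks for one condition
#'
#' Emits `nTypicalPeaks` typical enhancer peaks (identical in both
#' conditions) with winsorised log-normal sample signal, plus the planted
#' super-enhancer clusters of the condition's owner genes: each planted SE
#' has 2-6 constituents within sub-stitching gaps starting 5 kb downstream
#' of the owner TSS, every constituent carrying
#' `typical median x seSignalMultiplier` sample signal.  Input signal is
#' `inputFraction` of sample signal throughout.  The constituent layout of
#' an owner gene is drawn from an owner-keyed stream, so a shared owner has
#' the identical planted SE in both conditions and the condition files
#' differ only in planted-SE ownership.  A planted constituent that would
#' intersect the TSS-exclusion window of a non-owner gene is re-drawn up to
#' 100 times before erroring.
#'
#' @param config a [simulationConfig()].
#' @param genome output of [simulateGenome()].
#' @param truth output of [simulateTruth()].
#' @param condition `"model"` or `"ea"`.
#' @return a list with `peaks` (a `GRanges` as from [readPeaks()]) and
#'   `plantedSE` (`data.frame`: `geneId`, `chrom`, `start`, `end`,
#'   `nConstituents`, 0-based half-open region hull).
#' @export
simulateChipseqPeaks <- function(config, genome, truth,
                                 condition = c("model", "ea")) {
  condition <- match.arg(condition)
  genes <- genome$genes
  owners <- truth$genomicOwners[[condition]]

  # typical peaks: common across conditions, placed with at least the
  # stitching distance between any two so each typical region is a single
  # constituent (keeps the planted tail separable; clustered-peak
  # stitching is exercised by the caller's own tests)
  set.seed(stageSeed(config$seed, "typical"))
  n <- config$nTypicalPeaks
  placed <- placeSeparatedPeaks(config, genome, n, minGap = 12501L)
  chrom <- placed$chrom; start <- placed$start; len <- placed$len
  sig <- exp(stats::rnorm(n, config$signalMeanlog, config$signalSdlog))
  cap <- exp(config$signalMeanlog + config$signalSdlog)
  sig <- pmin(sig, cap)
  typical <- data.frame(chrom = chrom, start = start, end = start + len,
                        name = sprintf("typ_%04d", seq_len(n)),
                        sampleSignal = sig,
                        inputSignal = config$inputFraction * sig,
                        stringsAsFactors = FALSE)

  # planted SE clusters, one per owner, owner-keyed layout
  planted <- lapply(owners, function(g)
    plantSECluster(config, genome, g))
  plantedPeaks <- do.call(rbind, lapply(planted, `[[`, "peaks"))
  plantedSE <- do.call(rbind, lapply(planted, `[[`, "region"))
  df <- rbind(typical,
              plantedPeaks[, colnames(typical), drop = FALSE])
  gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end),
                name = df$name, sampleSignal = df$sampleSignal,
                inputSignal = df$inputSignal)
  list(peaks = sortPeaks(gr),
       plantedSE = plantedSE[order(plantedSE$geneId, method = "radix"),
                             , drop = FALSE])
}

# Rejection-sample typical peak positions so that any two peaks are at
# least minGap bases apart (boundary to boundary).
placeSeparatedPeaks <- function(config, genome, n, minGap = 12501L) {
  chroms <- names(genome$chromLengths)
  accS <- stats::setNames(vector("list", length(chroms)), chroms)
  accE <- accS
  chrom <- character(n); start <- integer(n); len <- integer(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(200L)) {
      ch <- sample(chroms, 1L)
      l <- sample(seq(config$typicalPeakLength[1L],
                      config$typicalPeakLength[2L]), 1L)
      s <- sample.int(genome$chromLengths[[ch]] - l - 1L, 1L)
      if (length(accS[[ch]]) &&
          any(s < accE[[ch]] + minGap & s + l > accS[[ch]] - minGap))
        next
      accS[[ch]] <- c(accS[[ch]], s); accE[[ch]] <- c(accE[[ch]], s + l)
      chrom[i] <- ch; start[i] <- s; len[i] <- l
      ok <- TRUE
      break
    }
    if (!ok) stop("could not place ", n, " separated typical peaks; ",
                  "increase the genome size")
  }
  list(chrom = chrom, start = start, len = len)
}

# One planted SE cluster near the owner TSS (+5 kb), re-drawn on collision
# with a non-owner TSS-exclusion window.
plantSECluster <- function(config, genome, ownerGene, tssExclusion = 2500L) {
  genes <- genome$genes
  g <- genes[genes$geneId == ownerGene, , drop = FALSE]
  set.seed(stageSeed(config$seed, paste0("plant_", ownerGene)))
  others <- genes[genes$chrom == g$chrom & genes$geneId != ownerGene,
                  , drop = FALSE]
  median <- exp(config$signalMeanlog)
  for (try in seq_len(100L)) {
    k <- sample(seq(config$seConstituents[1L], config$seConstituents[2L]),
                1L)
    lens <- sample(seq(config$seConstituentLength[1L],
                       config$seConstituentLength[2L]), k, replace = TRUE)
    gaps <- if (k > 1L)
      sample(seq(config$seConstituentGap[1L], config$seConstituentGap[2L]),
             k - 1L, replace = TRUE) else integer()
    start0 <- g$tss + 5000L
    starts <- start0 + cumsum(c(0L, lens[-k] + gaps))
    ends <- starts + lens
    if (ends[k] >= genome$chromLengths[[g$chrom]] - 1L) next
    collide <- any(vapply(seq_len(nrow(others)), function(j)
      any(starts <= others$tss[j] + tssExclusion &
            ends >= others$tss[j] - tssExclusion), logical(1L)))
    if (collide) next
    sig <- rep(median * config$seSignalMultiplier, k)
    return(list(
      peaks = data.frame(chrom = g$chrom, start = starts, end = ends,
                         name = sprintf("se_%s_%02d", ownerGene,
                                        seq_len(k)),
                         sampleSignal = sig,
                         inputSignal = config$inputFraction * sig,
                         stringsAsFactors = FALSE),
      region = data.frame(geneId = ownerGene, chrom = g$chrom,
                          start = starts[1L], end = ends[k],
                          nConstituents = k, stringsAsFactors = FALSE)))
  }
  stop("could not place planted SE for ", ownerGene,
       " after 100 attempts (TSS-exclusion collision)")
}
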