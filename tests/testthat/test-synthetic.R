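test_that("one seed fixes every emitted byte", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulateBundle(smallConfig(seed = 5), outdir = d1)
  simulateBundle(smallConfig(seed = 5), outdir = d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})

test_that("TF flagging uses the floor rule and small genomes error", {
  cfg <- smallConfig(nGenes = 10, tfFraction = 0.3, nClique = 2,
                     nPlantedSE = c(model = 4, ea = 4),
                     plantedShared = 2, seGenesModel = 20,
                     seGenesEa = 10, sharedSEGeneOverlap = 4,
                     candidateOverlap = 5, nUpModel = 40)
  g <- simulateGenome(cfg)
  expect_equal(sum(g$genes$isTF), 3L)

  expect_error(simulateGenome(smallConfig(chromLength = 400000)),
               "do not fit")
})

test_that("planted SE clusters occupy the top stitched signal ranks", {
  cfg <- smallConfig(seed = 31, sequenceScope = "none")
  b <- simulateBundle(cfg)
  res <- callSuperEnhancers(b$peaks$model, b$genome$genes)
  df <- as.data.frame(res$ranked)
  nPlanted <- cfg$nPlantedSE[["model"]]
  topIds <- df$regionId[df$rank <= nPlanted]
  consts <- constituents(res$ranked)
  regIds <- S4Vectors::mcols(enhancerRegions(res$ranked))$regionId
  topPeaks <- unlist(lapply(which(regIds %in% topIds), function(i)
    S4Vectors::mcols(consts[[i]])$name))
  expect_true(all(vapply(topIds, function(id) {
    pk <- S4Vectors::mcols(consts[[match(id, regIds)]])$name
    any(startsWith(pk, "se_"))
  }, logical(1L))))
  # and every planted owner is among the top-ranked regions' genes
  called <- res$assignment$geneId[res$assignment$seId %in% topIds]
  expect_setequal(called, b$truth$genomicOwners$model)
})

test_that("both conditions share typical peaks, differ in planted ownership", {
  cfg <- smallConfig(seed = 41, sequenceScope = "none")
  b <- simulateBundle(cfg)
  typ <- function(pk) {
    t <- pk[startsWith(S4Vectors::mcols(pk)$name, "typ_")]
    data.frame(n = S4Vectors::mcols(t)$name,
               s = GenomicRanges::start(t),
               sig = S4Vectors::mcols(t)$sampleSignal)
  }
  expect_equal(typ(b$peaks$model), typ(b$peaks$ea))
  ownerOf <- function(pk) sort(unique(sub("^se_(G\\d+)_.*", "\\1",
    grep("^se_", S4Vectors::mcols(pk)$name, value = TRUE))))
  expect_setequal(ownerOf(b$peaks$model), b$truth$genomicOwners$model)
  expect_setequal(ownerOf(b$peaks$ea), b$truth$genomicOwners$ea)
  # a shared owner has the identical planted cluster in both files
  shared <- b$truth$genomicOwners$shared[1L]
  seOf <- function(pk) {
    s <- pk[startsWith(S4Vectors::mcols(pk)$name,
                       paste0("se_", shared, "_"))]
    data.frame(start = GenomicRanges::start(s),
               end = GenomicRanges::end(s))
  }
  expect_equal(seOf(b$peaks$model), seOf(b$peaks$ea))
})

test_that("clique SE sequences carry the planted consensus sites", {
  cfg <- smallConfig(seed = 51)   # sequenceScope = "se"
  b <- simulateBundle(cfg)
  for (a in b$truth$clique) {
    nm <- names(b$seSequences)
    own <- b$seSequences[startsWith(nm, paste0("se_", a, "_"))]
    for (m in b$truth$clique) {
      cons <- b$motifs$consensus[[m]]
      found <- sum(vapply(seq_along(own), function(i)
        Biostrings::countPattern(cons, own[[i]]), integer(1L)))
      expect_gte(found, cfg$ownMotifCopies)
    }
  }
})

test_that("the DEG layer realises the planted overlap structure exactly", {
  cfg <- smallConfig(seed = 61, sequenceScope = "none")
  b <- simulateBundle(cfg)
  sets <- filterDEGs(b$deg)
  d <- diffSEGenes(b$truth$seGenes$model, b$truth$seGenes$ea)
  cand <- intersectCandidates(d, sets, "lost_up_model")
  expect_equal(as.character(cand), b$truth$candidates)
  expect_length(cand, cfg$candidateOverlap)
  expect_length(intersectCandidates(d, sets, "gained_up_ea"), 0L)
  expect_length(sets$up, cfg$nUpModel)
  expect_length(sets$down, cfg$nUpEa)
})

test_that("an infeasible candidate overlap is rejected", {
  expect_error(smallConfig(candidateOverlap = 60),
               "candidate_overlap infeasible")
})

test_that("a zero expression effect leaves the key gene exchangeable", {
  cfg <- smallConfig(seed = 71, expressionEffectSD = 0,
                     sequenceScope = "none")
  b <- simulateBundle(cfg)
  m <- b$expression$matrix
  lab <- b$expression$labels
  key <- b$truth$keyGene
  shift <- mean(m[key, lab == "model"]) - mean(m[key, lab != "model"])
  sdv <- stats::sd(m[key, lab != "model"])
  expect_lt(abs(shift), sdv)  # no planted effect beyond noise
})
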