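test_that("stitching honours the gap threshold and TSS exclusion", {
  genes <- makeGenes("chr9", 900000L)  # far away
  pk <- makePeaks("chr1", c(1000L, 14000L), c(2000L, 15000L))
  st <- stitchEnhancers(pk, genes)
  expect_length(st, 1L)  # gap 12000 <= 12500 merges
  expect_equal(GenomicRanges::start(st), 1001L)
  expect_equal(GenomicRanges::end(st), 15000L)

  pk2 <- makePeaks("chr1", c(1000L, 14600L), c(2000L, 15600L))
  expect_length(stitchEnhancers(pk2, genes), 2L)  # gap 12600 > 12500

  g <- makeGenes("chr1", 1000L)
  pk3 <- makePeaks("chr1", 900L, 1100L)
  st3 <- stitchEnhancers(pk3, g)
  expect_true(S4Vectors::mcols(st3)$excluded)
  expect_equal(S4Vectors::mcols(st3)$nConstituents, 1L)

  expect_error(stitchEnhancers(pk, genes, stitchDistance = -1), ">= 0")
})

test_that("stitching equals the brute-force transitive merge oracle", {
  set.seed(101)
  for (rep in seq_len(200)) {
    n <- sample(2:50, 1L)
    chrom <- sample(c("chrA", "chrB"), n, replace = TRUE)
    start <- sample.int(200000L, n)
    end <- start + sample.int(3000L, n)
    df <- data.frame(chrom = chrom, start = start, end = end,
                     stringsAsFactors = FALSE)
    df <- df[!duplicated(df), , drop = FALSE]
    nTss <- sample(0:4, 1L)
    tss <- if (nTss) sort(sample.int(200000L, nTss)) else integer()
    tssChrom <- sample(c("chrA", "chrB"), nTss, replace = TRUE)
    genes <- if (nTss) makeGenes(tssChrom, tss) else NULL
    pk <- makePeaks(df$chrom, df$start, df$end)
    st <- stitchEnhancers(pk, genes)
    oracle <- stitchOracle(df, split(tss, tssChrom))
    got <- S4Vectors::mcols(st)
    merged <- st[!got$excluded]
    gotDf <- data.frame(chrom = as.character(
                          GenomicRanges::seqnames(merged)),
                        start = GenomicRanges::start(merged) - 1L,
                        end = GenomicRanges::end(merged))
    expect_equal(gotDf, oracle$merged, ignore_attr = TRUE)
    expect_equal(sum(got$excluded), nrow(oracle$excluded))
  }
})

test_that("scores are input-subtracted sums clamped at zero, ties stable", {
  genes <- makeGenes("chr9", 1L)
  pk <- makePeaks("chr1", c(100L, 1500L), c(1000L, 2000L),
                  sampleSignal = c(10, 5), inputSignal = c(2, 1))
  rt <- rankEnhancers(stitchEnhancers(pk, genes))
  expect_equal(enhancerScores(rt), 12)  # (10-2) + (5-1)

  pk2 <- makePeaks("chr1", 100L, 1000L, sampleSignal = 1,
                   inputSignal = 5)
  rt2 <- rankEnhancers(stitchEnhancers(pk2, genes))
  expect_equal(enhancerScores(rt2), 0)  # clamped

  pk3 <- makePeaks("chr1", c(50000L, 100L), c(51000L, 1100L),
                   sampleSignal = 12, inputSignal = 0)
  rt3 <- rankEnhancers(stitchEnhancers(pk3, genes))
  df <- as.data.frame(rt3)
  expect_equal(df$start, c(100L, 50000L))  # tie broken by start
  expect_equal(df$rank, 1:2)
})

test_that("the cutoff matches the exhaustive argmin oracle", {
  # exactly linear scores: ties resolve to the largest index, no supers
  cut <- suppressWarnings(findSECutoff(1:10))
  expect_equal(cut@cutoffIndex, 10L)
  expect_equal(nSuper(cut), 0L)

  expect_warning(cutC <- findSECutoff(c(5, 5, 5)), "degenerate")
  expect_equal(nSuper(cutC), 0L)
  expect_true(isDegenerate(cutC))

  set.seed(202)
  for (rep in seq_len(300)) {
    s <- exp(stats::rnorm(sample(3:200, 1L), 1, 1))
    got <- findSECutoff(s)
    want <- cutoffOracle(s)
    expect_equal(got@cutoffIndex, want$cutoffIndex)
    expect_equal(nSuper(got), want$nSuper)
  }
})

test_that("the cutoff converges to the analytic slope-1 tangent point", {
  for (k in c(2, 3, 5)) {
    n <- 1001L
    s <- ((seq_len(n) - 1) / (n - 1))^k
    cut <- findSECutoff(s)
    xStar <- (1 / k)^(1 / (k - 1))
    xHat <- (cut@cutoffIndex - 1) / (n - 1)
    expect_lt(abs(xHat - xStar), 2 / (n - 1))
  }
})

test_that("classification is consistent, monotone and scale-invariant", {
  genes <- makeGenes("chr9", 1L)
  set.seed(11)
  start <- seq(0L, by = 40000L, length.out = 40L)
  pk <- makePeaks("chr1", start, start + 1000L,
                  sampleSignal = c(exp(stats::rnorm(36, 1, 1)),
                                   80, 85, 90, 95))
  rt <- rankEnhancers(stitchEnhancers(pk, genes))
  cut <- findSECutoff(rt)
  cl <- classifySuperEnhancers(rt, cut)
  df <- as.data.frame(cl)
  expect_equal(sum(df$isSuper), nSuper(cut))
  expect_true(all(df$rank[df$isSuper] < min(df$rank[!df$isSuper])))

  # provenance: a cutoff from other data is rejected
  other <- findSECutoff(c(1, 5, 9, 12))
  expect_error(classifySuperEnhancers(rt, other), "not computed from")

  # scale invariance of the normalised geometry
  set.seed(12)
  for (rep in seq_len(100)) {
    s <- exp(stats::rnorm(sample(3:100, 1L), 0, 1.5))
    a <- findSECutoff(s); b <- findSECutoff(3.7 * s)
    expect_equal(a@cutoffIndex, b@cutoffIndex)
    expect_equal(s > cutoffScore(a), 3.7 * s > cutoffScore(b))
  }
})

test_that("nearest-gene assignment matches the exhaustive oracle", {
  g <- makeGenes("chr1", c(150L, 1000L))
  se <- makePeaks("chr1", 100L, 200L)
  S4Vectors::mcols(se)$regionId <- "se1"
  a <- assignNearestGene(se, g)
  expect_equal(a$geneId, "g001")
  expect_equal(a$distance, 0L)  # midpoint 150, tss 150

  g2 <- makeGenes("chr1", c(150L, 250L))
  se2 <- makePeaks("chr1", 0L, 100L)
  S4Vectors::mcols(se2)$regionId <- "se1"
  expect_equal(assignNearestGene(se2, g2)$geneId, "g001")

  # unannotated chromosome stays unassigned
  seX <- makePeaks("chrX", 0L, 100L)
  S4Vectors::mcols(seX)$regionId <- "sex"
  expect_true(is.na(assignNearestGene(seX, g2)$geneId))

  set.seed(303)
  for (rep in seq_len(500)) {
    nG <- sample(1:12, 1L)
    genes <- makeGenes("chr1", sample.int(100000L, nG))
    s <- sample.int(100000L, 1L); e <- s + sample.int(5000L, 1L)
    se <- makePeaks("chr1", s, e)
    S4Vectors::mcols(se)$regionId <- "r"
    got <- assignNearestGene(se, genes)
    want <- nearestOracle("chr1", floor((s + e) / 2), genes)
    expect_equal(got$geneId, want$geneId)
    expect_equal(got$distance, want$distance)
  }
})
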