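test_that("single-base threshold enumeration matches the closed form", {
  pwm <- pwMotif("T1", matrix(c(0.97, 0.01, 0.01, 0.01), 4),
                 pseudocount = 1e-12)
  thr <- pwmThresholdScore(pwm, pThreshold = 0.25)
  expect_equal(thr$tailAtThreshold, 0.25)
  # only 'A' scores above threshold
  hitScore <- thr$intMatrix["A", 1L]
  expect_gte(hitScore, thr$threshold)
  expect_true(all(thr$intMatrix[c("C", "G", "T"), 1L] < thr$threshold))
})

test_that("threshold 1 admits every k-mer", {
  set.seed(5)
  pwm <- randomPWM(4)
  thr <- pwmThresholdScore(pwm, pThreshold = 1)
  # the minimal possible score: every window passes
  expect_equal(thr$threshold, sum(apply(thr$intMatrix, 2L, min)))
  expect_equal(thr$tailAtThreshold, 1)
})

test_that("the DP tail equals exhaustive k-mer enumeration exactly", {
  set.seed(6)
  for (rep in seq_len(20)) {
    w <- sample(1:6, 1L)
    conc <- sample(c(0.5, 1, 5), 1L)
    pwm <- randomPWM(w, concentration = conc)
    bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
    thr <- pwmThresholdScore(pwm, pThreshold = 1e-4, background = bg)
    # enumerate all 4^w k-mers on the same discretised scale
    grid <- as.matrix(expand.grid(rep(list(1:4), w)))
    scores <- vapply(seq_len(nrow(grid)), function(i)
      sum(thr$intMatrix[cbind(grid[i, ], seq_len(w))]), integer(1L))
    for (s in sample(unique(scores), min(10, length(unique(scores))))) {
      expect_equal(secircuit:::pwmTailProbability(thr, s),
                   mean(scores >= s), tolerance = 1e-12)
    }
  }
})

test_that("tail probability is monotone non-increasing in score", {
  set.seed(8)
  pwm <- randomPWM(5)
  thr <- pwmThresholdScore(pwm, pThreshold = 1e-3)
  expect_true(all(diff(thr$tail) <= 1e-15))
})

test_that("scanning finds planted sites on both strands", {
  set.seed(9)
  cons <- "ACGTACGTTA"
  m <- matrix(0.001, 4, 10, dimnames = list(c("A", "C", "G", "T"), NULL))
  b <- strsplit(cons, "")[[1L]]
  m[cbind(match(b, rownames(m)), 1:10)] <- 0.997
  pwm <- pwMotif("TFX", m)
  bgSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")
  fwd <- paste0(substr(bgSeq(60), 1, 10), cons, bgSeq(40))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(cons)))
  rev <- paste0(bgSeq(25), rc, bgSeq(25))
  hits <- scanMotifs(c(s1 = fwd, s2 = rev), list(TFX = pwm))
  h1 <- hits[hits$seId == "s1" & hits$strand == "+", ]
  expect_true(10 %in% h1$offset)
  h2 <- hits[hits$seId == "s2" & hits$strand == "-", ]
  expect_true(25 %in% h2$offset)
})

test_that("short sequences and N bases are handled", {
  pwm <- randomPWM(8)
  expect_equal(nrow(scanMotifs(c(tiny = "ACGT"), list(TF = pwm))), 0L)
  # N scores as the background expectation (log-odds 0), no error
  expect_silent(scanMotifs(c(withN = "ACGTNNNNACGTAGGTAC"),
                           list(TF = pwm)))
})

test_that("the empirical hit rate matches the threshold calibration", {
  set.seed(10)
  pwm <- randomPWM(8, name = "CAL", concentration = 2)
  thr <- pwmThresholdScore(pwm, pThreshold = 1e-4)
  nSeq <- 100L; len <- 2000L
  seqs <- stats::setNames(vapply(seq_len(nSeq), function(i)
    paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""),
    character(1L)), sprintf("s%03d", seq_len(nSeq)))
  hits <- scanMotifs(seqs, list(CAL = pwm), pThreshold = 1e-4)
  nPos <- nSeq * (len - 8L + 1L)
  rate <- nrow(hits) / nPos
  expected <- 2 * thr$tailAtThreshold  # both strands
  se <- sqrt(expected * (1 - expected) / nPos)
  expect_lt(abs(rate - expected), 3 * se + 1e-9)
  # and the discretised tail at threshold is close to the nominal 1e-4
  expect_lt(abs(thr$tailAtThreshold - 1e-4) / 1e-4, 0.2)
})
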