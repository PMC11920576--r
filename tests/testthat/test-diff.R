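test_that("differential SE sets follow the Venn algebra", {
  d <- diffSEGenes(c("a", "b", "c"), c("c", "d"))
  expect_equal(d$lost, c("a", "b"))
  expect_equal(d$gained, "d")
  expect_equal(d$shared, "c")

  same <- diffSEGenes(c("x", "y"), c("y", "x"))
  expect_length(same$lost, 0L)
  expect_length(same$gained, 0L)

  set.seed(99)
  pool <- sprintf("g%04d", 1:500)
  for (rep in seq_len(1000)) {
    m <- sample(pool, sample(0:80, 1L))
    e <- sample(pool, sample(0:80, 1L))
    d <- diffSEGenes(m, e)
    expect_equal(length(d$lost) + length(d$shared), length(unique(m)))
    expect_equal(length(d$gained) + length(d$shared), length(unique(e)))
    expect_length(intersect(d$lost, d$gained), 0L)
    expect_length(intersect(d$lost, d$shared), 0L)
  }
})

test_that("DEG filtering applies the adjusted-p cutoff and strict sign", {
  deg <- data.frame(geneId = c("a", "b", "c", "d"),
                    log2fc = c(1.7, 1.7, 0, -2),
                    pvalue = c(0.001, 0.1, 0.0005, 0.001),
                    qvalue = c(0.01, 0.2, 0.001, 0.04))
  sets <- filterDEGs(deg)
  expect_equal(sets$up, "a")           # q 0.2 fails, lfc 0 fails
  expect_equal(sets$down, "d")
  expect_false("c" %in% c(sets$up, sets$down))  # strict inequality

  degBad <- rbind(deg, data.frame(geneId = "e", log2fc = Inf,
                                  pvalue = 0.001, qvalue = 0.001))
  expect_warning(sets2 <- filterDEGs(degBad), "non-finite")
  expect_equal(sets2$up, "a")
})

test_that("candidate intersection respects the rule and provenance", {
  d <- diffSEGenes(c("a", "b", "c"), character())
  sets <- list(up = c("b", "c", "d"), down = character())
  cand <- intersectCandidates(d, sets, "lost_up_model")
  expect_equal(as.character(cand), c("b", "c"))
  expect_equal(attr(cand, "provenance")$rule, "lost_up_model")

  # the gained x up-after-treatment intersection may legitimately be empty
  empty <- intersectCandidates(d, sets, "gained_up_ea")
  expect_length(empty, 0L)
  expect_error(intersectCandidates(d, sets, "bogus"))
})

test_that("candidates are invariant to ordering and duplication", {
  d1 <- diffSEGenes(c("a", "b", "c", "a"), c("c", "c"))
  d2 <- diffSEGenes(c("c", "b", "a"), "c")
  sets <- list(up = c("b", "a", "b"), down = character())
  expect_equal(as.character(intersectCandidates(d1, sets,
                                                "lost_up_model")),
               as.character(intersectCandidates(d2, sets,
                                                "lost_up_model")))
})
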