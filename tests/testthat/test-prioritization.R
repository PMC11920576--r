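makeExpr <- function(nGenes, nPerGroup, shift = 0, shiftGene = 1L,
                     seed = 1) {
  set.seed(seed)
  labels <- rep(c("model", "ea", "sham"), each = nPerGroup)
  m <- matrix(stats::rnorm(nGenes * length(labels), 20, 3),
              nrow = nGenes,
              dimnames = list(sprintf("g%02d", seq_len(nGenes)), NULL))
  m[shiftGene, labels == "model"] <- m[shiftGene, labels == "model"] +
    shift * 3
  pmax(m, 0)
}

test_that("the error curve is recorded and the smallest adequate forest chosen", {
  # perfectly separable data: every class has its own marker gene
  expr <- makeExpr(5, 15, shift = 0)
  labels <- rep(c("model", "ea", "sham"), each = 15)
  expr[1, labels == "model"] <- expr[1, labels == "model"] + 200
  expr[2, labels == "ea"] <- expr[2, labels == "ea"] + 200
  sel <- selectNtree(expr, labels, maxTrees = 100, seed = 3)
  expect_length(sel$errorByNtree, 100L)
  expect_equal(min(sel$errorByNtree), 0)
  expect_equal(sel$chosenNtree,
               which(sel$errorByNtree == 0)[1L])

  # determinism
  sel2 <- selectNtree(expr, rep(c("model", "ea", "sham"), each = 15),
                      maxTrees = 100, seed = 3)
  expect_identical(sel$errorByNtree, sel2$errorByNtree)

  expect_error(selectNtree(expr, c("a", rep("b", 44))), ">= 2 samples")
})

test_that("permuted labels give the permutation-null error rate", {
  mins <- vapply(seq_len(20), function(s) {
    expr <- makeExpr(10, 10, shift = 0, seed = s)
    set.seed(s)
    labels <- sample(rep(c("model", "ea"), each = 15))
    sel <- selectNtree(expr, labels, maxTrees = 150, seed = s)
    min(sel$errorByNtree)
  }, numeric(1L))
  # balanced two-class null: error about 1 - max class frequency = 0.5
  expect_lt(abs(mean(mins) - 0.5), 0.15)
})

test_that("Gini importance ranks a planted effect first", {
  hits <- vapply(seq_len(10), function(s) {
    expr <- makeExpr(18, 20, shift = 3, shiftGene = 7L, seed = s)
    imp <- rankGenesGini(expr, rep(c("model", "ea", "sham"), each = 20),
                         ntree = 300, seed = s)
    imp$geneId[1L] == "g07"
  }, logical(1L))
  expect_gte(sum(hits), 9L)

  # single feature is trivially rank 1; constant features keep MDG 0
  one <- makeExpr(1, 10, shift = 2)
  imp1 <- rankGenesGini(one, rep(c("model", "ea", "sham"), each = 10),
                        ntree = 50, seed = 1)
  expect_equal(imp1$rank, 1L)
})

test_that("pure-noise features have no stable top gene", {
  tops <- vapply(seq_len(12), function(s) {
    expr <- makeExpr(12, 10, shift = 0, seed = 100 + s)
    imp <- rankGenesGini(expr, rep(c("model", "ea", "sham"), each = 10),
                         ntree = 100, seed = 100 + s)
    imp$geneId[1L]
  }, character(1L))
  expect_lt(max(table(tops)) / length(tops), 0.5)
})

test_that("Wang similarity honours identity, disjointness and bounds", {
  dag <- data.frame(term = c("t1", "t2", "t3", "u1"),
                    parent = c("R1", "R1", "t1", "R2"),
                    type = c("is_a", "is_a", "part_of", "is_a"))
  # identical term sets
  expect_equal(geneSimBMA(c("t1", "t3"), c("t1", "t3"), dag), 1)
  # disjoint roots, no shared ancestors
  expect_equal(termSimWang("t1", "u1", dag), 0)
  # bounded and symmetric
  s <- termSimWang("t1", "t3", dag)
  expect_gt(s, 0); expect_lte(s, 1)
  expect_equal(s, termSimWang("t3", "t1", dag))
})

test_that("the Friends ranking is symmetric and order-invariant", {
  dag <- data.frame(term = sprintf("t%d", 1:6),
                    parent = c("R", "R", "t1", "t1", "t2", "t2"),
                    type = rep(c("is_a", "part_of"), 3))
  ann <- list(gA = c("t1", "t3", "t4"), gB = c("t2", "t5"),
              gC = c("t1", "t2", "t3", "t5"))
  fr <- friendsRank(ann, dag)
  m <- fr$simMatrix
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 3))
  expect_true(all(m >= 0 & m <= 1))
  fr2 <- friendsRank(ann[c(3, 1, 2)], dag)
  expect_equal(fr$ranking, fr2$ranking)

  annBad <- c(ann, list(gD = character()))
  expect_warning(friendsRank(annBad, dag), "unannotated")
})

test_that("a superset-annotated gene attains the maximum mean similarity", {
  cfg <- smallConfig(seed = 21, sequenceScope = "none")
  genome <- simulateGenome(cfg)
  truth <- simulateTruth(cfg, genome$genes)
  onto <- simulateOntology(cfg, truth)
  fr <- friendsRank(onto$annotations, onto$dag)
  expect_equal(fr$ranking$geneId[1L], truth$keyGene)
  # verified against exhaustive pairwise recomputation
  others <- setdiff(names(onto$annotations), truth$keyGene)
  meanKey <- mean(vapply(others, function(g)
    geneSimBMA(onto$annotations[[truth$keyGene]],
               onto$annotations[[g]], onto$dag), numeric(1L)))
  expect_equal(unname(fr$score[truth$keyGene]), meanKey,
               tolerance = 1e-12)
})

test_that("the core-gene intersection follows the top-k rule", {
  rf <- data.frame(geneId = c("H", "A", "I", "Z"), mdg = 4:1,
                   rank = 1:4)
  fr <- data.frame(geneId = c("H", "X", "Y", "Z"), meanSim = 4:1 / 4,
                   rank = 1:4)
  expect_equal(coreGeneIntersection(rf, fr, k = 3), "H")
  fr2 <- data.frame(geneId = c("X", "Y", "W", "H"), meanSim = 4:1 / 4,
                    rank = 1:4)
  expect_warning(none <- coreGeneIntersection(rf, fr2, k = 3),
                 "disjoint")
  expect_length(none, 0L)
  expect_equal(coreGeneIntersection(rf, rf, k = 3),
               sort(c("H", "A", "I")))
  expect_error(coreGeneIntersection(rf, fr, k = 9), "exceeds")
})
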