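test_that("SE-assigned TFs are identified, non-TFs and motif-less dropped", {
  genes <- makeGenes("chr1", c(100L, 200L, 300L),
                     geneId = c("T1", "G1", "T2"),
                     isTF = c(TRUE, FALSE, TRUE))
  assign <- data.frame(seId = c("SE1", "SE2", "SE3"),
                       geneId = c("T1", "G1", "T2"),
                       distance = 0L)
  pwms <- list(T1 = randomPWM(4, "T1"))
  expect_warning(cand <- identifySETFs(assign, genes, pwms), "T2")
  expect_equal(cand$tf, "T1")

  # a TF with two SEs keeps both, flagged multi-SE
  assign2 <- data.frame(seId = c("SE1", "SE4"), geneId = "T1",
                        distance = 0L)
  cand2 <- identifySETFs(assign2, genes, pwms)
  expect_equal(nrow(cand2), 2L)
  expect_true(all(cand2$multiSE))

  empty <- identifySETFs(assign[0, ], genes, pwms)
  expect_equal(nrow(empty), 0L)
})

test_that("self-regulation requires at least three own-motif instances", {
  cand <- data.frame(tf = c("A", "B"), seId = c("SE_A", "SE_B"),
                     multiSE = FALSE)
  hits <- data.frame(tf = c(rep("A", 3), rep("B", 2)),
                     seId = c(rep("SE_A", 3), rep("SE_B", 2)),
                     constituent = 1L, offset = 0L, strand = "+",
                     score = 10, pvalue = 1e-5)
  sr <- detectSelfRegulating(cand, hits, minInstances = 3)
  expect_equal(sr$tf, "A")         # 3 instances retained
  expect_false("B" %in% sr$tf)     # 2 instances excluded
  sr1 <- detectSelfRegulating(cand, hits[5, ], minInstances = 1)
  expect_equal(sr1$tf, "B")        # parameter generalisation
})

test_that("graph edges follow the instance rule; degrees match hand counts", {
  cand <- data.frame(tf = c("A", "B"), seId = c("SE_A", "SE_B"),
                     multiSE = FALSE)
  selfHits <- rbind(
    data.frame(tf = "A", seId = "SE_A"), data.frame(tf = "A", seId = "SE_A"),
    data.frame(tf = "A", seId = "SE_A"),
    data.frame(tf = "B", seId = "SE_B"), data.frame(tf = "B", seId = "SE_B"),
    data.frame(tf = "B", seId = "SE_B"),
    data.frame(tf = "A", seId = "SE_B"), data.frame(tf = "A", seId = "SE_B"),
    data.frame(tf = "A", seId = "SE_B"))
  selfHits$constituent <- 1L
  sr <- detectSelfRegulating(cand, selfHits, 3)
  g <- buildTFGraph(sr, selfHits, cand, 3)
  e <- graphEdges(g)
  cross <- e[e$from != e$to, ]
  expect_equal(nrow(cross), 1L)    # only A -> B, not B -> A
  expect_equal(cross$from, "A")
  expect_equal(unname(inDegree(g)["B"]), 1L)
  expect_equal(unname(outDegree(g)["A"]), 1L)

  # hand-built 4-node graph: degree table matches the hand count
  g4 <- graphFromEdges(c("P", "Q", "R", "S"),
                       from = c("P", "P", "Q", "R", "S"),
                       to   = c("Q", "R", "P", "S", "R"))
  dt <- degreeTable(g4)
  expect_equal(dt$totalDegree[dt$tf == "P"], 3L)  # out 2 + in 1
  expect_equal(dt$totalDegree[dt$tf == "R"], 3L)  # in 2 + out 1
  expect_equal(sum(dt$outDegree), 5L)
})

test_that("circuit enumeration handles triangles and paths", {
  tri <- graphFromEdges(c("A", "B", "C"),
                        from = c("A", "B", "B", "C", "A", "C"),
                        to   = c("B", "A", "C", "B", "C", "A"))
  expect_equal(enumerateCircuits(tri), list(c("A", "B", "C")))

  path <- graphFromEdges(c("A", "B", "C"),
                         from = c("A", "B", "B", "C"),
                         to   = c("B", "A", "C", "B"))
  expect_equal(enumerateCircuits(path),
               list(c("A", "B"), c("B", "C")))
})

test_that("circuit enumeration equals the exhaustive subset oracle", {
  set.seed(404)
  for (rep in seq_len(100)) {
    n <- sample(2:10, 1L)
    nodes <- sprintf("T%02d", seq_len(n))
    adj <- matrix(stats::runif(n * n) < 0.45, n, n)
    diag(adj) <- FALSE
    from <- nodes[row(adj)[adj]]; to <- nodes[col(adj)[adj]]
    g <- graphFromEdges(nodes, from, to)
    got <- enumerateCircuits(g)
    und <- adj & t(adj)
    want <- circuitOracle(nodes, und)
    expect_equal(got, want)
  }
})

test_that("circuit enumeration agrees with igraph maximal cliques", {
  skip_if_not_installed("igraph")
  set.seed(405)
  for (rep in seq_len(50)) {
    n <- sample(3:12, 1L)
    nodes <- sprintf("T%02d", seq_len(n))
    adj <- matrix(stats::runif(n * n) < 0.5, n, n)
    diag(adj) <- FALSE
    from <- nodes[row(adj)[adj]]; to <- nodes[col(adj)[adj]]
    g <- graphFromEdges(nodes, from, to)
    got <- enumerateCircuits(g)
    und <- adj & t(adj)
    ig <- igraph::graph_from_adjacency_matrix(und, mode = "undirected")
    want <- lapply(igraph::max_cliques(ig, min = 2),
                   function(v) sort(nodes[as.integer(v)]))
    want <- want[order(vapply(want, paste, character(1L),
                              collapse = "\r"))]
    expect_equal(got, want)
  }
})

test_that("raising minInstances never adds nodes, edges or circuits", {
  set.seed(406)
  for (rep in seq_len(30)) {
    tfs <- sprintf("T%d", 1:5)
    cand <- data.frame(tf = tfs, seId = paste0("SE_", tfs),
                       multiSE = FALSE)
    nH <- 120L
    hits <- data.frame(tf = sample(tfs, nH, TRUE),
                       seId = sample(cand$seId, nH, TRUE),
                       constituent = 1L)
    res <- lapply(c(1, 3, 5), function(mi) {
      sr <- detectSelfRegulating(cand, hits, mi)
      g <- buildTFGraph(sr, hits, cand, mi)
      list(nodes = length(graphNodes(g)), edges = nrow(graphEdges(g)),
           circuits = length(enumerateCircuits(g)))
    })
    expect_true(res[[1]]$nodes >= res[[2]]$nodes)
    expect_true(res[[2]]$nodes >= res[[3]]$nodes)
    expect_true(res[[1]]$edges >= res[[2]]$edges)
    expect_true(res[[2]]$edges >= res[[3]]$edges)
  }
})

test_that("circuit scoring uses the membership-frequency mean", {
  single <- scoreCircuits(list(c("A", "B", "C")))
  expect_equal(single$table$score, 1)
  expect_equal(single$representative, c("A", "B", "C"))

  two <- scoreCircuits(list(c("A", "B"), c("A", "C")))
  expect_equal(two$table$score, c(0.75, 0.75))
  expect_equal(two$representative, c("A", "B"))  # lexicographic tie

  expect_warning(none <- scoreCircuits(list()), "no fully")
  expect_equal(nrow(none$table), 0L)
})

test_that("every reported circuit member pair is bidirectionally linked", {
  set.seed(407)
  for (rep in seq_len(20)) {
    n <- 8L
    nodes <- sprintf("T%02d", seq_len(n))
    adj <- matrix(stats::runif(n * n) < 0.5, n, n)
    diag(adj) <- FALSE
    g <- graphFromEdges(nodes, nodes[row(adj)[adj]],
                        nodes[col(adj)[adj]])
    e <- graphEdges(g)
    key <- paste(e$from, e$to)
    for (circ in enumerateCircuits(g)) {
      for (a in circ) for (b in setdiff(circ, a)) {
        expect_true(paste(a, b) %in% key)
      }
    }
  }
})
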