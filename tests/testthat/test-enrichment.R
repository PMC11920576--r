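test_that("the hypergeometric upper tail matches the closed form", {
  res <- oraTest(c("g1", "g2"), list(s = paste0("g", 1:5)),
                 paste0("g", 1:10))
  expect_equal(res$pvalue, 10 / 45, tolerance = 1e-12)
  expect_equal(res$k, 2L)

  # zero overlap: upper tail P[X >= 0] = 1
  res0 <- oraTest("g9", list(s = paste0("g", 1:5)), paste0("g", 1:10))
  expect_equal(res0$pvalue, 1)
})

test_that("p-values equal exhaustive enumeration for small universes", {
  set.seed(77)
  for (rep in seq_len(100)) {
    N <- sample(5:30, 1L)
    uni <- sprintf("u%02d", seq_len(N))
    K <- sample(1:N, 1L)
    n <- sample(1:N, 1L)
    set <- sample(uni, K)
    query <- sample(uni, n)
    res <- oraTest(query, list(s = set), uni)
    k <- length(intersect(set, query))
    expect_equal(res$pvalue, hyperOracle(N, K, n, k), tolerance = 1e-12)
  }
})

test_that("p is monotone non-increasing in the overlap", {
  ps <- vapply(0:5, function(k) {
    if (k == 0) return(1)
    stats::phyper(k - 1, 5, 15, 8, lower.tail = FALSE)
  }, numeric(1L))
  expect_true(all(diff(ps) <= 0))
})

test_that("BH adjustment preserves ordering and stays within [p, 1]", {
  set.seed(78)
  uni <- sprintf("u%03d", 1:200)
  sets <- lapply(stats::setNames(1:15, paste0("s", 1:15)),
                 function(i) sample(uni, sample(10:60, 1L)))
  res <- oraTest(sample(uni, 25), sets, uni)
  expect_true(all(res$qvalue >= res$pvalue - 1e-15))
  expect_true(all(res$qvalue <= 1))
  expect_true(!is.unsorted(res$qvalue))  # sorted by p => q non-decreasing
})

test_that("degenerate inputs are rejected", {
  expect_error(oraTest(character(), list(s = "g1"), c("g1", "g2")),
               "empty query")
  expect_error(oraTest("g1", list(s = "g1"), character()),
               "empty universe")
  expect_error(oraTest("zz", list(s = "g1"), c("g1", "g2")),
               "outside the universe")
})
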