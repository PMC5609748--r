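test_that("expression write/read round trip preserves values and layout", {
  set.seed(11)
  expr <- makeExpr(matrix(rnorm(12) * 10, 3, 4))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeExpression(expr, path)
  back <- readExpression(path)
  expect_identical(geneIds(back), geneIds(expr))
  expect_identical(sampleIds(back), sampleIds(expr))
  expect_equal(exprValues(back), exprValues(expr), tolerance = 1e-12)
  expect_identical(attr(back, "droppedRows"), 0L)
})

test_that("malformed expression input is rejected or filtered", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2\ts3",
               "a\t1\t2\t3",
               "a\t4\t5\t6"), path)
  expect_error(readExpression(path), "duplicated gene ids")

  writeLines(c("gene\ts1\ts2\ts3",
               "a\t1\t2\t3",
               "b\t4\t\t6",
               "c\t7\t8\t9"), path)
  expect_message(back <- readExpression(path), "1 row")
  expect_identical(geneIds(back), c("a", "c"))
  expect_identical(attr(back, "droppedRows"), 1L)

  writeLines(c("gene\ts1", "a\t1", "b\t2"), path)
  expect_error(readExpression(path), "at least 2 samples")
})

test_that("preprocessing centers rows, averages replicates before log2", {
  expr <- makeExpr(matrix(c(1, 2, 3,
                            5, 5, 5), 2, 3, byrow = TRUE))
  out <- preprocessExpression(expr)
  expect_equal(exprValues(out)[1, ], c(s1 = -1, s2 = 0, s3 = 1))
  expect_equal(unname(exprValues(out)[2, ]), c(0, 0, 0))
  # centering is idempotent
  expect_equal(exprValues(preprocessExpression(out)), exprValues(out))

  # replicates averaged on the absolute scale, then log2, then centered:
  # gene1 group A = mean(2, 6) = 4 -> log2 = 2; group B = 8 -> log2 = 3
  expr2 <- makeExpr(matrix(c(2, 6, 8,
                             4, 4, 4), 2, 3, byrow = TRUE))
  out2 <- preprocessExpression(
    expr2, replicateMap = c(s1 = "A", s2 = "A", s3 = "B"),
    log2Transform = TRUE)
  expect_equal(unname(exprValues(out2)[1, ]), c(2, 3) - 2.5)
  expect_identical(colnames(exprValues(out2)), c("A", "B"))

  expect_error(
    preprocessExpression(makeExpr(matrix(c(-1, 2, 2, 2), 2)),
                         log2Transform = TRUE),
    "strictly positive")
  expect_error(
    preprocessExpression(expr, replicateMap = c(s1 = "A", s2 = "A")),
    "missing from replicateMap")
})

test_that("sample covariance uses divisor n and demands centered input", {
  expr <- makeExpr(matrix(c(1, 1, -1, -1), 2, 2))  # samples (1,1), (-1,-1)
  S <- sampleCovariance(expr)
  expect_equal(unname(S), matrix(1, 2, 2))

  expect_equal(unname(sampleCovariance(matrix(c(1, -1, 0), 1, 3))),
               matrix(2 / 3))
  expect_equal(unname(sampleCovariance(makeExpr(matrix(0, 2, 3)))),
               matrix(0, 2, 2))
  expect_error(sampleCovariance(makeExpr(matrix(c(1, 2, 3, 4), 2))),
               "centered")
})

test_that("sample covariance equals the brute-force double loop", {
  set.seed(7)
  for (rep in 1:5) {
    v <- matrix(rnorm(20), 5, 4)
    v <- v - rowMeans(v)
    S <- sampleCovariance(makeExpr(v))
    brute <- matrix(0, 5, 5)
    for (i in 1:5) for (k in 1:5)
      brute[i, k] <- sum(v[i, ] * v[k, ]) / 4
    expect_equal(unname(S), brute, tolerance = 1e-12)
  }
})

test_that("edge lists are unordered, self-loop free, and round trip", {
  el <- EdgeList(c("a", "b"), c("b", "a"))
  expect_identical(edgeCount(el), 1L)

  expect_message(loop <- EdgeList("a", "a"), "1 self-loop")
  expect_identical(edgeCount(loop), 0L)
  expect_identical(attr(loop, "droppedSelfLoops"), 1L)

  el3 <- EdgeList(c("a", "a", "b"), c("b", "c", "c"),
                  weight = c(0.1, 0.2, 0.3))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeEdgeList(el3, path)
  back <- readEdgeList(path)
  expect_identical(edgeCount(back), 3L)
  expect_equal(edges(back)[, c("from", "to")], edges(el3)[, c("from", "to")])
  expect_equal(edges(back)$weight, edges(el3)$weight, tolerance = 1e-6)

  writeLines(c("a\tb", "c"), path)
  expect_error(readEdgeList(path), "malformed")
})

test_that("gene intersection preserves target order and drops singletons", {
  t <- makeExpr(matrix(1:12, 3, 4), genes = c("x", "y", "z"))
  r <- makeExpr(matrix(1:8, 2, 4), genes = c("z", "x"))
  both <- intersectGenes(t, r)
  expect_identical(geneIds(both$target), c("x", "z"))
  expect_identical(geneIds(both$related), c("x", "z"))
  r2 <- makeExpr(matrix(1:8, 2, 4), genes = c("q", "w"))
  expect_error(intersectGenes(t, r2), "fewer than 2 genes")
})
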