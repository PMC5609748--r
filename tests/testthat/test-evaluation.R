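test_that("confusion rates follow the four defining formulas", {
  # universe of 10 explicit pairs engineered to give
  # TP = 2, FP = 1, FN = 3, TN = 4
  nodes <- letters[1:6]
  pairs <- data.frame(a = c("a", "a", "a", "a", "a", "b", "b", "b", "c", "c"),
                      b = c("b", "c", "d", "e", "f", "c", "d", "e", "d", "e"))
  gold <- EdgeList(c("a", "a", "b", "b", "c"), c("b", "c", "c", "d", "d"),
                   nodeIds = nodes)
  pred <- EdgeList(c("a", "a", "a"), c("b", "c", "d"), nodeIds = nodes)
  m <- confusionMetrics(pred, gold, pairs = pairs)
  expect_identical(c(m@tp, m@fp, m@fn, m@tn), c(2L, 1L, 3L, 4L))
  expect_equal(m@precision, 2 / 3)
  expect_equal(m@recall, 0.4)
  expect_equal(m@accuracy, 0.6)
  expect_equal(m@specificity, 0.8)
})

test_that("degenerate predictions give the documented limits", {
  gold <- EdgeList(c("a", "a"), c("b", "c"))
  perfect <- confusionMetrics(gold, gold, universe = "all-pairs")
  expect_equal(c(perfect@precision, perfect@recall, perfect@accuracy,
                 perfect@specificity), rep(1, 4))

  none <- EdgeList(nodeIds = c("a", "b", "c"))
  m0 <- confusionMetrics(none, gold, universe = "all-pairs")
  expect_true(is.na(m0@precision))  # undefined, not zero
  expect_equal(m0@recall, 0)
  expect_equal(m0@specificity, 1)
})

test_that("the TF-target universe excludes unrelated pairs", {
  # gold: TFs {a}; nodes {a, b, c, d}; universe = pairs touching a = 3
  gold <- EdgeList(c("a", "a"), c("b", "c"),
                   nodeIds = c("a", "b", "c", "d"), tfIds = "a")
  # b-c lies outside the TF-target universe and never counts
  pred <- EdgeList(c("a", "a", "b"), c("b", "d", "c"))
  m <- confusionMetrics(pred, gold, universe = "tf-target")
  expect_identical(m@universeSize, 3L)
  expect_identical(c(m@tp, m@fp, m@fn, m@tn), c(1L, 1L, 1L, 0L))

  noTf <- EdgeList(c("a"), c("b"))
  noTf@tfIds <- character()
  expect_error(confusionMetrics(pred, noTf), "no regulator ids")

  # gold edges outside an explicit universe are reported and excluded
  expect_message(
    m2 <- confusionMetrics(pred, gold,
                           pairs = data.frame(a = "a", b = "b")),
    "outside the pair universe")
  expect_identical(m2@universeSize, 1L)
  expect_identical(m2@tp, 1L)
})

test_that("confusion counts are permutation invariant and sum correctly", {
  set.seed(77)
  nodes <- paste0("g", 1:12)
  for (rep in 1:5) {
    mk <- function() {
      idx <- which(upper.tri(diag(12)), arr.ind = TRUE)
      sel <- idx[sample(nrow(idx), 10), ]
      EdgeList(nodes[sel[, 1]], nodes[sel[, 2]], nodeIds = nodes)
    }
    gold <- mk(); pred <- mk()
    m <- confusionMetrics(pred, gold, universe = "all-pairs")
    expect_identical(m@tp + m@fp + m@tn + m@fn, m@universeSize)
    expect_identical(m@universeSize, 66L)

    relab <- setNames(sample(nodes), nodes)
    relabel <- function(el) EdgeList(relab[edges(el)$from],
                                     relab[edges(el)$to],
                                     nodeIds = unname(relab))
    m2 <- confusionMetrics(relabel(pred), relabel(gold),
                           universe = "all-pairs")
    expect_identical(c(m@tp, m@fp, m@tn, m@fn), c(m2@tp, m2@fp, m2@tn, m2@fn))
  }
})

test_that("true-positive overlap counts shared edges with the reference", {
  nodes <- letters[1:8]
  gold <- EdgeList(c("a", "a", "b", "c", "d"), c("b", "c", "c", "d", "e"),
                   nodeIds = nodes)
  nets <- list(
    ref = EdgeList(c("a", "a", "b"), c("b", "c", "c"), nodeIds = nodes),
    partial = EdgeList(c("a", "c", "e"), c("b", "d", "f"), nodeIds = nodes),
    disjoint = EdgeList(c("d", "f"), c("e", "g"), nodeIds = nodes))
  tab <- tpOverlap(nets, gold, reference = "ref")
  expect_identical(tab$tp, c(3L, 2L, 1L))
  # reference vs itself overlaps fully; disjoint TP sets overlap 0
  expect_identical(tab$commonWithReference, c(3L, 1L, 0L))
  expect_true(all(tab$commonWithReference <= pmin(tab$tp, tab$tp[1])))
  expect_error(tpOverlap(nets, gold, reference = "nope"), "unknown reference")
})
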