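test_that("partial correlations follow the standardized-precision formula", {
  expect_equal(partialCorrelations(diag(c(2, 3, 4))), diag(1, 3))
  th <- matrix(c(2, -1, -1, 2), 2)
  expect_equal(partialCorrelations(th)[1, 2], 0.5)
  expect_error(partialCorrelations(matrix(c(0, 1, 1, 1), 2)),
               "strictly positive")
  # bounded in [-1, 1] for random SPD matrices
  for (seed in 1:100) {
    r <- partialCorrelations(randomSPD(5, seed = seed))
    expect_true(all(r >= -1 - 1e-10 & r <= 1 + 1e-10))
  }
})

test_that("hard thresholding zeroes strictly-below-threshold entries only", {
  # |pcor| values {0.1, 0.5, 0.9}; the 50th percentile is 0.5, and the
  # keep rule is |rho| >= t, so exactly the 0.1 pair is zeroed
  theta <- matrix(c(1, -0.1, -0.5,
                    -0.1, 1, -0.9,
                    -0.5, -0.9, 1), 3, byrow = TRUE)
  net <- hardThreshold(theta, percentile = 50)
  expect_equal(net@thetaSparse[1, 2], 0)
  expect_equal(net@thetaSparse[1, 3], -0.5)
  expect_equal(net@thetaSparse[2, 3], -0.9)
  expect_equal(diag(net@thetaSparse), diag(theta))  # diagonal untouched
  expect_equal(sum(adjacencyMatrix(net)[upper.tri(theta)]), 2)

  # extreme percentiles: empty and full graphs
  set.seed(3)
  th <- randomSPD(6, seed = 3)
  full <- hardThreshold(th, percentile = 1e-9)
  # the interpolated threshold can graze the single minimum |pcor| entry
  expect_gte(sum(adjacencyMatrix(full)[upper.tri(th)]), 14)
  empty <- hardThreshold(th, percentile = 100 - 1e-9)
  # the maximum |pcor| sits exactly at the ~100th percentile and is kept
  expect_lte(sum(adjacencyMatrix(empty)[upper.tri(th)]), 1)
  expect_error(hardThreshold(th, percentile = 0), "percentile")
})

test_that("EBIC matches hand arithmetic and rejects indefinite candidates", {
  expect_equal(ebicScore(diag(2), diag(2), n = 4, gamma = 0.5), 8)
  th <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(ebicScore(th, diag(2), n = 4, gamma = 0.5),
               -4 * (log(0.75) - 2) + log(4) + 4 * 0.5 * log(2))
  expect_identical(ebicScore(matrix(c(1, 2, 2, 1), 2), diag(2), 4), Inf)
})

test_that("EBIC df equals the network edge count (cross-module check)", {
  dat <- sparseGGMData(10, 40, seed = 4)
  net <- selectThreshold(
    mapPrecision(posteriorUpdate(wishartPrior(diag(10)),
                                 sampleCovariance(dat$expr), 40)),
    sampleCovariance(dat$expr), 40)
  df <- sum(net@thetaSparse[upper.tri(net@thetaSparse)] != 0)
  expect_identical(edgeCount(asEdgeList(net)), as.integer(df))
  expect_identical(sum(adjacencyMatrix(net)[upper.tri(net@adjacency)]),
                   as.numeric(df))
})

test_that("threshold selection minimizes EBIC with sparser tie-breaking", {
  dat <- sparseGGMData(30, 200, seed = 5)
  S <- sampleCovariance(dat$expr)
  theta <- mapPrecision(posteriorUpdate(wishartPrior(diag(30)), S, 200))
  grid <- c(80, 85, 90, 92.5, 95, 97.5, 99)
  net <- selectThreshold(theta, S, 200, percentileGrid = grid)
  # independent exhaustive loop
  vals <- vapply(grid, function(pct)
    ebicScore(hardThreshold(theta, percentile = pct), S, 200), numeric(1))
  expect_equal(net@ebicValue, min(vals))
  expect_equal(net@percentileUsed, max(grid[vals == min(vals)]))

  # duplicated grid entries change nothing
  net2 <- selectThreshold(theta, S, 200, percentileGrid = c(grid, grid))
  expect_equal(net2@percentileUsed, net@percentileUsed)
  expect_equal(net2@thetaSparse, net@thetaSparse)

  # fixed one-point grid is honored regardless of EBIC
  net95 <- selectThreshold(theta, S, 200, percentileGrid = 95)
  expect_equal(net95@percentileUsed, 95)
})

test_that("edge count is non-increasing in the percentile", {
  th <- randomSPD(20, seed = 12)
  counts <- vapply(c(10, 30, 50, 70, 90, 99), function(pct)
    sum(adjacencyMatrix(hardThreshold(th, percentile = pct))) / 2,
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("thresholding commutes with gene reordering", {
  th <- randomSPD(8, seed = 14)
  dimnames(th) <- list(paste0("g", 1:8), paste0("g", 1:8))
  perm <- sample(8)
  net <- hardThreshold(th, percentile = 60)
  netP <- hardThreshold(th[perm, perm], percentile = 60)
  expect_equal(adjacencyMatrix(netP), adjacencyMatrix(net)[perm, perm])
})

test_that("edge extraction reflects the nonzero pattern", {
  net <- hardThreshold(diag(c(1, 2, 3)), percentile = 50)
  expect_identical(edgeCount(asEdgeList(net)), 0L)

  th <- matrix(c(1, -0.6, 0, -0.6, 1, 0, 0, 0, 1), 3)
  dimnames(th) <- list(c("a", "b", "c"), c("a", "b", "c"))
  el <- asEdgeList(hardThreshold(th, percentile = 50))
  expect_identical(edgeCount(el), 1L)
  expect_identical(edges(el)$from, "a")
  expect_identical(edges(el)$to, "b")
  expect_equal(edges(el)$weight, 0.6)
})

test_that("selected networks beat random edge sets of equal size", {
  wins <- 0L
  for (seed in 1:20) {
    dat <- sparseGGMData(30, 200, seed = seed)
    S <- sampleCovariance(dat$expr)
    theta <- mapPrecision(posteriorUpdate(wishartPrior(diag(30)), S, 200))
    net <- selectThreshold(theta, S, 200)
    pred <- asEdgeList(net)
    trueAdj <- (dat$theta != 0) & upper.tri(dat$theta)
    genes <- rownames(dat$theta) <- colnames(dat$theta) <-
      paste0("g", 1:30)
    idx <- which(trueAdj, arr.ind = TRUE)
    gold <- EdgeList(genes[idx[, 1]], genes[idx[, 2]], nodeIds = genes)
    ppv <- metricsTable(confusionMetrics(pred, gold,
                                         universe = "all-pairs"))$precision
    set.seed(seed + 1000)
    allPairs <- which(upper.tri(dat$theta), arr.ind = TRUE)
    rnd <- allPairs[sample(nrow(allPairs), edgeCount(pred)), , drop = FALSE]
    rndEl <- EdgeList(genes[rnd[, 1]], genes[rnd[, 2]], nodeIds = genes)
    ppvRnd <- metricsTable(confusionMetrics(rndEl, gold,
                                            universe = "all-pairs"))$precision
    if (isTRUE(ppv > ppvRnd)) wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})
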