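test_that("normalization scales to the median total, logs and standardizes", {
  ## two cells with totals 100 and 300: median 200, scale factors 2 and 2/3
  counts <- matrix(c(60, 40, 180, 120), 2, 2)
  m <- makeGbm(counts)
  norm <- normalizeMatrix(m)
  expect_equal(unname(norm@scaleFactors), c(2, 2 / 3))
  expect_equal(as.vector(norm@logNorm),
               as.vector(log1p(counts %*% diag(c(2, 2 / 3)))))
  ## this 2x2 example has proportional columns, so scaled rows are
  ## constant: both genes drop as zero-variance
  expect_setequal(norm@droppedGenes, c("G001", "G002"))

  set.seed(51)
  big <- makeGbm(matrix(rpois(600, 4), 20, 30))
  nb <- normalizeMatrix(big)
  expect_true(all(abs(rowMeans(nb@standardized)) < 1e-8))
  expect_true(all(abs(apply(nb@standardized, 1, sd) - 1) < 1e-8))
})

test_that("normalization commutes with column permutation and drops empty
           cells", {
  set.seed(52)
  counts <- matrix(rpois(200, 3), 10, 20)
  counts[, 3] <- 0
  m <- makeGbm(counts)
  expect_warning(norm <- normalizeMatrix(m), "zero total")
  expect_equal(norm@droppedCells, "BC003")

  keep <- counts[, -3]
  perm <- sample(ncol(keep))
  n1 <- normalizeMatrix(makeGbm(keep))
  n2 <- normalizeMatrix(makeGbm(keep[, perm]))
  common <- intersect(rownames(n1@standardized), rownames(n2@standardized))
  expect_equal(n2@standardized[common, ],
               n1@standardized[common, perm], ignore_attr = TRUE)
})

test_that("planted high-dispersion genes are selected", {
  set.seed(53)
  nCells <- 200
  base <- matrix(rpois(190 * nCells, 5), 190, nCells)
  ## same mean (5) but bursty: 0 or 20 with probability 1/4; enough
  ## background per bin that the bin medians stay at the baseline
  hot <- matrix(rbinom(10 * nCells, 1, 0.25) * 20, 10, nCells)
  m <- makeGbm(rbind(base, hot))
  hotIds <- sprintf("G%03d", 191:200)
  top <- selectVariableGenes(m, nTop = 20, nBins = 20)
  expect_true(all(hotIds %in% top))
})

test_that("normalized dispersion matches a brute-force small case and is
           gene-order invariant", {
  set.seed(54)
  counts <- matrix(rpois(40 * 50, rep(exp(runif(40, 0, 3)), 50)), 40, 50)
  m <- makeGbm(counts)
  top <- selectVariableGenes(m, nTop = 40, nBins = 20)
  disp <- attr(top, "dispersion")

  ## independent oracle: plain-loop reimplementation of the stated rule
  totals <- colSums(counts)
  scaled <- counts %*% diag(median(totals) / totals)
  mu <- rowMeans(scaled)
  v <- apply(scaled, 1, var)
  d <- v / mu
  ids <- sprintf("G%03d", 1:40)
  ord <- order(mu, ids)
  bin <- ceiling(match(seq_along(mu), ord) * 20 / 40)
  expected <- numeric(40)
  for (b in 1:20) {
    ii <- which(bin == b)           # two genes per bin
    md <- median(d[ii])
    madd <- median(abs(d[ii] - md)) # over 2 values: half their gap
    expected[ii] <- abs(d[ii] - md) / max(madd, 1e-12)
  }
  expect_equal(unname(disp[ids]), expected)

  perm <- sample(40)
  top2 <- selectVariableGenes(makeGbm(counts[perm, ],
                                      genes = ids[perm]),
                              nTop = 40, nBins = 20)
  expect_identical(as.character(top2), as.character(top))
})

test_that("well-separated clusters are recovered exactly and the scree
           behaves", {
  sim <- simulateExpressionClusters(nClusters = 2, cellsPerCluster = 60,
                                    nGenes = 100, effectSize = 10,
                                    seed = 55)
  norm <- normalizeMatrix(sim$matrix)
  res <- reduceAndCluster(norm, k = 2, nPcs = 10, seed = 1)
  expect_equal(adjustedRand(res@labels, sim$labels[names(res@labels)]), 1)

  ## k = 1: SSE is the total squared distance to the centroid
  res1 <- reduceAndCluster(norm, k = 1, nPcs = 10, seed = 1)
  centred <- sweep(res1@pcs, 2, colMeans(res1@pcs))
  expect_equal(unname(res1@sse["1"]), sum(centred^2))

  ## determinism under the seed
  res2 <- reduceAndCluster(norm, k = 2, nPcs = 10, seed = 1)
  expect_identical(res@labels, res2@labels)
  expect_error(reduceAndCluster(norm, k = 1000, nPcs = 10), "exceeds")
})

test_that("planted markers are recovered exactly and ranked on top", {
  sim <- simulateExpressionClusters(nClusters = 3, cellsPerCluster = 50,
                                    nGenes = 120, markersPerCluster = 5,
                                    effectSize = 10, seed = 56)
  norm <- normalizeMatrix(sim$matrix)
  mk <- clusterMarkerGenes(norm, sim$labels, topN = 5)
  for (cl in names(sim$markers)) {
    expect_setequal(mk$markers[[cl]], sim$markers[[cl]])
  }
  expect_s3_class(mk$dendrogram, "hclust")

  ## identical clusters score zero everywhere
  x <- makeGbm(matrix(rep(rpois(20, 5), 10), 20, 10))
  nx <- suppressWarnings(normalizeMatrix(x))
  labs <- setNames(rep(1:2, each = 5), barcodes(x))
  mk0 <- clusterMarkerGenes(nx, labs)
  expect_true(all(mk0$scores == 0))
})

test_that("reference classification is exact at zero noise and applies the
           subset tie-break once", {
  set.seed(57)
  profiles <- matrix(rgamma(40 * 4, 2), 40, 4,
                     dimnames = list(sprintf("G%03d", 1:40),
                                     c("CD4+ helper", "CD4+ naive",
                                       "NK", "B")))
  refs <- referenceProfileSet(profiles,
                              containment = list(`CD4+ helper` =
                                                   c("CD4+ naive")))
  ## cells that are exact copies of the profiles classify perfectly
  ## (populations without subset relations)
  cells <- profiles[, c("NK", "B", "NK")]
  colnames(cells) <- paste0("c", 1:3)
  labels <- classifyByReference(cells, refs)
  expect_identical(as.character(labels), c("NK", "B", "NK"))

  ## winner CD4+ helper with runner-up CD4+ naive is reassigned
  base <- sort(rgamma(40, 3))
  helper <- base
  naive <- base; naive[c(1, 2)] <- naive[c(2, 1)]
  nk <- rev(base)
  b <- sample(base)
  p2 <- cbind(`CD4+ helper` = helper, `CD4+ naive` = naive, NK = nk, B = b)
  rownames(p2) <- sprintf("G%03d", 1:40)
  refs2 <- referenceProfileSet(p2, containment = list(`CD4+ helper` =
                                                        c("CD4+ naive")))
  cell <- matrix(base, dimnames = list(rownames(p2), "c1"))
  out <- classifyByReference(cell, refs2)
  rho <- attr(out, "correlations")
  expect_equal(colnames(rho)[order(-rho[1, ])][1:2],
               c("CD4+ helper", "CD4+ naive"))
  expect_identical(unname(out[1]), "CD4+ naive")

  ## no reassignment when the runner-up is not a subset of the winner
  refs3 <- referenceProfileSet(p2, containment = list(`CD4+ helper` = "B"))
  out3 <- classifyByReference(cell, refs3)
  expect_identical(unname(out3[1]), "CD4+ helper")
})

test_that("profile comparison finds planted up-regulated genes exactly", {
  set.seed(58)
  a <- matrix(rpois(50 * 30, 8), 50, 30)
  b <- a
  planted <- c(4, 17, 23, 31, 49)
  b[planted, ] <- a[planted, ] * 4
  ga <- makeGbm(a); gb <- makeGbm(b)
  cmp <- compareProfiles(ga, gb, fold = 2)
  expect_setequal(cmp$upGenes, sprintf("G%03d", planted))

  same <- compareProfiles(ga, ga)
  expect_equal(same$r, 1)
  expect_length(same$upGenes, 0)

  ## unrelated random profiles correlate near zero
  set.seed(59)
  x <- makeGbm(matrix(rpois(2000, 5), 100, 20))
  y <- makeGbm(matrix(rpois(2000, 5), 100, 20))
  expect_lt(abs(compareProfiles(x, y)$r), 0.3)
})
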