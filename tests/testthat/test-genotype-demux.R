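test_that("site log-likelihood matches closed forms and is symmetric", {
  expect_equal(siteLogLikelihood(0, 0, "RR"), 0)
  expect_equal(siteLogLikelihood(5, 0, "RR", errorRate = 0.001),
               5 * log(0.999))
  expect_equal(siteLogLikelihood(3, 3, "RA"), log(choose(6, 3) * 0.5^6))
  expect_equal(log(0.3125), siteLogLikelihood(3, 3, "RA"))

  set.seed(61)
  for (i in 1:50) {
    r <- rpois(1, 3); a <- rpois(1, 3)
    expect_equal(siteLogLikelihood(r, a, "RR", 0.01),
                 siteLogLikelihood(a, r, "AA", 0.01))
  }
})

test_that("the K=1 fit equals the per-site pooled posterior oracle", {
  sim <- simulateTwoDonorAlleles(donorSimConfig(nCells = 80,
                                                mixFraction = 0,
                                                nSites = 60,
                                                coveredPerCell = 20,
                                                seed = 2))
  m1 <- fitMixture(sim$counts, K = 1)
  r <- as.matrix(refCounts(sim$counts))
  a <- as.matrix(altCounts(sim$counts))
  for (s in seq_len(nrow(r))) {
    ll <- vapply(1:3, function(g)
      sum(siteLogLikelihood(r[s, ], a[s, ], g, 0.001)[r[s, ] + a[s, ] > 0]),
      numeric(1))
    post <- exp(ll - max(ll)); post <- post / sum(post)
    expect_equal(unname(m1@genotypeProb[s, , 1]), post, tolerance = 1e-8)
  }
})

test_that("two cells separated by one deep discriminating site get
           opposite confident assignments", {
  ref <- matrix(c(30, 0), 1, 2)
  alt <- matrix(c(0, 30), 1, 2)
  acp <- AlleleCountPair(ref, alt, sites = "chr1:1:A:G",
                         cells = c("c1", "c2"))
  m <- fitMixture(acp, K = 2, mixtureParams(nIterations = 300,
                                            nBurnin = 100), seed = 4)
  expect_false(m@cellMap[1] == m@cellMap[2])
  expect_true(all(m@cellMapProb > 0.99))
})

test_that("relabelling undoes constructed label switching", {
  set.seed(62)
  p <- c(rep(0.95, 40), rep(0.05, 60))
  P <- matrix(rep(p, each = 80), 80, 100)
  P <- P + matrix(rnorm(8000, 0, 0.01), 80, 100)
  P <- pmin(pmax(P, 0.001), 0.999)
  flipped <- P
  even <- seq(2, 80, by = 2)
  flipped[even, ] <- 1 - flipped[even, ]
  rel <- relabelChain(flipped)
  expect_true(rel$converged)
  ## the even iterations are flipped back (up to one global swap)
  expect_true(identical(rel$flips, seq_len(80) %in% even) ||
                identical(rel$flips, !(seq_len(80) %in% even)))
  q <- colMeans(rel$assignProb)
  expect_true(max(abs(q - p)) < 0.05 || max(abs((1 - q) - p)) < 0.05)

  ## a chain with no switching gets identity permutations
  relId <- relabelChain(P)
  expect_false(any(relId$flips))

  ## globally permuting the labels permutes the result, nothing more
  relSwap <- relabelChain(1 - P)
  expect_equal(relSwap$assignProb, 1 - relId$assignProb,
               tolerance = 1e-12)
})

test_that("model selection applies the strict 90%/75% rule", {
  k1 <- makeModelK1(100)
  allSure <- makeModelK2(rep(1, 100))
  expect_equal(selectModel(k1, allSure)$K, 2L)
  unsure <- makeModelK2(rep(0.5, 100))
  expect_equal(selectModel(k1, unsure)$K, 1L)
  ## 89 confident cells out of 100 miss the 90% requirement
  boundary <- makeModelK2(c(rep(0.9, 89), rep(0.6, 11)))
  expect_equal(selectModel(k1, boundary)$K, 1L)
  exact <- makeModelK2(c(rep(0.9, 90), rep(0.6, 10)))
  expect_equal(selectModel(k1, exact)$K, 2L)
})

test_that("genotype overlap counts agreement over shared sites", {
  g1 <- setNames(c(1L, 2L, 3L, 1L), paste0("s", 1:4))
  expect_equal(genotypeOverlap(g1, g1), 100)
  g2 <- setNames(c(2L, 3L, 1L, 2L), paste0("s", 1:4))
  expect_equal(genotypeOverlap(g1, g2), 0)
  expect_error(genotypeOverlap(g1, setNames(1L, "sX")), "no shared")

  ## generator truth: unrelated donors agree at the configured IBS rate
  sim <- simulateTwoDonorAlleles(donorSimConfig(nCells = 10, nSites = 2000,
                                                coveredPerCell = 5,
                                                ibs = 0.73, seed = 63))
  sites <- rownames(sim$counts)
  ov <- genotypeOverlap(setNames(sim$truth$genotypes[, 1], sites),
                        setNames(sim$truth$genotypes[, 2], sites))
  se <- 100 * sqrt(0.73 * 0.27 / 2000)
  expect_lt(abs(ov - 73), 2 * se + 1e-9)

  simSame <- simulateTwoDonorAlleles(donorSimConfig(nCells = 10,
                                                    nSites = 500,
                                                    coveredPerCell = 5,
                                                    ibs = 1, seed = 64))
  expect_equal(genotypeOverlap(
    setNames(simSame$truth$genotypes[, 1], rownames(simSame$counts)),
    setNames(simSame$truth$genotypes[, 2], rownames(simSame$counts))),
    100)
})

test_that("demultiplexing evaluation reports sensitivity, PPV and the
           called fraction", {
  truth <- rep(c("B", "C"), c(70, 30))
  perfect <- makeModelK2(rep(1, 100), map = rep(c(1L, 2L), c(70, 30)))
  ev <- evaluateDemux(truth, perfect)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$ppv, 1)
  expect_equal(ev$calledMixFraction, 0.3)

  ## K = 1 means the mixture was not detected
  ev1 <- evaluateDemux(truth, makeModelK1(100))
  expect_false(ev1$detected)
  expect_true(is.na(ev1$sensitivity))

  ## random assignments at the truth fraction give PPV near the fraction
  set.seed(65)
  n <- 4000; f <- 0.3
  truthBig <- rep(c("B", "C"), c(n * (1 - f), n * f))
  randMap <- ifelse(runif(n) < f, 2L, 1L)
  evr <- evaluateDemux(truthBig, makeModelK2(rep(1, n), map = randMap))
  expect_equal(evr$ppv, f, tolerance = 0.12)
})

test_that("group-exclusive SNV selection applies quality and support
           filters", {
  nCells <- 20
  groupA <- sprintf("A%02d", 1:10)
  groupB <- sprintf("B%02d", 1:10)
  sites <- sprintf("s%02d", 1:16)
  alt <- matrix(0, 16, nCells, dimnames = list(sites, c(groupA, groupB)))
  alt[1:5, 1:6] <- 4      # A-exclusive, well supported
  alt[6:10, 11:16] <- 4   # B-exclusive
  alt[11:15, c(1:4, 11:14)] <- 4  # shared
  alt[16, 1:6] <- 4       # A-exclusive but low qual
  qual <- setNames(rep(150, 16), sites)
  qual["s16"] <- 99
  acp <- AlleleCountPair(matrix(1, 16, nCells), alt,
                         sites = sites, cells = c(groupA, groupB))
  sel <- selectDiscriminatingSnvs(acp, qual, groupA, groupB)
  expect_setequal(sel$groupA, sites[1:5])
  expect_setequal(sel$groupB, sites[6:10])

  ## support thresholds: one supporting cell or too few UMIs
  alt2 <- alt
  alt2[1, ] <- 0
  alt2[1, 1] <- 12        # one cell only
  alt2[2, ] <- 0
  alt2[2, 1:6] <- 1       # 6 UMIs < 10
  acp2 <- AlleleCountPair(matrix(1, 16, nCells), alt2,
                          sites = sites, cells = c(groupA, groupB))
  sel2 <- selectDiscriminatingSnvs(acp2, qual, groupA, groupB)
  expect_setequal(sel2$groupA, sites[3:5])
})

test_that("SNV-fraction labelling flags the multiplet band and doubles the
           rate", {
  out <- snvLabelCells(c(10, 5, 0, 3), c(0, 5, 10, 0))
  expect_identical(unname(out$labels), c("A", "multiplet", "B", "A"))

  ## zero counts are unassigned and excluded from the denominator
  out2 <- snvLabelCells(c(10, 0), c(0, 0))
  expect_identical(unname(out2$labels), c("A", "unassigned"))
  expect_equal(out2$multipletFraction, 0)

  ## constructed 1:1 mix with injected cross-group doublets
  set.seed(66)
  n <- 2000
  crossRate <- 0.015   # half of a 3% doublet rate is cross-group
  isCross <- runif(n) < crossRate
  aCnt <- ifelse(isCross, rpois(n, 6) + 1,
                 ifelse(seq_len(n) %% 2 == 0, rpois(n, 12) + 5, 0))
  bCnt <- ifelse(isCross, rpois(n, 6) + 1,
                 ifelse(seq_len(n) %% 2 == 0, 0, rpois(n, 12) + 5))
  res <- snvLabelCells(aCnt, bCnt)
  ci <- qbinom(c(0.025, 0.975), n, crossRate) / n
  expect_gte(res$multipletFraction, ci[1])
  expect_lte(res$multipletFraction, ci[2])
  expect_equal(res$inferredMultipletRate, 2 * res$multipletFraction)
})

test_that("the sampler is deterministic given the seed and recovers a
           balanced mixture", {
  sim <- simulateTwoDonorAlleles(donorSimConfig(nCells = 400,
                                                mixFraction = 0.5,
                                                nSites = 200, seed = 6))
  p <- mixtureParams(nIterations = 300, nBurnin = 100)
  mA <- fitMixture(sim$counts, K = 2, p, seed = 9)
  mB <- fitMixture(sim$counts, K = 2, p, seed = 9)
  expect_identical(mA@cellProb, mB@cellProb)
  expect_identical(mA@genotypeProb, mB@genotypeProb)

  ev <- evaluateDemux(sim$truth$donor, mA)
  acc <- max(mean((mA@cellMap == 1) == (sim$truth$donor == 1)),
             mean((mA@cellMap == 2) == (sim$truth$donor == 1)))
  expect_gt(acc, 0.99)
})

test_that("a pure single-donor sample selects K = 1 across seeds", {
  p <- mixtureParams(nIterations = 300, nBurnin = 100)
  k1Count <- 0L
  for (s in 1:10) {
    sim <- simulateTwoDonorAlleles(donorSimConfig(nCells = 600,
                                                  mixFraction = 0,
                                                  seed = 100 + s))
    sel <- selectModel(fitMixture(sim$counts, K = 1),
                       fitMixture(sim$counts, K = 2, p, seed = s))
    k1Count <- k1Count + (sel$K == 1L)
  }
  expect_gte(k1Count, 9L)
})
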