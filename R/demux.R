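## Genotype-free demultiplexing: binomial mixture over per-cell SNV
## allele counts, Gibbs inference, Stephens relabelling, model selection
## and downstream comparisons.

GENOTYPES <- c("RR", "RA", "AA")

genotypeAltProb <- function(genotype, errorRate) {
  g <- if (is.character(genotype)) match(genotype, GENOTYPES)
       else as.integer(genotype)
  if (any(is.na(g) | g < 1L | g > 3L)) stop("genotype must be RR, RA or AA")
  c(errorRate, 0.5, 1 - errorRate)[g]
}

#' Binomial log-likelihood of allele counts under a genotype
#'
#' The alt-allele count at a site is modelled as Binomial(n = ref + alt,
#' p), where p is the fixed error rate for R/R, 0.5 for R/A and one minus
#' the error rate for A/A. Vectorized over `r`, `a`.
#'
#' @param r,a reference and alternate UMI counts (non-negative).
#' @param genotype `"RR"`, `"RA"`, `"AA"` (or 1:3).
#' @param errorRate fixed allele observation error (default 0.001).
#' @return log-likelihood; 0 for sites with no coverage (r + a = 0).
#' @export
siteLogLikelihood <- function(r, a, genotype, errorRate = 0.001) {
  stopifnot(all(r >= 0), all(a >= 0))
  p <- genotypeAltProb(genotype, errorRate)
  lchoose(r + a, a) + a * log(p) + r * log1p(-p)
}

## covered triplets (0-based site/cell) with per-genotype logliks
alleleTriplets <- function(counts, errorRate) {
  r <- methods::as(refCounts(counts), "TsparseMatrix")
  a <- methods::as(altCounts(counts), "TsparseMatrix")
  keyR <- r@i + as.numeric(r@j) * nrow(r)
  keyA <- a@i + as.numeric(a@j) * nrow(a)
  uk <- sort(unique(c(keyR, keyA)))
  rv <- numeric(length(uk)); av <- numeric(length(uk))
  rv[match(keyR, uk)] <- r@x
  av[match(keyA, uk)] <- a@x
  keep <- rv + av > 0
  uk <- uk[keep]; rv <- rv[keep]; av <- av[keep]
  list(site = as.integer(uk %% nrow(r)),
       cell = as.integer(uk %/% nrow(r)),
       r = rv, a = av,
       ll = cbind(siteLogLikelihood(rv, av, 1L, errorRate),
                  siteLogLikelihood(rv, av, 2L, errorRate),
                  siteLogLikelihood(rv, av, 3L, errorRate)))
}

## Spectral seed for the K = 2 chain: per-site Pearson residuals of the
## alt-allele fraction carry a rank-one signature of a second genotype
## (cells of the second donor deviate coherently at discriminating
## sites). Power iteration extracts the leading singular pair; a 1-D
## 2-means split of the per-cell score seeds the genome assignment.
## When no second genotype is present the leading direction is noise and
## the split is arbitrary, so the chain collapses to the symmetric mode
## and the model-selection rule falls back to K = 1.
spectralInitZ <- function(tri, nSites, nCells, nSweeps = 30L) {
  n <- tri$r + tri$a
  num <- rowsum(tri$a, tri$site)
  den <- rowsum(n, tri$site)
  phat <- setNames((num[, 1L] + 0.5) / (den[, 1L] + 1), rownames(num))
  p <- phat[as.character(tri$site)]
  x <- (tri$a - n * p) / sqrt(n * p * (1 - p))
  s1 <- tri$site + 1L
  c1 <- tri$cell + 1L
  v <- stats::rnorm(nSites)
  v <- v / sqrt(sum(v^2))
  u <- numeric(nCells)
  for (i in seq_len(nSweeps)) {
    u[] <- 0
    uu <- rowsum(x * v[s1], c1)
    u[as.integer(rownames(uu))] <- uu[, 1L]
    nu <- sqrt(sum(u^2))
    if (nu == 0) break
    u <- u / nu
    v[] <- 0
    vv <- rowsum(x * u[c1], s1)
    v[as.integer(rownames(vv))] <- vv[, 1L]
    nv <- sqrt(sum(v^2))
    if (nv == 0) break
    v <- v / nv
  }
  if (length(unique(u)) < 2L)
    return(sample.int(2L, nCells, replace = TRUE) - 1L)
  ## deterministic 1-D Lloyd split seeded at the extremes
  centers <- range(u)
  for (i in 1:100) {
    grp <- as.integer(abs(u - centers[2L]) < abs(u - centers[1L])) + 1L
    if (length(unique(grp)) < 2L) break
    new <- c(mean(u[grp == 1L]), mean(u[grp == 2L]))
    if (isTRUE(all.equal(new, centers))) break
    centers <- new
  }
  minor <- which.min(tabulate(grp, 2L))
  as.integer(grp == minor)
}

#' Stephens relabelling of a two-genome Gibbs chain
#'
#' Mixture posteriors are invariant under permutation of the genome
#' labels, so a chain may switch labels between sweeps. Following
#' Stephens' decision-theoretic scheme, per-iteration label permutations
#' (for K = 2, flip or keep) are chosen to minimize the Kullback-Leibler
#' divergence between each iteration's cell-assignment probabilities and
#' their running average, iterating until the permutations stabilize.
#'
#' @param assignProb iterations x cells matrix of the per-iteration
#'   conditional probability that each cell belongs to genome 1.
#' @param maxRounds maximum relabelling passes (default 100).
#' @return list: `assignProb` (relabelled), `flips` (logical per
#'   iteration), `rounds`, `converged`.
#' @export
relabelChain <- function(assignProb, maxRounds = 100L) {
  P <- assignProb
  nIt <- nrow(P)
  flips <- rep(FALSE, nIt)
  converged <- FALSE
  rounds <- 0L
  eps <- 1e-12
  for (round in seq_len(maxRounds)) {
    rounds <- round
    Pcur <- P
    Pcur[flips, ] <- 1 - Pcur[flips, ]
    q <- pmin(pmax(colMeans(Pcur), eps), 1 - eps)
    lq <- log(q); l1q <- log1p(-q)
    ## KL to the average, up to the (flip-invariant) entropy term
    cost0 <- -(P %*% lq + (1 - P) %*% l1q)
    cost1 <- -((1 - P) %*% lq + P %*% l1q)
    newFlips <- as.vector(cost1 < cost0)
    if (identical(newFlips, flips)) {
      converged <- TRUE
      break
    }
    flips <- newFlips
  }
  if (!converged) warning("relabelling did not stabilize after ",
                          maxRounds, " rounds")
  P[flips, ] <- 1 - P[flips, ]
  list(assignProb = P, flips = flips, rounds = rounds,
       converged = converged)
}

#' Fit the K-genome binomial mixture by Gibbs sampling
#'
#' For K = 1 the posterior factorizes over sites (uniform genotype
#' prior), so the per-site genotype posterior is the normalized
#' pooled-count likelihood, computed in closed form. For K = 2 a Gibbs
#' sampler alternates cell-to-genome assignment and per-genome genotype
#' updates; `nChains` independent chains are relabelled per Stephens,
#' aligned to each other, and merged. Posteriors are post-burn-in sample
#' frequencies. Genotypes are initialized at the pooled per-site MAP and
#' assignments at random; the run is reproducible given `seed`.
#'
#' @param counts an [AlleleCountPair-class].
#' @param K number of genomes, 1 or 2.
#' @param params a [MixtureParams-class].
#' @param seed RNG seed.
#' @return A [GenotypeModel-class].
#' @export
fitMixture <- function(counts, K = 2L, params = mixtureParams(), seed = 1L) {
  K <- as.integer(K)
  stopifnot(K %in% c(1L, 2L))
  nSites <- nrow(counts)
  nCells <- ncol(counts)
  tri <- alleleTriplets(counts, params@errorRate)
  if (!length(tri$site)) stop("no covered sites")
  sites <- rownames(counts)
  cells <- colnames(counts)

  ## pooled per-site log-likelihoods (K = 1 posterior; K = 2 init)
  pooled <- matrix(0, nSites, 3L)
  for (g in 1:3) {
    s <- rowsum(tri$ll[, g], tri$site)
    pooled[as.integer(rownames(s)) + 1L, g] <- s[, 1L]
  }

  if (K == 1L) {
    w <- exp(pooled - apply(pooled, 1L, max))
    post <- w / rowSums(w)
    gp <- array(post, dim = c(nSites, 3L, 1L),
                dimnames = list(sites, GENOTYPES, NULL))
    return(methods::new("GenotypeModel", K = 1L, genotypeProb = gp,
                        cellProb = matrix(1, nCells, 1L,
                                          dimnames = list(cells, NULL)),
                        cellMap = setNames(rep(1L, nCells), cells),
                        cellMapProb = setNames(rep(1, nCells), cells),
                        mixtureFraction = 0,
                        diagnostics = list(seed = as.integer(seed),
                                           closedForm = TRUE)))
  }

  set.seed(seed)
  chains <- vector("list", params@nChains)
  for (ch in seq_len(params@nChains)) {
    zInit <- spectralInitZ(tri, nSites, nCells)
    ## each genome's genotypes start at the pooled MAP of its seed cells
    gInit <- matrix(max.col(pooled, ties.method = "first") - 1L,
                    nrow = nSites, ncol = K)
    for (k in seq_len(K)) {
      inK <- zInit[tri$cell + 1L] == k - 1L
      if (!any(inK)) next
      llK <- matrix(0, nSites, 3L)
      for (g in 1:3) {
        s <- rowsum(tri$ll[inK, g], tri$site[inK])
        llK[as.integer(rownames(s)) + 1L, g] <- s[, 1L]
      }
      seen <- rowSums(llK != 0) > 0
      gInit[seen, k] <- max.col(llK[seen, , drop = FALSE],
                                ties.method = "first") - 1L
    }
    raw <- gibbs_mixture_chain(tri$site, tri$cell, tri$ll, nSites, nCells,
                               K, params@nIterations, params@nBurnin,
                               zInit, gInit)
    rel <- relabelChain(raw$p1)
    z <- raw$z
    z[rel$flips, ] <- 1L - z[rel$flips, ]
    gmat <- raw$g  # nKeep x (nSites*K), genome index fastest
    if (any(rel$flips)) {
      swap <- rel$flips
      g1 <- seq(1L, nSites * K, by = K)
      gmat[swap, ] <- gmat[swap, c(rbind(g1 + 1L, g1))]
    }
    chains[[ch]] <- list(z = z, p = rel$assignProb, g = gmat,
                         relabel = rel[c("rounds", "converged")])
  }
  ## align chains by their mean assignment probabilities
  refP <- colMeans(chains[[1L]]$p)
  for (ch in seq_along(chains)[-1L]) {
    p <- colMeans(chains[[ch]]$p)
    if (sum(abs(p - refP)) > sum(abs((1 - p) - refP))) {
      chains[[ch]]$p <- 1 - chains[[ch]]$p
      chains[[ch]]$z <- 1L - chains[[ch]]$z
      g1 <- seq(1L, nSites * K, by = K)
      chains[[ch]]$g <- chains[[ch]]$g[, c(rbind(g1 + 1L, g1))]
    }
  }
  zAll <- do.call(rbind, lapply(chains, `[[`, "z"))
  gAll <- do.call(rbind, lapply(chains, `[[`, "g"))

  cellProb <- cbind(colMeans(zAll == 0L), colMeans(zAll == 1L))
  dimnames(cellProb) <- list(cells, NULL)
  cellMap <- max.col(cellProb, ties.method = "first")
  cellMapProb <- cellProb[cbind(seq_len(nCells), cellMap)]

  gp <- array(0, dim = c(nSites, 3L, K),
              dimnames = list(sites, GENOTYPES, NULL))
  for (k in seq_len(K)) {
    cols <- seq(k, nSites * K, by = K)
    sub <- gAll[, cols, drop = FALSE]
    for (g in 1:3) gp[, g, k] <- colMeans(sub == g - 1L)
  }
  frac <- min(mean(cellMap == 1L), mean(cellMap == 2L))
  chainAgree <- if (length(chains) > 1L)
    1 - mean(abs(colMeans(chains[[1L]]$p) - colMeans(chains[[2L]]$p)))
    else NA_real_
  methods::new("GenotypeModel", K = 2L, genotypeProb = gp,
               cellProb = cellProb,
               cellMap = setNames(cellMap, cells),
               cellMapProb = setNames(cellMapProb, cells),
               mixtureFraction = frac,
               diagnostics = list(seed = as.integer(seed),
                                  relabel = lapply(chains, `[[`, "relabel"),
                                  chainAgreement = chainAgree))
}

#' Choose between the one- and two-genome models
#'
#' The two-genome model is selected only when at least
#' `cellFractionThreshold` (default 90%) of cells have a MAP-genome
#' posterior strictly above `posteriorThreshold` (default 0.75);
#' otherwise the mixture is below the detection level and K = 1 is
#' returned.
#'
#' @param modelK1,modelK2 [GenotypeModel-class] fits on the same counts.
#' @param params a [MixtureParams-class].
#' @return list: `K` (1 or 2), `model` (the chosen fit),
#'   `confidentFraction`.
#' @export
selectModel <- function(modelK1, modelK2, params = mixtureParams()) {
  stopifnot(modelK1@K == 1L, modelK2@K == 2L)
  confident <- mean(modelK2@cellMapProb > params@posteriorThreshold)
  if (confident >= params@cellFractionThreshold)
    list(K = 2L, model = modelK2, confidentFraction = confident)
  else
    list(K = 1L, model = modelK1, confidentFraction = confident)
}

#' MAP genotypes of one genome
#'
#' @param model a [GenotypeModel-class].
#' @param genome genome index.
#' @return named integer vector (1 = R/R, 2 = R/A, 3 = A/A) over the
#'   sites whose posterior is informative (not exactly uniform).
#' @export
mapGenotypes <- function(model, genome = 1L) {
  p <- model@genotypeProb[, , genome]
  if (is.null(dim(p))) p <- matrix(p, ncol = 3L)
  g <- max.col(p, ties.method = "first")
  defined <- p[cbind(seq_len(nrow(p)), g)] > 1 / 3 + 1e-9
  setNames(g, rownames(model@genotypeProb))[defined]
}

#' Percent genotype overlap between two genotype sets
#'
#' Over the SNV sites shared between the two sets (both with a defined
#' MAP genotype), the percentage at which the genotypes agree. Used to
#' match an inferred genotype group against a pure reference sample
#' (same-individual pairs sit near 98%, unrelated pairs near 73%).
#'
#' @param a,b named genotype vectors as from [mapGenotypes()] (or
#'   [GenotypeModel-class] objects, taking genome 1).
#' @return percent agreement over shared sites.
#' @export
genotypeOverlap <- function(a, b) {
  if (methods::is(a, "GenotypeModel")) a <- mapGenotypes(a)
  if (methods::is(b, "GenotypeModel")) b <- mapGenotypes(b)
  shared <- intersect(names(a), names(b))
  if (!length(shared)) stop("no shared SNV sites with defined genotypes")
  100 * mean(a[shared] == b[shared])
}

#' Evaluate a demultiplexing call against simulation truth
#'
#' The minor population is the smaller predicted genome. Sensitivity and
#' PPV are computed for minor-population membership against the true
#' labels; when the selected model is K = 1 the mixture was not detected
#' and both are reported as `NA`.
#'
#' @param truth per-cell true donor labels (two values; the rarer one is
#'   the true minor population).
#' @param selection result of [selectModel()], or a
#'   [GenotypeModel-class] with K = 2.
#' @return list: `detected`, `sensitivity`, `ppv`, `calledMixFraction`.
#' @export
evaluateDemux <- function(truth, selection) {
  model <- if (methods::is(selection, "GenotypeModel")) selection
           else selection$model
  if (model@K == 1L)
    return(list(detected = FALSE, sensitivity = NA_real_, ppv = NA_real_,
                calledMixFraction = 0))
  minorGenome <- which.min(tabulate(model@cellMap, nbins = 2L))
  predMinor <- model@cellMap == minorGenome
  ## pair genomes with truth classes by overall agreement (the pairing is
  ## only ambiguous in a perfectly balanced mixture)
  classes <- sort(unique(truth))
  agree1 <- mean((model@cellMap == minorGenome) == (truth == classes[1L]))
  trueMinorClass <- if (agree1 >= 0.5) classes[1L] else classes[2L]
  trueMinor <- truth == trueMinorClass
  tp <- sum(predMinor & trueMinor)
  list(detected = TRUE,
       sensitivity = tp / sum(trueMinor),
       ppv = if (any(predMinor)) tp / sum(predMinor) else NA_real_,
       calledMixFraction = mean(predMinor))
}

#' Select SNVs exclusive to one of two known cell groups
#'
#' High-quality SNVs (site QUAL, total supporting UMIs and supporting
#' cell count thresholds) observed in exactly one of two disjoint cell
#' groups — the cell-line variant of SNV-based cell labelling.
#'
#' @param counts an [AlleleCountPair-class]; a site is "observed" in a
#'   cell when its alt-allele UMI count is positive.
#' @param siteQual named per-site calling quality.
#' @param groupA,groupB disjoint cell barcode sets.
#' @param minQual minimum site QUAL (default 100).
#' @param minUmi minimum total supporting UMIs (default 10).
#' @param minCells minimum supporting cells (default 2).
#' @return list: `groupA`, `groupB` (site keys exclusive to each group).
#' @export
selectDiscriminatingSnvs <- function(counts, siteQual, groupA, groupB,
                                     minQual = 100, minUmi = 10,
                                     minCells = 2) {
  if (length(intersect(groupA, groupB)))
    stop("cell groups must be disjoint")
  alt <- altCounts(counts)
  qual <- siteQual[rownames(alt)]
  umiTotal <- Matrix::rowSums(alt)
  cellSupport <- Matrix::rowSums(alt > 0)
  pass <- !is.na(qual) & qual >= minQual & umiTotal >= minUmi &
    cellSupport >= minCells
  inA <- Matrix::rowSums(alt[, groupA, drop = FALSE] > 0) > 0
  inB <- Matrix::rowSums(alt[, groupB, drop = FALSE] > 0) > 0
  list(groupA = rownames(alt)[pass & inA & !inB],
       groupB = rownames(alt)[pass & inB & !inA])
}

#' Label cells by their group-enriched SNV fractions
#'
#' With per-cell counts of group-A-enriched and group-B-enriched SNV
#' observations, the fraction `f = B / (A + B)` labels the cell A when
#' `f < low`, B when `f > high`, and multiplet in between. Cells with no
#' counts are `"unassigned"` and excluded from the rate denominator. The
#' inferred multiplet rate doubles the observed multiplet fraction to
#' account for unobservable same-group multiplets.
#'
#' @param aCounts,bCounts per-cell SNV observation counts.
#' @param low,high multiplet band (defaults 0.2 and 0.8, inclusive).
#' @return list: `labels` (`"A"`, `"B"`, `"multiplet"`, `"unassigned"`),
#'   `multipletFraction`, `inferredMultipletRate`.
#' @export
snvLabelCells <- function(aCounts, bCounts, low = 0.2, high = 0.8) {
  tot <- aCounts + bCounts
  f <- ifelse(tot > 0, bCounts / tot, NA_real_)
  labels <- ifelse(is.na(f), "unassigned",
                   ifelse(f < low, "A", ifelse(f > high, "B", "multiplet")))
  if (!is.null(names(aCounts))) names(labels) <- names(aCounts)
  assigned <- labels != "unassigned"
  mf <- if (any(assigned)) mean(labels[assigned] == "multiplet") else NA_real_
  list(labels = labels, multipletFraction = mf,
       inferredMultipletRate = if (is.na(mf)) NA_real_ else min(1, 2 * mf))
}
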