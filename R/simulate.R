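## Seeded synthetic-data generators with truth tables. Every pipeline
## input can be generated here, so the whole package is testable without
## external data.

#' Read-simulation configuration
#'
#' Describes the generative process for aligned-read records: one GEM per
#' cell, negative-binomial UMI totals per cell, genes drawn from
#' population-specific weights, optional doublets (a GEM capturing a
#' second cell), ambient molecules (drawn from the pooled gene
#' distribution of all populations), per-base substitution errors on
#' barcode and UMI with a two-level quality model (Q30 everywhere, Q10 at
#' error positions, so the posterior correction path is exercised
#' deterministically), and PCR read duplication.
#'
#' @param populations named list; each element is
#'   `list(nCells =, genes = named weight vector, species = optional tag)`.
#' @param umiMean,umiDispersion negative-binomial mean and size of
#'   per-cell UMI totals (defaults 300 and 10; the size-10 NB gives a
#'   coefficient of variation in the ~33-43% range observed for cell
#'   lines).
#' @param whitelistSize designed barcodes to simulate (default 2000).
#' @param barcodeLength,umiLength defaults 14 and 10 (5 supported).
#' @param errorRate per-base substitution probability on barcodes and
#'   UMIs (default 0).
#' @param ambientFraction fraction of molecules drawn from the ambient
#'   pool (default 0).
#' @param doubletRate probability a GEM captures a second cell
#'   (default 0).
#' @param readsPerMolecule mean reads per molecule, >= 1; the excess is
#'   Poisson (default 1.5, so PCR duplicates exist).
#' @param mappedFraction fraction of reads confidently mapped to a gene
#'   (default 1; the rest get MAPQ 50 and no gene).
#' @param seed mandatory RNG seed.
#' @return a classed configuration list for [simulateReads()].
#' @export
readSimConfig <- function(populations, umiMean = 300, umiDispersion = 10,
                          whitelistSize = 2000, barcodeLength = 14,
                          umiLength = 10, errorRate = 0,
                          ambientFraction = 0, doubletRate = 0,
                          readsPerMolecule = 1.5, mappedFraction = 1,
                          seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(errorRate >= 0, errorRate <= 1,
            ambientFraction >= 0, ambientFraction <= 1,
            doubletRate >= 0, doubletRate <= 1,
            readsPerMolecule >= 1, mappedFraction >= 0, mappedFraction <= 1)
  structure(list(populations = populations, umiMean = umiMean,
                 umiDispersion = umiDispersion,
                 whitelistSize = whitelistSize,
                 barcodeLength = barcodeLength, umiLength = umiLength,
                 errorRate = errorRate, ambientFraction = ambientFraction,
                 doubletRate = doubletRate,
                 readsPerMolecule = readsPerMolecule,
                 mappedFraction = mappedFraction,
                 seed = as.integer(seed)),
            class = "ReadSimConfig")
}

## distinct UMIs for one GEM; within each gene group, pairwise Hamming
## distance > 1 and no homopolymers, so the truth table is exact under
## the pipeline's UMI rules
sampleUmis <- function(n, genes, len) {
  umis <- randomSeq(n, len)
  for (tries in 1:50) {
    bad <- logical(n)
    bad[umis == strrep(substr(umis, 1, 1), len)] <- TRUE
    bad[duplicated(umis)] <- TRUE
    for (ii in split(seq_len(n), genes)) {
      if (length(ii) < 2L) next
      chars <- strsplit(umis[ii], "", fixed = TRUE)
      for (x in seq_along(ii)[-1L]) {
        for (y in seq_len(x - 1L)) {
          if (sum(chars[[x]] != chars[[y]]) <= 1L) bad[ii[x]] <- TRUE
        }
      }
    }
    if (!any(bad)) break
    umis[bad] <- randomSeq(sum(bad), len)
  }
  umis
}

## inject substitution errors; qualities Q30, Q10 at error positions
injectErrors <- function(seqs, rate, len) {
  quals <- rep(strrep(intToPhred(30), len), length(seqs))
  if (rate > 0) {
    nErr <- rbinom(length(seqs), len, rate)
    hit <- which(nErr > 0)
    for (i in hit) {
      pos <- sample.int(len, nErr[i])
      s <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
      q <- rep(30L, len)
      for (p in pos) {
        s[p] <- sample(DNA_BASES[DNA_BASES != s[p]], 1L)
        q[p] <- 10L
      }
      seqs[i] <- paste(s, collapse = "")
      quals[i] <- intToPhred(q)
    }
  }
  list(seq = seqs, qual = quals)
}

#' Simulate aligned-read records with full truth bookkeeping
#'
#' @param config a [readSimConfig()] object.
#' @return list: `records` (data.frame as from [readAlignedRecords()]),
#'   `whitelist` (a [BarcodeWhitelist-class]), `truth` (list:
#'   `matrix` — the exact molecule-level [GeneBarcodeMatrix-class];
#'   `cells` — per-barcode population(s) and doublet flag; `reads` —
#'   per-read true barcode/UMI/gene).
#' @export
simulateReads <- function(config) {
  stopifnot(inherits(config, "ReadSimConfig"))
  set.seed(config$seed)
  pops <- config$populations
  nCellsPop <- vapply(pops, function(p) p$nCells, 0)
  nGems <- sum(nCellsPop)
  if (config$whitelistSize < nGems)
    stop("whitelist smaller than the number of cells")
  wlSeqs <- unique(randomSeq(config$whitelistSize * 1.05,
                             config$barcodeLength))[
    seq_len(config$whitelistSize)]
  gemBarcodes <- sample(wlSeqs, nGems)

  popNames <- names(pops)
  gemPop <- rep(popNames, nCellsPop)
  doublet <- runif(nGems) < config$doubletRate
  secondPop <- rep(NA_character_, nGems)
  secondPop[doublet] <- sample(popNames, sum(doublet), replace = TRUE,
                               prob = nCellsPop / nGems)

  geneOf <- function(pop) names(pops[[pop]]$genes)
  allGenes <- unique(unlist(lapply(pops, function(p) names(p$genes))))
  ambientW <- numeric(length(allGenes))
  names(ambientW) <- allGenes
  for (p in popNames) {
    w <- pops[[p]]$genes / sum(pops[[p]]$genes)
    ambientW[names(w)] <- ambientW[names(w)] + w * nCellsPop[p]
  }
  ambientW <- ambientW / sum(ambientW)

  recs <- vector("list", nGems)
  truthMol <- vector("list", nGems)
  for (g in seq_len(nGems)) {
    nPer <- rnbinom(1L, mu = config$umiMean, size = config$umiDispersion)
    members <- c(gemPop[g], if (doublet[g]) secondPop[g])
    if (doublet[g])
      nPer <- nPer + rnbinom(1L, mu = config$umiMean,
                             size = config$umiDispersion)
    if (nPer == 0L) next
    memberOfMol <- sample(members, nPer, replace = TRUE)
    genes <- vapply(memberOfMol, function(p) {
      w <- pops[[p]]$genes
      sample(names(w), 1L, prob = w)
    }, "")
    amb <- runif(nPer) < config$ambientFraction
    if (any(amb))
      genes[amb] <- sample(allGenes, sum(amb), replace = TRUE,
                           prob = ambientW)
    umis <- sampleUmis(nPer, genes, config$umiLength)
    nReads <- 1L + rpois(nPer, config$readsPerMolecule - 1)
    mol <- data.frame(barcode = gemBarcodes[g], umi = umis, gene = genes,
                      stringsAsFactors = FALSE)
    truthMol[[g]] <- mol
    recs[[g]] <- mol[rep(seq_len(nPer), nReads), , drop = FALSE]
  }
  truthMol <- do.call(rbind, truthMol)
  reads <- do.call(rbind, recs)
  reads <- reads[sample.int(nrow(reads)), , drop = FALSE]

  bc <- injectErrors(reads$barcode, config$errorRate, config$barcodeLength)
  um <- injectErrors(reads$umi, config$errorRate, config$umiLength)
  mapped <- runif(nrow(reads)) < config$mappedFraction
  records <- data.frame(
    barcode_seq = bc$seq, barcode_quals = bc$qual,
    umi_seq = um$seq, umi_quals = um$qual,
    gene_id = ifelse(mapped, reads$gene, NA_character_),
    mapq = ifelse(mapped, 255L, 50L),
    sample_index = "S1", run_id = "run1",
    stringsAsFactors = FALSE, row.names = NULL)

  genesSorted <- sort(allGenes)
  bcs <- sort(unique(truthMol$barcode))
  tm <- Matrix::sparseMatrix(
    i = match(truthMol$gene, genesSorted),
    j = match(truthMol$barcode, bcs),
    x = rep(1, nrow(truthMol)),
    dims = c(length(genesSorted), length(bcs)))
  species <- NULL
  if (all(grepl("^[^:]+:", genesSorted)))
    species <- sub(":.*$", "", genesSorted)
  truthMatrix <- GeneBarcodeMatrix(tm, genes = genesSorted, barcodes = bcs,
                                   species = species)
  cells <- data.frame(barcode = gemBarcodes, population = gemPop,
                      doublet = doublet, second_population = secondPop,
                      stringsAsFactors = FALSE)
  list(records = records, whitelist = barcodeWhitelist(wlSeqs),
       truth = list(matrix = truthMatrix, cells = cells,
                    reads = data.frame(true_barcode = reads$barcode,
                                       true_umi = reads$umi,
                                       true_gene = reads$gene,
                                       stringsAsFactors = FALSE)))
}

#' Two-donor allele-count simulation configuration
#'
#' Emulates the statistical structure of per-cell SNV allele counts from
#' a mixture of two individuals: per-site alt allele frequencies uniform
#' on \[0.1, 0.9\], Hardy-Weinberg genotypes within each donor, the
#' second donor copying the first at an identity-by-state fraction of
#' sites (0.73 by default, the unrelated-individual baseline; 0.98
#' emulates a same-individual replicate), sparse per-cell site coverage
#' (~50 covered sites per cell by default) with 1 + Poisson(1) UMIs per
#' covered site, and binomial allele observations with a fixed error
#' rate.
#'
#' @param nCells cells (default 6000).
#' @param mixFraction minor-donor fraction in \[0, 1\].
#' @param nSites SNV sites (default 500).
#' @param ibs fraction of sites at which the two donors share a genotype
#'   (default 0.73).
#' @param coveredPerCell mean covered sites per cell (default 50).
#' @param umiPerSite mean UMIs at a covered site (default 2; the draw is
#'   1 + Poisson(umiPerSite - 1), support 1 upward).
#' @param errorRate allele observation error (default 0.001).
#' @param afRange alt allele frequency range (default c(0.1, 0.9)).
#' @param seed mandatory RNG seed.
#' @return a classed configuration list for [simulateTwoDonorAlleles()].
#' @export
donorSimConfig <- function(nCells = 6000, mixFraction = 0.5, nSites = 500,
                           ibs = 0.73, coveredPerCell = 50, umiPerSite = 2,
                           errorRate = 0.001, afRange = c(0.1, 0.9), seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(mixFraction >= 0, mixFraction <= 1, ibs >= 0, ibs <= 1,
            coveredPerCell <= nSites, umiPerSite >= 1)
  structure(list(nCells = nCells, mixFraction = mixFraction,
                 nSites = nSites, ibs = ibs,
                 coveredPerCell = coveredPerCell, umiPerSite = umiPerSite,
                 errorRate = errorRate, afRange = afRange,
                 seed = as.integer(seed)),
            class = "DonorSimConfig")
}

#' Simulate per-cell SNV allele counts for a two-donor mixture
#'
#' @param config a [donorSimConfig()] object.
#' @return list: `counts` (an [AlleleCountPair-class]), `truth` (list:
#'   `donor` per-cell labels, `genotypes` sites x 2 integer matrix
#'   (1 = R/R, 2 = R/A, 3 = A/A), `af` per-site alt frequencies).
#' @export
simulateTwoDonorAlleles <- function(config) {
  stopifnot(inherits(config, "DonorSimConfig"))
  set.seed(config$seed)
  nS <- config$nSites
  nC <- config$nCells
  af <- runif(nS, config$afRange[1L], config$afRange[2L])
  hw <- cbind((1 - af)^2, 2 * af * (1 - af), af^2)
  g1 <- vapply(seq_len(nS), function(s)
    sample.int(3L, 1L, prob = hw[s, ]), 0L)
  g2 <- g1
  differ <- runif(nS) >= config$ibs
  for (s in which(differ)) {
    p <- hw[s, ]
    p[g1[s]] <- 0
    g2[s] <- sample.int(3L, 1L, prob = p)
  }
  G <- cbind(g1, g2)

  nMinor <- round(config$mixFraction * nC)
  donor <- c(rep(2L, nMinor), rep(1L, nC - nMinor))
  donor <- donor[sample.int(nC)]

  covRate <- config$coveredPerCell / nS
  nCov <- rbinom(nC, nS, covRate)
  siteIdx <- unlist(lapply(nCov, function(n) sample.int(nS, n)))
  cellIdx <- rep(seq_len(nC), nCov)
  nUmi <- 1L + rpois(length(siteIdx), config$umiPerSite - 1)
  pAlt <- c(config$errorRate, 0.5, 1 - config$errorRate)[
    G[cbind(siteIdx, donor[cellIdx])]]
  alt <- rbinom(length(siteIdx), nUmi, pAlt)
  ref <- nUmi - alt

  refAlt <- sample(DNA_BASES, 2L)  # cosmetic site keys
  sites <- sprintf("chr1:%d:%s:%s", seq_len(nS) * 100L,
                   refAlt[1L], refAlt[2L])
  cells <- sprintf("CELL%05d", seq_len(nC))
  refM <- Matrix::sparseMatrix(i = siteIdx, j = cellIdx, x = ref,
                               dims = c(nS, nC))
  altM <- Matrix::sparseMatrix(i = siteIdx, j = cellIdx, x = alt,
                               dims = c(nS, nC))
  counts <- AlleleCountPair(refM, altM, sites = sites, cells = cells)
  list(counts = counts,
       truth = list(donor = setNames(donor, cells), genotypes = G,
                    af = af))
}

#' Simulate an expression matrix with planted clusters and markers
#'
#' Baseline negative-binomial expression shared by all cells, with each
#' cluster's marker genes up-regulated by a common fold change.
#'
#' @param nClusters number of clusters.
#' @param cellsPerCluster cells per cluster (scalar or vector).
#' @param nGenes total genes (default 200).
#' @param markersPerCluster planted markers per cluster (default 5).
#' @param effectSize marker fold change (default 8).
#' @param baselineMean mean counts per gene (default 2).
#' @param dispersion negative-binomial size (default 10).
#' @param seed mandatory RNG seed.
#' @return list: `matrix` (a [GeneBarcodeMatrix-class]), `labels`
#'   (per-cell true cluster), `markers` (per-cluster gene sets).
#' @export
simulateExpressionClusters <- function(nClusters, cellsPerCluster,
                                       nGenes = 200, markersPerCluster = 5,
                                       effectSize = 8, baselineMean = 2,
                                       dispersion = 10, seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  if (length(cellsPerCluster) == 1L)
    cellsPerCluster <- rep(cellsPerCluster, nClusters)
  stopifnot(nGenes >= nClusters * markersPerCluster)
  nCells <- sum(cellsPerCluster)
  genes <- sprintf("GENE%04d", seq_len(nGenes))
  cells <- sprintf("CELL%05d", seq_len(nCells))
  labels <- rep(seq_len(nClusters), cellsPerCluster)
  markers <- lapply(seq_len(nClusters), function(c)
    genes[(c - 1L) * markersPerCluster + seq_len(markersPerCluster)])
  names(markers) <- as.character(seq_len(nClusters))
  mu <- matrix(baselineMean, nGenes, nCells)
  for (c in seq_len(nClusters)) {
    mi <- match(markers[[c]], genes)
    mu[mi, labels == c] <- baselineMean * effectSize
  }
  counts <- matrix(rnbinom(nGenes * nCells, mu = mu, size = dispersion),
                   nGenes, nCells)
  m <- GeneBarcodeMatrix(Matrix::Matrix(counts, sparse = TRUE),
                         genes = genes, barcodes = cells)
  list(matrix = m, labels = setNames(labels, cells), markers = markers)
}
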