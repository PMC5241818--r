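## Cell calling from the total-UMI distribution, usable-read and capture
## metrics, and library merging/downsampling.

#' Call cell-containing barcodes from the UMI count distribution
#'
#' Let `n = max(1, round(0.01 * expectedCells))`, the rank of the barcode
#' anchoring the top of the distribution, and `T` the total UMI count of
#' the rank-`n` barcode (descending totals, ties broken by barcode lexical
#' order). All barcodes whose total strictly exceeds `0.10 * T` — i.e.
#' within the same order of magnitude as the top barcodes — are called
#' cells.
#'
#' @param object a [GeneBarcodeMatrix-class].
#' @param expectedCells expected recovered cell count (>= 1).
#' @return A [CellSet-class].
#' @export
callCells <- function(object, expectedCells) {
  stopifnot(expectedCells >= 1)
  totals <- Matrix::colSums(umiCounts(object))
  if (!length(totals)) stop("matrix has no barcodes")
  n <- max(1L, round(0.01 * expectedCells))
  if (n > length(totals)) {
    warning("rank ", n, " exceeds the ", length(totals),
            " available barcodes; using the last barcode")
    n <- length(totals)
  }
  o <- order(-totals, names(totals))
  top <- unname(totals[o][n])
  thr <- 0.10 * top
  called <- names(totals)[totals > thr]
  methods::new("CellSet", calledBarcodes = called,
               expectedCells = as.integer(expectedCells),
               thresholdUmi = thr, totals = totals)
}

#' Fraction of usable reads
#'
#' The product of the four per-stage fractions: reads with (1) a valid
#' barcode, (2) a valid UMI, (3) association with a called cell barcode
#' and (4) confident exonic mapping.
#'
#' @param validBarcode,validUmi,cellAssociated,confidentlyMapped fractions
#'   in \[0, 1\].
#' @return their product.
#' @export
usableReadsFraction <- function(validBarcode, validUmi, cellAssociated,
                                confidentlyMapped) {
  m <- c(validBarcode, validUmi, cellAssociated, confidentlyMapped)
  if (any(!is.finite(m)) || any(m < 0 | m > 1))
    stop("all four metrics must be fractions in [0, 1]")
  prod(m)
}

#' Cell capture efficiency
#'
#' Ratio of cells detected by sequencing to cells loaded. Values above 1
#' indicate a counting error and are flagged with a warning but returned.
#'
#' @param cellsDetected,cellsLoaded counts; `cellsLoaded > 0`.
#' @return the ratio.
#' @export
captureEfficiency <- function(cellsDetected, cellsLoaded) {
  stopifnot(cellsLoaded > 0, cellsDetected >= 0)
  r <- cellsDetected / cellsLoaded
  if (r > 1) warning("capture efficiency above 1: check cell counts")
  r
}

#' Merge gene-barcode matrices from multiple channels
#'
#' Barcode-wise concatenation of matrices sharing one gene list. Barcodes
#' colliding across inputs are disambiguated by "-1", "-2", ... suffixes
#' (GEM-group style); totals are preserved.
#'
#' @param matrices list of [GeneBarcodeMatrix-class] objects.
#' @return A merged [GeneBarcodeMatrix-class].
#' @export
mergeLibraries <- function(matrices) {
  stopifnot(length(matrices) >= 1L)
  g <- geneIDs(matrices[[1L]])
  for (m in matrices[-1L]) {
    if (!identical(geneIDs(m), g))
      stop("gene lists differ between matrices")
  }
  bcs <- lapply(matrices, barcodes)
  flat <- unlist(bcs, use.names = FALSE)
  if (anyDuplicated(flat)) {
    bcs <- lapply(seq_along(bcs), function(i)
      if (length(bcs[[i]])) paste0(bcs[[i]], "-", i) else bcs[[i]])
    flat <- unlist(bcs, use.names = FALSE)
  }
  counts <- do.call(cbind, lapply(matrices, umiCounts))
  sp <- geneSpecies(matrices[[1L]])
  GeneBarcodeMatrix(counts, genes = g, barcodes = flat, species = sp)
}

#' Merge record streams from multiple sequencing runs
#'
#' Concatenates the streams and removes duplicates across runs: the
#' duplicate key is (barcode, UMI, gene), never the run, so a molecule
#' sequenced in two runs is counted once.
#'
#' @param streams list of record data.frames from the same library.
#' @return list as from [markDuplicates()].
#' @export
mergeRuns <- function(streams) {
  markDuplicates(do.call(rbind, streams))
}

#' Downsample a matrix to a target mean UMI count per cell
#'
#' Each cell's retained molecules are drawn without replacement
#' (multivariate hypergeometric across its genes): cell `j` keeps
#' `round(rate * total_j)` of its `total_j` molecules, where
#' `rate = target / mean(totals)` (or is given directly). Seeded and
#' reproducible.
#'
#' @param object a [GeneBarcodeMatrix-class].
#' @param targetMeanPerCell target mean total UMI per cell (ignored when
#'   `rate` is given).
#' @param seed RNG seed.
#' @param rate optional retention rate in \[0, 1\].
#' @return A downsampled [GeneBarcodeMatrix-class].
#' @export
downsampleMatrix <- function(object, targetMeanPerCell = NULL, seed = 1L,
                             rate = NULL) {
  m <- umiCounts(object)
  totals <- Matrix::colSums(m)
  if (is.null(rate)) {
    if (is.null(targetMeanPerCell))
      stop("give targetMeanPerCell or rate")
    cur <- mean(totals)
    if (targetMeanPerCell > cur)
      stop("target ", targetMeanPerCell, " exceeds current mean ", cur)
    rate <- if (cur > 0) targetMeanPerCell / cur else 0
  }
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 1) return(object)
  set.seed(seed)
  out <- methods::as(m, "TsparseMatrix")
  for (j in seq_len(ncol(m))) {
    idx <- which(out@j == j - 1L)
    if (!length(idx)) next
    nKeep <- round(rate * totals[j])
    counts <- out@x[idx]
    if (nKeep <= 0) {
      out@x[idx] <- 0
    } else if (nKeep < sum(counts)) {
      ## without-replacement draw across the cell's molecules
      mol <- rep(seq_along(idx), counts)
      kept <- tabulate(sample(mol, nKeep), nbins = length(idx))
      out@x[idx] <- kept
    }
  }
  GeneBarcodeMatrix(Matrix::drop0(out), genes = geneIDs(object),
                    barcodes = barcodes(object),
                    species = geneSpecies(object))
}
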