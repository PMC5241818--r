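## Expression normalization and dispersion-based variable-gene selection.

#' Normalize a UMI count matrix
#'
#' Counts are scaled per cell to the median total (`count / cell_total *
#' median(cell_totals)`), log-transformed as `ln(1 + x)` (the pseudocount
#' handles zeros), and finally each gene is standardized to mean 0 and
#' standard deviation 1 across cells. Genes with no UMI in any cell are
#' removed; cells with zero total are dropped with a warning;
#' zero-variance genes are excluded from the standardized matrix and
#' listed.
#'
#' @param object a [GeneBarcodeMatrix-class] (or sparse genes x cells
#'   matrix).
#' @return A [NormalizedMatrix-class].
#' @export
normalizeMatrix <- function(object) {
  m <- if (methods::is(object, "GeneBarcodeMatrix")) umiCounts(object)
       else methods::as(object, "CsparseMatrix")
  totals <- Matrix::colSums(m)
  droppedCells <- colnames(m)[totals == 0]
  if (length(droppedCells)) {
    warning(length(droppedCells), " cell(s) with zero total dropped")
    m <- m[, totals > 0, drop = FALSE]
    totals <- totals[totals > 0]
  }
  if (!ncol(m)) stop("no cell with a nonzero total")
  detected <- Matrix::rowSums(m) > 0
  droppedGenes <- rownames(m)[!detected]
  m <- m[detected, , drop = FALSE]
  sf <- median(totals) / totals
  scaled <- m %*% Matrix::Diagonal(x = sf)
  dimnames(scaled) <- dimnames(m)
  logNorm <- scaled
  logNorm@x <- log1p(logNorm@x)
  dense <- as.matrix(logNorm)
  mu <- rowMeans(dense)
  sdv <- apply(dense, 1L, stats::sd)
  zeroVar <- sdv == 0
  droppedGenes <- c(droppedGenes, rownames(dense)[zeroVar])
  std <- (dense[!zeroVar, , drop = FALSE] - mu[!zeroVar]) / sdv[!zeroVar]
  methods::new("NormalizedMatrix", logNorm = logNorm, standardized = std,
               scaleFactors = setNames(sf, colnames(m)),
               geneMeans = mu[!zeroVar], geneSds = sdv[!zeroVar],
               droppedGenes = droppedGenes, droppedCells = droppedCells)
}

#' Select highly variable genes by normalized dispersion
#'
#' Dispersion (variance / mean) is computed per gene on median-scaled —
#' not log-transformed, not standardized — counts. Genes are placed into
#' `nBins` equal-frequency bins by mean expression, and the normalized
#' dispersion is the absolute difference between a gene's dispersion and
#' the median dispersion of its bin, divided by the bin's raw median
#' absolute deviation of dispersions (zero MAD guarded by 1e-12). The top
#' `nTop` genes by normalized dispersion are returned; ties and gene
#' order are resolved by gene ID, so the selection is invariant to input
#' gene order.
#'
#' @param object a [GeneBarcodeMatrix-class] (or sparse genes x cells
#'   matrix).
#' @param nTop number of genes to return (default 1000).
#' @param nBins number of mean-expression bins (default 20).
#' @return character vector of gene IDs, ranked; the `dispersion`
#'   attribute carries the named normalized dispersions of all scored
#'   genes.
#' @export
selectVariableGenes <- function(object, nTop = 1000, nBins = 20) {
  m <- if (methods::is(object, "GeneBarcodeMatrix")) umiCounts(object)
       else methods::as(object, "CsparseMatrix")
  totals <- Matrix::colSums(m)
  keepCells <- totals > 0
  m <- m[, keepCells, drop = FALSE]
  totals <- totals[keepCells]
  sf <- median(totals) / totals
  scaled <- m %*% Matrix::Diagonal(x = sf)
  mu <- Matrix::rowMeans(scaled)
  ex2 <- Matrix::rowMeans(scaled^2)
  v <- (ex2 - mu^2) * ncol(scaled) / max(1, ncol(scaled) - 1)
  keep <- mu > 0
  if (sum(keep) < nBins)
    stop("need at least ", nBins, " genes with nonzero mean")
  ids <- rownames(m)[keep]
  mu <- mu[keep]
  d <- v[keep] / mu
  ## equal-frequency bins by mean; ranks tie-broken by gene ID for
  ## order invariance
  r <- rank(mu, ties.method = "first")
  ord <- order(mu, ids)
  r <- match(seq_along(mu), ord)  # rank with ID tie-break
  bin <- ceiling(r * nBins / length(mu))
  dprime <- numeric(length(d))
  for (b in unique(bin)) {
    ii <- bin == b
    medD <- median(d[ii])
    madD <- median(abs(d[ii] - medD))
    dprime[ii] <- abs(d[ii] - medD) / max(madD, 1e-12)
  }
  names(dprime) <- ids
  sel <- ids[order(-dprime, ids)]
  out <- head(sel, nTop)
  attr(out, "dispersion") <- dprime
  out
}
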