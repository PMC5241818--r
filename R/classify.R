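## Correlation-based cell classification against purified reference
## profiles, and bulk profile comparison between samples.

#' Classify cells against reference expression profiles
#'
#' Each cell is assigned the reference population with which its
#' expression has the highest Spearman correlation (average ranks on
#' ties), computed over the genes shared between the cell matrix and the
#' profiles. When the winning population contains biological subsets
#' (per the reference set's containment map) and the runner-up is one of
#' those subsets, the cell is reassigned to the runner-up; the rule is
#' applied once. Cells with undefined correlations everywhere (constant
#' vectors) are labelled `"unassigned"`.
#'
#' @param object a [GeneBarcodeMatrix-class] (or genes x cells matrix).
#' @param references a [ReferenceProfileSet-class].
#' @return character vector of per-cell labels (named by barcode) with a
#'   `"correlations"` attribute (cells x populations Spearman matrix).
#' @export
classifyByReference <- function(object, references) {
  m <- if (methods::is(object, "GeneBarcodeMatrix")) umiCounts(object)
       else object
  common <- intersect(rownames(m), rownames(references@profiles))
  if (!length(common)) stop("no genes shared with the reference profiles")
  x <- as.matrix(m[common, , drop = FALSE])
  p <- references@profiles[common, , drop = FALSE]
  rho <- suppressWarnings(cor(x, p, method = "spearman"))
  labels <- character(ncol(x))
  pops <- colnames(p)
  contain <- references@containment
  for (i in seq_len(ncol(x))) {
    r <- rho[i, ]
    if (all(is.na(r))) {
      labels[i] <- "unassigned"
      next
    }
    o <- order(-r, pops, na.last = TRUE)
    win <- pops[o[1L]]
    if (length(contain[[win]]) && length(o) > 1L) {
      runner <- pops[o[2L]]
      if (!is.na(rho[i, runner]) && runner %in% contain[[win]])
        win <- runner
    }
    labels[i] <- win
  }
  names(labels) <- colnames(x)
  attr(labels, "correlations") <- rho
  labels
}

#' Compare mean expression profiles of two samples
#'
#' Computes the Pearson correlation between the per-gene mean UMI counts
#' of two samples (over genes detected in at least one cell of either),
#' and lists the genes whose mean in B exceeds `fold` times the mean in A
#' (a pseudocount on both means guards zero denominators). Both samples
#' are expected to be downsampled to comparable depth by the caller.
#'
#' @param a,b [GeneBarcodeMatrix-class] objects (or genes x cells
#'   matrices) over the same gene universe.
#' @param fold up-regulation fold threshold (default 2).
#' @param pseudocount added to both means (default 1).
#' @return list: `r` (Pearson correlation), `upGenes` (genes up in `b`),
#'   `ratio` (named fold ratios), `meanA`, `meanB`.
#' @export
compareProfiles <- function(a, b, fold = 2, pseudocount = 1) {
  ma <- if (methods::is(a, "GeneBarcodeMatrix")) umiCounts(a) else a
  mb <- if (methods::is(b, "GeneBarcodeMatrix")) umiCounts(b) else b
  common <- intersect(rownames(ma), rownames(mb))
  if (!length(common)) stop("no genes shared between the samples")
  ma <- ma[common, , drop = FALSE]
  mb <- mb[common, , drop = FALSE]
  meanA <- Matrix::rowMeans(ma)
  meanB <- Matrix::rowMeans(mb)
  detected <- Matrix::rowSums(ma) + Matrix::rowSums(mb) > 0
  r <- cor(meanA[detected], meanB[detected])
  ratio <- (meanB + pseudocount) / (meanA + pseudocount)
  up <- names(ratio)[detected & ratio >= fold]
  list(r = r, upGenes = up, ratio = ratio,
       meanA = meanA, meanB = meanB)
}
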