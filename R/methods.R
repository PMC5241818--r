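#' @describeIn GeneBarcodeMatrix UMI count assay accessor.
#' @param object a `GeneBarcodeMatrix`.
#' @export
setMethod("umiCounts", "GeneBarcodeMatrix",
          function(object) assay(object, "counts"))

#' @describeIn GeneBarcodeMatrix gene IDs.
#' @export
setMethod("geneIDs", "GeneBarcodeMatrix", function(object) rownames(object))

#' @describeIn GeneBarcodeMatrix per-gene species tags (or `NULL`).
#' @export
setMethod("geneSpecies", "GeneBarcodeMatrix", function(object) {
  rd <- rowData(object)
  if ("species" %in% colnames(rd)) rd$species else NULL
})

#' @describeIn GeneBarcodeMatrix cell barcodes.
#' @export
setMethod("barcodes", "GeneBarcodeMatrix", function(object) colnames(object))

setMethod("show", "GeneBarcodeMatrix", function(object) {
  cat("GeneBarcodeMatrix:", nrow(object), "genes x", ncol(object),
      "barcodes\n")
  cat("  total UMIs:", sum(assay(object, "counts")), "\n")
  sp <- geneSpecies(object)
  if (!is.null(sp))
    cat("  species:", paste(unique(sp), collapse = ", "), "\n")
})

#' @describeIn AlleleCountPair reference-allele counts.
#' @param object an `AlleleCountPair`.
#' @export
setMethod("refCounts", "AlleleCountPair",
          function(object) assay(object, "ref"))

#' @describeIn AlleleCountPair alternate-allele counts.
#' @export
setMethod("altCounts", "AlleleCountPair",
          function(object) assay(object, "alt"))

#' @describeIn AlleleCountPair cell barcodes.
#' @export
setMethod("barcodes", "AlleleCountPair", function(object) colnames(object))

setMethod("show", "AlleleCountPair", function(object) {
  cat("AlleleCountPair:", nrow(object), "SNV sites x", ncol(object),
      "cells\n")
  cat("  covered (ref+alt > 0) entries:",
      sum((assay(object, "ref") + assay(object, "alt")) > 0), "\n")
})

#' @describeIn CellSet called barcodes.
#' @param object a `CellSet`.
#' @export
setMethod("calledBarcodes", "CellSet", function(object) object@calledBarcodes)

setMethod("show", "CellSet", function(object) {
  cat("CellSet:", length(object@calledBarcodes), "cells called of",
      length(object@totals), "barcodes (UMI threshold >",
      format(object@thresholdUmi), ")\n")
})

setMethod("show", "SpeciesCallResult", function(object) {
  tab <- table(object@calls$label)
  cat("SpeciesCallResult:", nrow(object@calls), "barcodes;",
      paste(names(tab), as.integer(tab), sep = "=", collapse = ", "), "\n")
  cat("  observed mixed fraction:",
      format(object@observedMixedFraction, digits = 4),
      "-> inferred multiplet rate:",
      format(object@inferredMultipletRate, digits = 4), "\n")
})

setMethod("show", "ClusterResult", function(object) {
  cat("ClusterResult: k =", object@k, "over", length(object@labels),
      "cells,", ncol(object@pcs), "PCs (seed", object@seed, ")\n")
})

setMethod("show", "GenotypeModel", function(object) {
  cat("GenotypeModel: K =", object@K, ";", nrow(object@cellProb), "cells,",
      dim(object@genotypeProb)[1L], "sites\n")
  if (object@K > 1L)
    cat("  minor-genome fraction:",
        format(object@mixtureFraction, digits = 4), "\n")
})

setMethod("show", "NormalizedMatrix", function(object) {
  cat("NormalizedMatrix:", nrow(object@standardized), "genes x",
      ncol(object@standardized), "cells (",
      length(object@droppedGenes), "genes,",
      length(object@droppedCells), "cells dropped )\n")
})
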