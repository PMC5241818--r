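#' Extract the UMI count assay
#' @param object a [GeneBarcodeMatrix-class].
#' @return sparse genes x barcodes count matrix.
#' @export
setGeneric("umiCounts", function(object) standardGeneric("umiCounts"))

#' Gene identifiers
#' @param object a container with gene rows.
#' @return character vector of gene IDs.
#' @export
setGeneric("geneIDs", function(object) standardGeneric("geneIDs"))

#' Per-gene species tags
#' @param object a [GeneBarcodeMatrix-class].
#' @return character vector of species tags, or `NULL`.
#' @export
setGeneric("geneSpecies", function(object) standardGeneric("geneSpecies"))

#' Cell barcodes
#' @param object a container with barcode columns.
#' @return character vector of barcodes.
#' @export
setGeneric("barcodes", function(object) standardGeneric("barcodes"))

#' Reference-allele UMI counts
#' @param object an [AlleleCountPair-class].
#' @return sparse sites x cells matrix.
#' @export
setGeneric("refCounts", function(object) standardGeneric("refCounts"))

#' Alternate-allele UMI counts
#' @param object an [AlleleCountPair-class].
#' @return sparse sites x cells matrix.
#' @export
setGeneric("altCounts", function(object) standardGeneric("altCounts"))

#' Barcodes called as cell-containing
#' @param object a [CellSet-class].
#' @return character vector of called barcodes.
#' @export
setGeneric("calledBarcodes", function(object) standardGeneric("calledBarcodes"))
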