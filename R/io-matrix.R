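## Gene-barcode matrix IO: MatrixMarket coordinate integer file plus
## genes.tsv / barcodes.tsv sidecars, the public 10x directory layout.

#' Write a GeneBarcodeMatrix to an MTX directory
#'
#' Writes `matrix.mtx` (MatrixMarket coordinate integer), `genes.tsv`
#' (gene ID, gene name, and species tag when present) and `barcodes.tsv`.
#' [readGeneBarcodeMatrix()] restores the object exactly, including row
#' and column ordering.
#'
#' @param object a [GeneBarcodeMatrix-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeGeneBarcodeMatrix <- function(object, dir) {
  stopifnot(methods::is(object, "GeneBarcodeMatrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- umiCounts(object)
  tm <- methods::as(m, "TsparseMatrix")
  ## MatrixMarket coordinate integer, 1-based, sorted by column then row
  o <- order(tm@j, tm@i)
  con <- file(file.path(dir, "matrix.mtx"), "w")
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               paste(nrow(m), ncol(m), length(tm@x))), con)
  if (length(tm@x))
    writeLines(paste(tm@i[o] + 1L, tm@j[o] + 1L,
                     format(tm@x[o], scientific = FALSE, trim = TRUE)), con)
  close(con)
  rd <- rowData(object)
  genes <- data.frame(id = rownames(object), name = rd$gene_name,
                      stringsAsFactors = FALSE)
  if ("species" %in% colnames(rd)) genes$species <- rd$species
  write.table(genes, file.path(dir, "genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  bcs <- colnames(object)
  writeLines(if (is.null(bcs)) character(0) else bcs,
             file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a GeneBarcodeMatrix from an MTX directory
#'
#' @param dir directory containing `matrix.mtx`, `genes.tsv`,
#'   `barcodes.tsv`.
#' @return A [GeneBarcodeMatrix-class].
#' @export
readGeneBarcodeMatrix <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx)) stop("matrix.mtx not found in ", dir)
  m <- Matrix::readMM(mtx)
  glines <- readLines(file.path(dir, "genes.tsv"))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  if (length(glines)) {
    gf <- read.table(text = glines, sep = "\t", colClasses = "character",
                     quote = "")
  } else {
    gf <- data.frame(V1 = character(0), V2 = character(0))
  }
  if (nrow(gf) != nrow(m) || length(barcodes) != ncol(m))
    stop("format error: MTX dimensions (", nrow(m), " x ", ncol(m),
         ") do not match sidecar lengths (", nrow(gf), " genes, ",
         length(barcodes), " barcodes)")
  GeneBarcodeMatrix(m, genes = gf[[1L]], barcodes = barcodes,
                    geneNames = if (ncol(gf) >= 2L) gf[[2L]] else gf[[1L]],
                    species = if (ncol(gf) >= 3L) gf[[3L]] else NULL)
}
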