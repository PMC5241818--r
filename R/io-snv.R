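## SNV site table IO: a minimal VCF v4 subset. Per-site supporting-cell
## counts travel in INFO key NCELLS (a sidecar TSV keyed by chrom:pos is
## accepted as an alternative); the minimal supporting base quality may
## travel in INFO key BQ.

siteKey <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

infoField <- function(info, key) {
  pat <- paste0("(^|;)", key, "=([^;]*)")
  m <- regexec(pat, info)
  vapply(regmatches(info, m), function(x)
    if (length(x) >= 3L) x[3L] else NA_character_, "")
}

#' Read and filter an SNV site table from a minimal VCF
#'
#' Retains biallelic SNVs (single-base REF and ALT; indels and
#' multi-allelic records are skipped with a message) passing three filters:
#' site quality `QUAL >= minQual`, minimal supporting base quality
#' `>= minBaseQual` (INFO key `BQ`; records without `BQ` are not filtered
#' on it), and support from at least `minCells` cell barcodes (INFO key
#' `NCELLS`, or the `cellCounts` sidecar).
#'
#' @param path VCF file (CHROM POS ID REF ALT QUAL columns used).
#' @param minQual minimum site QUAL (default 30).
#' @param minBaseQual minimum supporting base quality (default 1).
#' @param minCells minimum number of supporting cell barcodes (default 2).
#' @param cellCounts optional sidecar: data.frame with columns `chrom`,
#'   `pos`, `n_cells`, or a path to such a TSV.
#' @return data.frame with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `qual`, `n_cells`, `site` (key `chrom:pos:ref:alt`).
#' @export
readSnvSites <- function(path, minQual = 30, minBaseQual = 1, minCells = 2,
                         cellCounts = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (!nrow(fix)) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      qual = numeric(0), n_cells = integer(0),
                      site = character(0), stringsAsFactors = FALSE))
  }
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  indel <- !multi & (nchar(fix$REF) != 1L | nchar(fix$ALT) != 1L)
  nSkip <- sum(multi | indel)
  if (nSkip)
    message("skipped ", nSkip, " multi-allelic/indel record(s)")
  fix <- fix[!multi & !indel, , drop = FALSE]
  qual <- suppressWarnings(as.numeric(fix$QUAL))
  nCells <- suppressWarnings(as.integer(infoField(fix$INFO, "NCELLS")))
  if (!is.null(cellCounts)) {
    if (is.character(cellCounts))
      cellCounts <- read.table(cellCounts, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
    key <- paste(fix$CHROM, fix$POS, sep = ":")
    sideKey <- paste(cellCounts$chrom, cellCounts$pos, sep = ":")
    nCells <- cellCounts$n_cells[match(key, sideKey)]
  }
  if (all(is.na(nCells)) && nrow(fix))
    stop("per-site supporting-cell counts missing: provide INFO key ",
         "NCELLS or a cellCounts sidecar")
  baseQual <- suppressWarnings(as.numeric(infoField(fix$INFO, "BQ")))
  keep <- !is.na(qual) & qual >= minQual &
    !is.na(nCells) & nCells >= minCells &
    (is.na(baseQual) | baseQual >= minBaseQual)
  fix <- fix[keep, , drop = FALSE]
  out <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                    ref = fix$REF, alt = fix$ALT, qual = qual[keep],
                    n_cells = as.integer(nCells[keep]),
                    stringsAsFactors = FALSE)
  out$site <- siteKey(out$chrom, out$pos, out$ref, out$alt)
  if (anyDuplicated(out[, c("chrom", "pos")]))
    stop("duplicate (chrom, pos) in SNV table")
  rownames(out) <- NULL
  out
}

#' Write an SNV site table as a minimal VCF
#'
#' @param sites data.frame with `chrom`, `pos`, `ref`, `alt`, `qual`,
#'   `n_cells` and optionally `base_qual`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSnvSites <- function(sites, path) {
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##INFO=<ID=NCELLS,Number=1,Type=Integer,",
                  "Description=\"Supporting cell barcodes\">"),
           paste0("##INFO=<ID=BQ,Number=1,Type=Float,",
                  "Description=\"Minimal supporting base quality\">"),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- paste0("NCELLS=", sites$n_cells)
  if (!is.null(sites$base_qual))
    info <- paste0(info, ";BQ=", sites$base_qual)
  body <- paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt,
                sites$qual, ".", info, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write / read an AlleleCountPair as an MTX pair
#'
#' `ref.mtx` and `alt.mtx` (MatrixMarket) with `sites.tsv` and
#' `cells.tsv` sidecars; exact round trip.
#'
#' @param object an [AlleleCountPair-class].
#' @param dir directory.
#' @return `dir` (write) or an `AlleleCountPair` (read).
#' @export
writeAlleleCountPair <- function(object, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(refCounts(object), file.path(dir, "ref.mtx"))
  Matrix::writeMM(altCounts(object), file.path(dir, "alt.mtx"))
  writeLines(rownames(object), file.path(dir, "sites.tsv"))
  writeLines(colnames(object), file.path(dir, "cells.tsv"))
  invisible(dir)
}

#' @rdname writeAlleleCountPair
#' @export
readAlleleCountPair <- function(dir) {
  r <- Matrix::readMM(file.path(dir, "ref.mtx"))
  a <- Matrix::readMM(file.path(dir, "alt.mtx"))
  sites <- readLines(file.path(dir, "sites.tsv"))
  cells <- readLines(file.path(dir, "cells.tsv"))
  if (nrow(r) != length(sites) || ncol(r) != length(cells))
    stop("format error: MTX dimensions do not match sidecars")
  AlleleCountPair(r, a, sites = sites, cells = cells)
}
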