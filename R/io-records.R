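## Aligned-read record IO.
##
## A "record" is one sequenced cDNA read carrying the raw (uncorrected)
## cell barcode and UMI with their base qualities, the gene the read was
## confidently assigned to (or NA), and the MAPQ. Records are held in a
## plain data.frame with columns:
##   barcode_seq, barcode_quals, umi_seq, umi_quals, gene_id, mapq,
##   sample_index, run_id
## Qualities are Phred+33 strings (FASTQ convention).

RECORD_COLUMNS <- c("barcode_seq", "barcode_quals", "umi_seq", "umi_quals",
                    "gene_id", "mapq", "sample_index", "run_id")

validateRecords <- function(rec) {
  checkSequences(rec$barcode_seq, "barcode")
  checkSequences(rec$umi_seq, "UMI")
  if (any(nchar(rec$barcode_seq) != nchar(rec$barcode_quals)))
    stop("barcode sequence/quality length mismatch (record ",
         which(nchar(rec$barcode_seq) != nchar(rec$barcode_quals))[1L], ")")
  if (any(nchar(rec$umi_seq) != nchar(rec$umi_quals)))
    stop("UMI sequence/quality length mismatch (record ",
         which(nchar(rec$umi_seq) != nchar(rec$umi_quals))[1L], ")")
  if (any(rec$mapq < 0 | rec$mapq > 255))
    stop("MAPQ out of [0, 255] (record ",
         which(rec$mapq < 0 | rec$mapq > 255)[1L], ")")
  invisible(rec)
}

emptyRecords <- function() {
  out <- data.frame(barcode_seq = character(0), barcode_quals = character(0),
                    umi_seq = character(0), umi_quals = character(0),
                    gene_id = character(0), mapq = integer(0),
                    sample_index = character(0), run_id = character(0),
                    stringsAsFactors = FALSE)
  out
}

#' Read aligned-read records
#'
#' Reads the per-read table consumed by [countPipeline()]. Two dialects are
#' supported: a TSV with the canonical columns (`barcode_seq`,
#' `barcode_quals`, `umi_seq`, `umi_quals`, `gene_id`, `mapq`,
#' `sample_index`, `run_id`; empty or `.` gene_id means "not confidently
#' assigned to a gene"), and a minimal SAM text subset where the same fields
#' are mapped from optional tags `CR`/`CY` (raw barcode and qualities),
#' `UR`/`UY` (raw UMI and qualities), `GX` (gene), `BC` (sample index) and
#' `RG` (run), with MAPQ from the mandatory fifth column.
#'
#' @param path file to read.
#' @param dialect `"tsv"` (default) or `"sam"`.
#' @return data.frame of records, in file order.
#' @export
readAlignedRecords <- function(path, dialect = c("tsv", "sam")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "tsv") readRecordsTsv(path) else readRecordsSam(path)
}

readRecordsTsv <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) return(emptyRecords())
  rec <- read.table(text = lines, sep = "\t", header = TRUE,
                    colClasses = "character", quote = "",
                    na.strings = character(0), check.names = FALSE)
  missing <- setdiff(RECORD_COLUMNS, colnames(rec))
  if (length(missing))
    stop("format error: missing column(s) ", paste(missing, collapse = ", "))
  rec <- rec[, RECORD_COLUMNS]
  rec$gene_id[rec$gene_id %in% c("", ".")] <- NA_character_
  mapq <- suppressWarnings(as.integer(rec$mapq))
  bad <- which(is.na(mapq))
  if (length(bad))
    stop("format error: non-integer MAPQ at line ", bad[1L] + 1L)
  rec$mapq <- mapq
  validateRecords(rec)
}

#' Write aligned-read records (TSV dialect)
#'
#' @param records record data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeAlignedRecords <- function(records, path) {
  out <- records[, RECORD_COLUMNS]
  out$gene_id[is.na(out$gene_id)] <- "."
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

samTag <- function(tags, key) {
  hit <- regmatches(tags, regexpr(paste0("(^|\t)", key, ":Z:[^\t]*"), tags))
  out <- rep(NA_character_, length(tags))
  found <- lengths(regmatches(tags,
            gregexpr(paste0("(^|\t)", key, ":Z:[^\t]*"), tags))) > 0
  out[found] <- sub(paste0(".*", key, ":Z:"), "", hit)
  out
}

readRecordsSam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) return(emptyRecords())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 11L)
  if (length(short))
    stop("format error: truncated SAM line ", short[1L])
  mapq <- suppressWarnings(as.integer(vapply(fields, `[`, "", 5L)))
  tags <- vapply(fields, function(f)
    paste(f[-(1:11)], collapse = "\t"), "")
  rec <- data.frame(
    barcode_seq = samTag(tags, "CR"),
    barcode_quals = samTag(tags, "CY"),
    umi_seq = samTag(tags, "UR"),
    umi_quals = samTag(tags, "UY"),
    gene_id = samTag(tags, "GX"),
    mapq = mapq,
    sample_index = samTag(tags, "BC"),
    run_id = samTag(tags, "RG"),
    stringsAsFactors = FALSE)
  need <- c("barcode_seq", "barcode_quals", "umi_seq", "umi_quals")
  bad <- which(apply(is.na(rec[, need]), 1L, any))
  if (length(bad))
    stop("format error: missing CR/CY/UR/UY tag at SAM record ", bad[1L])
  rec$sample_index[is.na(rec$sample_index)] <- "S1"
  rec$run_id[is.na(rec$run_id)] <- "run1"
  validateRecords(rec)
}
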