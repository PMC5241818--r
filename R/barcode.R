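## Counting core: barcode correction against the whitelist, UMI
## validation/collapse, duplicate marking, and the full record-to-matrix
## pipeline.

#' Barcode whitelist
#'
#' The set of designed cell-barcode sequences, with the observed count of
#' each (the prior for the posterior correction model).
#'
#' @slot sequences designed barcode sequences (unique, one length).
#' @slot priorCounts named non-negative counts; names are a subset of
#'   `sequences`. Barcodes without an entry have count 0.
#' @export
setClass("BarcodeWhitelist", representation(
  sequences = "character", priorCounts = "numeric"))

setValidity("BarcodeWhitelist", function(object) {
  if (anyDuplicated(object@sequences)) return("duplicate whitelist barcodes")
  if (length(unique(nchar(object@sequences))) > 1L)
    return("whitelist barcodes must share one length")
  if (!all(names(object@priorCounts) %in% object@sequences))
    return("priorCounts keys must be whitelist barcodes")
  if (length(object@priorCounts) && any(object@priorCounts < 0))
    return("priorCounts must be non-negative")
  TRUE
})

#' @rdname BarcodeWhitelist-class
#' @param sequences designed barcode sequences.
#' @param priorCounts named observed counts (optional).
#' @return A `BarcodeWhitelist`.
#' @export
barcodeWhitelist <- function(sequences, priorCounts = numeric(0)) {
  methods::new("BarcodeWhitelist", sequences = sequences,
               priorCounts = priorCounts)
}

#' Read a whitelist (one barcode per line)
#' @param path text file.
#' @return A [BarcodeWhitelist-class].
#' @export
readBarcodeWhitelist <- function(path) {
  barcodeWhitelist(readLines(path))
}

## prior probability per whitelist barcode: observed count + 1 pseudocount
## (unseen designed barcodes stay reachable)
whitelistPriors <- function(whitelist) {
  p <- setNames(rep(1, length(whitelist@sequences)), whitelist@sequences)
  if (length(whitelist@priorCounts))
    p[names(whitelist@priorCounts)] <- whitelist@priorCounts + 1
  p
}

#' Correct an observed cell barcode against the whitelist
#'
#' An observed barcode already on the whitelist is returned unchanged.
#' Otherwise every whitelist barcode at Hamming distance exactly 1 is a
#' candidate: the likelihood that candidate `c` produced the observation is
#' the sequencing-error probability `10^(-q/10)` at the mismatched base
#' (matching bases contribute 1), and the posterior is proportional to
#' `prior(c) * likelihood(c)`, normalized over candidates. The highest
#' posterior candidate is returned if its posterior reaches
#' `posteriorThreshold`; equal posteriors are broken by lexical order.
#'
#' @param observedSeq observed barcode sequence.
#' @param observedQuals Phred+33 quality string (same length).
#' @param whitelist a [BarcodeWhitelist-class].
#' @param params a [CorrectionParams-class].
#' @return corrected barcode, or `NA_character_` if no candidate reaches
#'   the threshold.
#' @export
correctBarcode <- function(observedSeq, observedQuals, whitelist,
                           params = correctionParams()) {
  bcLen <- nchar(whitelist@sequences[1L])
  if (nchar(observedSeq) != bcLen)
    stop("observed barcode length ", nchar(observedSeq),
         " does not match whitelist length ", bcLen)
  if (nchar(observedQuals) != nchar(observedSeq))
    stop("barcode sequence/quality length mismatch")
  if (observedSeq %in% whitelist@sequences) return(observedSeq)
  priors <- whitelistPriors(whitelist)
  .correctOne(observedSeq, observedQuals, whitelist@sequences, priors,
              params@posteriorThreshold)
}

.correctOne <- function(seq, quals, wlSeqs, priors, threshold) {
  cands <- intersect(hamming1Neighbours(seq), wlSeqs)
  if (!length(cands)) return(NA_character_)
  cands <- sort(cands)  # lexical tie-break
  q <- phredToInt(quals)
  obs <- strsplit(seq, "", fixed = TRUE)[[1L]]
  lik <- vapply(cands, function(cand) {
    pos <- which(strsplit(cand, "", fixed = TRUE)[[1L]] != obs)
    10^(-q[pos] / 10)
  }, numeric(1))
  post <- priors[cands] * lik
  post <- post / sum(post)
  best <- which.max(post)  # first max = lexically first on ties
  if (post[best] >= threshold) cands[best] else NA_character_
}

#' Validate a UMI
#'
#' A UMI is valid when every base quality strictly exceeds `umiMinQual`,
#' the sequence is not a homopolymer, and it contains no N.
#'
#' @param umiSeq UMI sequence.
#' @param umiQuals Phred+33 quality string.
#' @param params a [CorrectionParams-class].
#' @return `TRUE` (accept) or `FALSE` (reject).
#' @export
validateUmi <- function(umiSeq, umiQuals, params = correctionParams()) {
  if (!nchar(umiSeq)) stop("empty UMI")
  if (grepl("N", umiSeq, fixed = TRUE)) return(FALSE)
  if (isHomopolymer(umiSeq)) return(FALSE)
  all(phredToInt(umiQuals) > params@umiMinQual)
}

## vectorized UMI validity over character vectors
validUmiMask <- function(umiSeq, umiQuals, params) {
  minQ <- vapply(umiQuals, function(q) min(utf8ToInt(q)) - 33L, 0L,
                 USE.NAMES = FALSE)
  homo <- umiSeq == strrep(substr(umiSeq, 1L, 1L), nchar(umiSeq))
  hasN <- grepl("N", umiSeq, fixed = TRUE)
  minQ > params@umiMinQual & !homo & !hasN
}

#' Collapse sequencing-error UMIs within one barcode x gene group
#'
#' A UMI at Hamming distance 1 from another UMI of the same cell barcode
#' and gene with strictly more reads is relabelled to that UMI. All
#' corrections are decided against the pre-collapse read counts in a
#' single pass (no chaining); among several richer neighbours the one
#' with most reads wins, with lexical order breaking ties.
#'
#' @param umis character vector: the raw UMI of every read in the group.
#' @return character vector of corrected per-read UMIs.
#' @export
collapseUmis <- function(umis) {
  if (length(umis) < 2L) return(umis)
  counts <- table(umis)
  uniq <- names(counts)
  if (length(uniq) < 2L) return(umis)
  mapped <- setNames(uniq, uniq)
  chars <- strsplit(uniq, "", fixed = TRUE)
  for (i in seq_along(uniq)) {
    d1 <- vapply(chars, function(x) sum(x != chars[[i]]) == 1L, NA)
    richer <- which(d1 & counts > counts[i])
    if (length(richer)) {
      best <- richer[order(-counts[richer], uniq[richer])][1L]
      mapped[i] <- uniq[best]
    }
  }
  unname(mapped[umis])
}

#' Mark PCR duplicates
#'
#' Reads sharing a (corrected) barcode, UMI and gene ID are PCR copies of
#' one cDNA molecule; the first encountered is retained.
#'
#' @param records record data.frame with corrected `barcode_seq`,
#'   `umi_seq` and `gene_id`.
#' @param ignoreRun unused placeholder for API symmetry; duplicate keys
#'   never include `run_id`, so merging runs deduplicates across them.
#' @return list: `records` (unique molecules, first occurrence kept) and
#'   `nDuplicates` (reads marked).
#' @export
markDuplicates <- function(records, ignoreRun = TRUE) {
  key <- paste(records$barcode_seq, records$umi_seq, records$gene_id,
               sep = "\r")
  dup <- duplicated(key)
  list(records = records[!dup, , drop = FALSE],
       nDuplicates = sum(dup))
}

#' Records-to-matrix digital counting pipeline
#'
#' Applies, in order: barcode correction (reads with no acceptable
#' whitelist barcode dropped), UMI validation, the confident-mapping
#' filter (`mapq == confidentMapq` and a uniquely assigned gene), UMI
#' collapse within each barcode x gene group, and duplicate marking. The
#' resulting matrix entry (g, b) is the number of distinct retained
#' molecules, i.e. unique (barcode, UMI, gene) triples.
#'
#' Barcode priors are taken from the whitelist's `priorCounts` when
#' present, otherwise computed from the exact whitelist matches observed
#' in the input.
#'
#' @param records record data.frame (see [readAlignedRecords()]).
#' @param whitelist a [BarcodeWhitelist-class].
#' @param params a [CorrectionParams-class].
#' @param genes optional fixed gene universe for the matrix rows.
#' @return list: `matrix` (a [GeneBarcodeMatrix-class]), `metrics` (stage
#'   fractions and counts; `validBarcodeFraction`, `validUmiFraction`,
#'   `confidentlyMappedFraction`, `nDuplicatesMarked`, ...).
#' @export
countPipeline <- function(records, whitelist, params = correctionParams(),
                          genes = NULL) {
  nTotal <- nrow(records)
  metrics <- list(nRecords = nTotal)
  if (nTotal == 0L) {
    g <- if (is.null(genes)) character(0) else genes
    m <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(length(g), 0L))
    warning("no input records: empty matrix")
    metrics[c("validBarcodeFraction", "validUmiFraction",
              "confidentlyMappedFraction")] <- NA_real_
    metrics$nDuplicatesMarked <- 0L
    return(list(matrix = GeneBarcodeMatrix(m, genes = g,
                                           barcodes = character(0)),
                metrics = metrics))
  }

  ## 1. barcode correction
  exact <- records$barcode_seq %in% whitelist@sequences
  wl <- whitelist
  if (!length(wl@priorCounts)) {
    tab <- table(records$barcode_seq[exact])
    wl@priorCounts <- setNames(as.numeric(tab), names(tab))
  }
  priors <- whitelistPriors(wl)
  corrected <- records$barcode_seq
  bad <- which(!exact)
  if (length(bad)) {
    keyU <- paste(records$barcode_seq[bad], records$barcode_quals[bad])
    uniqIdx <- bad[!duplicated(keyU)]
    fixes <- vapply(uniqIdx, function(i)
      .correctOne(records$barcode_seq[i], records$barcode_quals[i],
                  wl@sequences, priors, params@posteriorThreshold),
      NA_character_)
    corrected[bad] <- fixes[match(keyU, keyU[!duplicated(keyU)])]
  }
  records$barcode_seq <- corrected
  keep <- !is.na(corrected)
  metrics$validBarcodeFraction <- mean(keep)
  records <- records[keep, , drop = FALSE]

  ## 2. UMI validation
  if (nrow(records)) {
    ok <- validUmiMask(records$umi_seq, records$umi_quals, params)
    metrics$validUmiFraction <- mean(ok)
    records <- records[ok, , drop = FALSE]
  } else metrics$validUmiFraction <- NA_real_

  ## 3. confident mapping with a unique gene assignment
  if (nrow(records)) {
    ok <- records$mapq == params@confidentMapq & !is.na(records$gene_id)
    metrics$confidentlyMappedFraction <- mean(ok)
    records <- records[ok, , drop = FALSE]
  } else metrics$confidentlyMappedFraction <- NA_real_

  ## 4. UMI collapse within barcode x gene
  if (nrow(records)) {
    grp <- paste(records$barcode_seq, records$gene_id, sep = "\r")
    idx <- split(seq_len(nrow(records)), grp)
    for (ii in idx) {
      if (length(ii) > 1L)
        records$umi_seq[ii] <- collapseUmis(records$umi_seq[ii])
    }
  }

  ## 5. duplicate marking
  dm <- markDuplicates(records)
  metrics$nDuplicatesMarked <- dm$nDuplicates
  mol <- dm$records
  metrics$nMolecules <- nrow(mol)

  g <- if (is.null(genes)) sort(unique(mol$gene_id)) else genes
  b <- sort(unique(mol$barcode_seq))
  m <- Matrix::sparseMatrix(
    i = match(mol$gene_id, g), j = match(mol$barcode_seq, b),
    x = rep(1, nrow(mol)), dims = c(length(g), length(b)))
  species <- NULL
  if (length(g) && all(grepl("^[^:]+:", g)))
    species <- sub(":.*$", "", g)
  if (nrow(mol) == 0L) warning("empty count matrix")
  list(matrix = GeneBarcodeMatrix(m, genes = g, barcodes = b,
                                  species = species),
       metrics = metrics)
}
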