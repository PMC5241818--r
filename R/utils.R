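#' @useDynLib dropletCounts, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats median mad quantile rbinom rpois rnbinom runif cor
#'   prcomp kmeans hclust as.dist setNames rmultinom
#' @importFrom utils read.table write.table head
NULL

DNA_BASES <- c("A", "C", "G", "T")

## Phred+33 encoded quality string <-> integer scores
phredToInt <- function(qual) {
  if (length(qual) == 1L && is.character(qual)) {
    as.integer(charToRaw(qual)) - 33L
  } else {
    lapply(qual, function(q) as.integer(charToRaw(q)) - 33L)
  }
}

intToPhred <- function(q) {
  rawToChar(as.raw(as.integer(q) + 33L))
}

## Hamming distance between two equal-length strings
hammingDist <- function(a, b) {
  x <- strsplit(a, "", fixed = TRUE)[[1L]]
  y <- strsplit(b, "", fixed = TRUE)[[1L]]
  stopifnot(length(x) == length(y))
  sum(x != y)
}

isHomopolymer <- function(seq) {
  bases <- strsplit(seq, "", fixed = TRUE)[[1L]]
  all(bases == bases[1L])
}

## All sequences at Hamming distance exactly 1 from `seq`
hamming1Neighbours <- function(seq) {
  bases <- strsplit(seq, "", fixed = TRUE)[[1L]]
  out <- character(0)
  for (i in seq_along(bases)) {
    for (b in DNA_BASES[DNA_BASES != bases[i]]) {
      mut <- bases
      mut[i] <- b
      out <- c(out, paste(mut, collapse = ""))
    }
  }
  out
}

checkSequences <- function(seqs, what = "sequence") {
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("non-ACGTN base in ", what, " (record ",
         paste(head(which(bad), 5L), collapse = ", "), ")")
  }
  invisible(TRUE)
}

randomSeq <- function(n, len) {
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  apply(m, 1L, paste, collapse = "")
}

## rounds like the conventional "round half up" so that printed-value
## comparisons at one decimal are stable across platforms
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
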