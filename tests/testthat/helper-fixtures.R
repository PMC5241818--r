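## fixtures are generated in code; nothing is read from disk

makeRecords <- function(barcode, umi, gene, mapq = 255L,
                        bcQual = 30L, umiQual = 30L,
                        run = "run1") {
  n <- max(length(barcode), length(umi), length(gene))
  barcode <- rep_len(barcode, n)
  umi <- rep_len(umi, n)
  data.frame(
    barcode_seq = barcode,
    barcode_quals = strrep(rawToChar(as.raw(bcQual + 33L)), nchar(barcode)),
    umi_seq = umi,
    umi_quals = strrep(rawToChar(as.raw(umiQual + 33L)), nchar(umi)),
    gene_id = rep_len(gene, n),
    mapq = rep_len(as.integer(mapq), n),
    sample_index = rep_len("S1", n),
    run_id = rep_len(run, n),
    stringsAsFactors = FALSE)
}

qstr <- function(quals) rawToChar(as.raw(as.integer(quals) + 33L))

makeGbm <- function(counts, genes = NULL, barcodes = NULL, species = NULL) {
  if (is.null(genes)) genes <- sprintf("G%03d", seq_len(nrow(counts)))
  if (is.null(barcodes)) barcodes <- sprintf("BC%03d", seq_len(ncol(counts)))
  GeneBarcodeMatrix(Matrix::Matrix(counts, sparse = TRUE),
                    genes = genes, barcodes = barcodes, species = species)
}

## two-population barnyard configuration used across tests
barnyardConfig <- function(nCells = 40, umiMean = 100, seed = 1, ...) {
  set.seed(seed * 7919)
  readSimConfig(populations = list(
    human = list(nCells = nCells,
                 genes = setNames(rgamma(30, 2) + 0.1,
                                  paste0("hg19:HG", 1:30)),
                 species = "hg19"),
    mouse = list(nCells = nCells,
                 genes = setNames(rgamma(30, 2) + 0.1,
                                  paste0("mm10:MG", 1:30)),
                 species = "mm10")),
    umiMean = umiMean, seed = seed, ...)
}

adjustedRand <- function(a, b) mclust::adjustedRandIndex(a, b)

## a GenotypeModel stub with prescribed per-cell MAP posteriors
makeModelK2 <- function(mapProb, map = NULL) {
  n <- length(mapProb)
  if (is.null(map)) map <- rep(1L, n)
  cp <- matrix(0, n, 2L)
  cp[cbind(seq_len(n), map)] <- mapProb
  cp[cbind(seq_len(n), 3L - map)] <- 1 - mapProb
  methods::new("GenotypeModel", K = 2L,
               genotypeProb = array(1 / 3, c(1L, 3L, 2L),
                                    dimnames = list("s1", NULL, NULL)),
               cellProb = cp, cellMap = map, cellMapProb = mapProb,
               mixtureFraction = min(mean(map == 1L), mean(map == 2L)),
               diagnostics = list())
}

makeModelK1 <- function(n) {
  methods::new("GenotypeModel", K = 1L,
               genotypeProb = array(1 / 3, c(1L, 3L, 1L),
                                    dimnames = list("s1", NULL, NULL)),
               cellProb = matrix(1, n, 1L),
               cellMap = rep(1L, n), cellMapProb = rep(1, n),
               mixtureFraction = 0, diagnostics = list())
}
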