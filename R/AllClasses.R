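#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

## ---------------------------------------------------------------------------
## Count containers
## ---------------------------------------------------------------------------

#' GeneBarcodeMatrix: sparse genes x barcodes UMI count container
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with a single sparse
#' integer assay `"counts"` holding deduplicated UMI counts, genes as rows and
#' cell barcodes as columns. Row metadata carries the gene symbol and an
#' optional species tag (used by the barnyard analytics, e.g. when the
#' reference is a union of the human and mouse genomes).
#'
#' @export
setClass("GeneBarcodeMatrix", contains = "SummarizedExperiment")

setValidity("GeneBarcodeMatrix", function(object) {
  msg <- character(0)
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    m <- assay(object, "counts")
    if (length(m@x) && any(m@x < 0))
      msg <- c(msg, "counts must be non-negative")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "gene IDs must be unique")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "barcodes must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneBarcodeMatrix
#'
#' @param counts genes x barcodes matrix (coerced to sparse `dgCMatrix`);
#'   dimnames give gene IDs and barcodes unless `genes`/`barcodes` are given.
#' @param genes character vector of gene IDs.
#' @param barcodes character vector of cell barcode sequences.
#' @param geneNames optional gene symbols (defaults to the IDs).
#' @param species optional per-gene species tag.
#' @return A [GeneBarcodeMatrix-class] object.
#' @examples
#' m <- GeneBarcodeMatrix(Matrix::Matrix(c(0, 1, 2, 0), 2, 2),
#'                        genes = c("g1", "g2"), barcodes = c("AA", "AC"))
#' umiCounts(m)
#' @export
GeneBarcodeMatrix <- function(counts, genes = rownames(counts),
                              barcodes = colnames(counts),
                              geneNames = NULL, species = NULL) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(genes) || is.null(barcodes))
    stop("gene IDs and barcodes are required")
  dimnames(counts) <- list(genes, barcodes)
  if (is.null(geneNames)) geneNames <- genes
  rd <- DataFrame(gene_id = genes, gene_name = geneNames)
  if (!is.null(species)) rd$species <- species
  rownames(rd) <- genes
  methods::new("GeneBarcodeMatrix",
               SummarizedExperiment(assays = list(counts = counts),
                                    rowData = rd))
}

#' AlleleCountPair: per-cell SNV reference/alternate UMI counts
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with two equally
#' shaped sparse assays, `"ref"` and `"alt"`, holding UMI counts supporting
#' the reference and alternate allele at each SNV site (rows) in each cell
#' (columns). Row metadata carries `chrom`, `pos` (1-based), `ref`, `alt`.
#'
#' @export
setClass("AlleleCountPair", contains = "SummarizedExperiment")

setValidity("AlleleCountPair", function(object) {
  msg <- character(0)
  if (!all(c("ref", "alt") %in% assayNames(object)))
    msg <- c(msg, "assays 'ref' and 'alt' are required")
  else {
    r <- assay(object, "ref"); a <- assay(object, "alt")
    if (!identical(dim(r), dim(a)))
      msg <- c(msg, "ref and alt assays must have identical shape")
    if ((length(r@x) && any(r@x < 0)) || (length(a@x) && any(a@x < 0)))
      msg <- c(msg, "allele counts must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AlleleCountPair
#'
#' @param ref,alt sites x cells count matrices (coerced to sparse).
#' @param sites site keys (e.g. `"chr1:123:A:G"`); default from rownames.
#' @param cells cell barcodes; default from colnames.
#' @param siteInfo optional data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @return An [AlleleCountPair-class] object.
#' @export
AlleleCountPair <- function(ref, alt, sites = rownames(ref),
                            cells = colnames(ref), siteInfo = NULL) {
  toSparse <- function(m)
    methods::as(methods::as(methods::as(m, "dMatrix"), "generalMatrix"),
                "CsparseMatrix")
  ref <- toSparse(ref); alt <- toSparse(alt)
  dimnames(ref) <- dimnames(alt) <- list(sites, cells)
  rd <- if (is.null(siteInfo)) DataFrame(site = sites)
        else DataFrame(siteInfo)
  rownames(rd) <- sites
  methods::new("AlleleCountPair",
               SummarizedExperiment(assays = list(ref = ref, alt = alt),
                                    rowData = rd))
}

## ---------------------------------------------------------------------------
## Parameter objects
## ---------------------------------------------------------------------------

#' Barcode/UMI correction parameters
#'
#' @slot posteriorThreshold minimum posterior probability to accept a
#'   whitelist correction (default 0.975).
#' @slot umiMinQual Phred score that every UMI base must strictly exceed
#'   (default 10).
#' @slot confidentMapq MAPQ value marking a confidently, uniquely mapped read
#'   (default 255, the STAR unique-mapper convention).
#' @export
setClass("CorrectionParams", representation(
  posteriorThreshold = "numeric",
  umiMinQual = "numeric",
  confidentMapq = "integer"))

setValidity("CorrectionParams", function(object) {
  if (object@posteriorThreshold <= 0 || object@posteriorThreshold > 1)
    return("posteriorThreshold must be in (0, 1]")
  if (object@umiMinQual < 0) return("umiMinQual must be >= 0")
  TRUE
})

#' @rdname CorrectionParams-class
#' @param posteriorThreshold,umiMinQual,confidentMapq see slots.
#' @return A `CorrectionParams` object.
#' @export
correctionParams <- function(posteriorThreshold = 0.975, umiMinQual = 10,
                             confidentMapq = 255L) {
  methods::new("CorrectionParams", posteriorThreshold = posteriorThreshold,
               umiMinQual = umiMinQual, confidentMapq = as.integer(confidentMapq))
}

#' Binomial-mixture demultiplexing parameters
#'
#' @slot errorRate fixed per-base allele observation error (default 0.001).
#' @slot nIterations,nBurnin Gibbs sampler schedule (defaults 500 / 200).
#' @slot nChains independent chains merged after relabelling (default 2).
#' @slot cellFractionThreshold fraction of cells that must be confidently
#'   assigned for the two-genome model to be selected (default 0.90).
#' @slot posteriorThreshold per-cell posterior defining "confidently
#'   assigned" (default 0.75, strict).
#' @export
setClass("MixtureParams", representation(
  errorRate = "numeric",
  nIterations = "integer",
  nBurnin = "integer",
  nChains = "integer",
  cellFractionThreshold = "numeric",
  posteriorThreshold = "numeric"))

setValidity("MixtureParams", function(object) {
  if (object@errorRate <= 0 || object@errorRate >= 0.5)
    return("errorRate must be in (0, 0.5)")
  if (object@nBurnin >= object@nIterations)
    return("nBurnin must be smaller than nIterations")
  if (object@cellFractionThreshold <= 0 || object@cellFractionThreshold >= 1 ||
      object@posteriorThreshold <= 0 || object@posteriorThreshold >= 1)
    return("thresholds must be in (0, 1)")
  TRUE
})

#' @rdname MixtureParams-class
#' @param errorRate,nIterations,nBurnin,nChains,cellFractionThreshold,posteriorThreshold
#'   see slots.
#' @return A `MixtureParams` object.
#' @export
mixtureParams <- function(errorRate = 0.001, nIterations = 500L,
                          nBurnin = 200L, nChains = 2L,
                          cellFractionThreshold = 0.90,
                          posteriorThreshold = 0.75) {
  methods::new("MixtureParams", errorRate = errorRate,
               nIterations = as.integer(nIterations),
               nBurnin = as.integer(nBurnin), nChains = as.integer(nChains),
               cellFractionThreshold = cellFractionThreshold,
               posteriorThreshold = posteriorThreshold)
}

## ---------------------------------------------------------------------------
## Result objects
## ---------------------------------------------------------------------------

#' Called-cell set
#'
#' Result of [callCells()]: the barcodes judged to contain cells, based on
#' the total-UMI distribution, together with the threshold used.
#'
#' @slot calledBarcodes barcodes passing the threshold.
#' @slot expectedCells user-supplied expected recovered cell count.
#' @slot thresholdUmi UMI total that a called barcode must strictly exceed.
#' @slot totals named per-barcode total UMI counts (all barcodes).
#' @export
setClass("CellSet", representation(
  calledBarcodes = "character",
  expectedCells = "integer",
  thresholdUmi = "numeric",
  totals = "numeric"))

setValidity("CellSet", function(object) {
  if (!all(object@calledBarcodes %in% names(object@totals)))
    return("calledBarcodes must be a subset of the barcodes in totals")
  if (length(object@calledBarcodes) &&
      any(object@totals[object@calledBarcodes] <= object@thresholdUmi))
    return("every called barcode must exceed thresholdUmi")
  TRUE
})

#' Species-mixing (barnyard) call result
#'
#' @slot calls per-barcode data.frame: barcode, per-species UMI totals,
#'   majority species, significance flags and final label.
#' @slot cutoffs named per-species significance cutoffs.
#' @slot observedMixedFraction fraction of called barcodes labelled mixed.
#' @slot inferredMultipletRate twice the observed mixed fraction (capped at 1).
#' @export
setClass("SpeciesCallResult", representation(
  calls = "data.frame",
  cutoffs = "numeric",
  observedMixedFraction = "numeric",
  inferredMultipletRate = "numeric"))

#' Normalized expression matrix
#'
#' Holds both the log-scale normalized matrix (median-of-totals scaling then
#' `ln(1+x)`) and its per-gene standardized version (mean 0, sd 1), plus the
#' statistics needed to reproduce either.
#'
#' @slot logNorm sparse genes x cells log-normalized matrix.
#' @slot standardized dense genes x cells z-scored matrix (zero-variance
#'   genes removed).
#' @slot scaleFactors per-cell multiplier `median(totals)/total`.
#' @slot geneMeans,geneSds per-gene statistics used for standardization.
#' @slot droppedGenes genes removed (all-zero or zero variance).
#' @slot droppedCells cells removed (zero total).
#' @export
setClass("NormalizedMatrix", representation(
  logNorm = "ANY",
  standardized = "matrix",
  scaleFactors = "numeric",
  geneMeans = "numeric",
  geneSds = "numeric",
  droppedGenes = "character",
  droppedCells = "character"))

#' Dimensionality-reduction and k-means clustering result
#'
#' @slot labels per-cell cluster label in `1..k`.
#' @slot k number of clusters of the reported labelling.
#' @slot sse named within-cluster sum of squared errors per candidate k
#'   (scree).
#' @slot pcs cells x nPcs principal-component projections.
#' @slot tsne optional cells x 2 embedding (decorative; `NULL` when Rtsne is
#'   not installed or not requested).
#' @slot seed RNG seed used.
#' @export
setClass("ClusterResult", representation(
  labels = "integer",
  k = "integer",
  sse = "numeric",
  pcs = "matrix",
  tsne = "ANY",
  seed = "integer"))

#' Reference expression profile set
#'
#' Mean expression profiles of purified populations plus a containment map
#' recording which populations are biological subsets of others (e.g. naive
#' CD4+ cells within CD4+ T-helper cells), used by the classification
#' tie-break rule.
#'
#' @slot profiles genes x populations matrix of mean expression.
#' @slot containment named list: population -> character vector of
#'   populations that are subsets of it.
#' @export
setClass("ReferenceProfileSet", representation(
  profiles = "matrix",
  containment = "list"))

setValidity("ReferenceProfileSet", function(object) {
  pops <- colnames(object@profiles)
  if (is.null(pops)) return("profiles must have population column names")
  if (length(object@containment)) {
    if (!all(names(object@containment) %in% pops))
      return("containment names must be populations")
    ## acyclicity: subset relation must never point back at an ancestor
    for (p in names(object@containment)) {
      seen <- p; frontier <- object@containment[[p]]
      while (length(frontier)) {
        if (any(frontier %in% seen)) return("containment map must be acyclic")
        seen <- c(seen, frontier)
        frontier <- unlist(object@containment[frontier], use.names = FALSE)
      }
    }
  }
  TRUE
})

#' @rdname ReferenceProfileSet-class
#' @param profiles genes x populations matrix.
#' @param containment named list of subset relations.
#' @return A `ReferenceProfileSet`.
#' @export
referenceProfileSet <- function(profiles, containment = list()) {
  methods::new("ReferenceProfileSet", profiles = as.matrix(profiles),
               containment = containment)
}

#' Fitted genotype mixture model
#'
#' Posterior summaries of the binomial-mixture model over per-cell SNV
#' allele counts, estimated by Gibbs sampling (K = 2) or in closed form
#' (K = 1).
#'
#' @slot K number of genomes in the model (1 or 2).
#' @slot genotypeProb sites x 3 x K array of genotype posteriors over
#'   R/R, R/A, A/A.
#' @slot cellProb cells x K matrix of genome-assignment posteriors.
#' @slot cellMap per-cell MAP genome index.
#' @slot cellMapProb posterior probability of the MAP genome.
#' @slot mixtureFraction fraction of cells assigned to the minor genome.
#' @slot diagnostics list: relabelling rounds/flips, chain agreement, seed.
#' @export
setClass("GenotypeModel", representation(
  K = "integer",
  genotypeProb = "array",
  cellProb = "matrix",
  cellMap = "integer",
  cellMapProb = "numeric",
  mixtureFraction = "numeric",
  diagnostics = "list"))

setValidity("GenotypeModel", function(object) {
  if (nrow(object@cellProb) &&
      any(abs(rowSums(object@cellProb) - 1) > 1e-6))
    return("per-cell assignment posteriors must sum to 1")
  gsum <- apply(object@genotypeProb, c(1, 3), sum)
  if (length(gsum) && any(abs(gsum - 1) > 1e-6))
    return("per-site genotype posteriors must sum to 1")
  if (object@mixtureFraction < 0 || object@mixtureFraction > 1)
    return("mixtureFraction must be in [0, 1]")
  TRUE
})
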