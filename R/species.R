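## Barnyard (species-mixing) analytics: species assignment per barcode,
## multiplet rate inference, barcode crosstalk, and expected multiplet
## composition from cluster sizes.

perSpeciesTotals <- function(object, cells) {
  sp <- geneSpecies(object)
  if (is.null(sp)) stop("matrix genes carry no species tags")
  species <- sort(unique(sp))
  m <- umiCounts(object)[, cells, drop = FALSE]
  tot <- vapply(species, function(s)
    Matrix::colSums(m[sp == s, , drop = FALSE]), numeric(length(cells)))
  if (length(cells) == 1L) tot <- matrix(tot, nrow = 1L,
                                         dimnames = list(cells, species))
  tot
}

#' Assign called barcodes to species and flag cross-species multiplets
#'
#' Each called barcode gets a per-species UMI total. A barcode's count for
#' species X is significant when it exceeds the `percentile` quantile
#' (default the 1st percentile, i.e. the count sits inside the top 99%) of
#' the species-X totals among barcodes whose majority species is X. A
#' barcode significant in more than one species is labelled `mixed`;
#' otherwise it is labelled with its majority species.
#'
#' @param object a [GeneBarcodeMatrix-class] with species-tagged genes.
#' @param cellSet a [CellSet-class] (or character vector of barcodes).
#' @param percentile significance quantile within the majority-species
#'   distribution (default 0.01).
#' @return A [SpeciesCallResult-class].
#' @export
classifySpecies <- function(object, cellSet, percentile = 0.01) {
  cells <- if (methods::is(cellSet, "CellSet")) calledBarcodes(cellSet)
           else cellSet
  tot <- perSpeciesTotals(object, cells)
  species <- colnames(tot)
  if (length(species) < 2L) stop("need at least two species")
  majority <- species[max.col(tot, ties.method = "first")]
  cutoffs <- vapply(species, function(s) {
    own <- tot[majority == s, s]
    if (!length(own))
      stop("species '", s, "' has no majority-assigned barcodes; ",
           "significance cutoff undefined")
    unname(quantile(own, probs = percentile))
  }, numeric(1))
  sig <- sweep(tot, 2L, cutoffs, ">")
  label <- ifelse(rowSums(sig) > 1L, "mixed", majority)
  calls <- data.frame(barcode = cells, tot, majority = majority,
                      label = label, stringsAsFactors = FALSE,
                      check.names = FALSE, row.names = NULL)
  mixedFrac <- mean(label == "mixed")
  methods::new("SpeciesCallResult", calls = calls, cutoffs = cutoffs,
               observedMixedFraction = mixedFrac,
               inferredMultipletRate = inferMultipletRate(
                 sum(label == "mixed"), length(cells)))
}

#' Inferred multiplet rate
#'
#' Twice the observed fraction of barcodes with significant UMI counts
#' from both species: same-species multiplets are invisible in a barnyard
#' design, so with roughly balanced loading the observable cross-species
#' multiplets are about half of all multiplets.
#'
#' @param nMixed number of dual-significant barcodes.
#' @param nCells number of cell-containing barcodes.
#' @return inferred rate in \[0, 1\] (capped at 1 with a warning).
#' @export
inferMultipletRate <- function(nMixed, nCells) {
  stopifnot(nCells > 0, nMixed >= 0, nMixed <= nCells)
  r <- 2 * nMixed / nCells
  if (r > 1) {
    warning("inferred multiplet rate above 1; capping")
    r <- 1
  }
  r
}

#' Barcode crosstalk per species
#'
#' For the barcodes purely labelled with species X, the fraction of their
#' UMIs that belong to any other species (mixed barcodes excluded). A
#' proxy for ambient RNA / barcode contamination.
#'
#' @param object a [GeneBarcodeMatrix-class] with species-tagged genes.
#' @param result a [SpeciesCallResult-class] (or a named label vector).
#' @return named numeric, one fraction per species; `NA` when a species
#'   has no pure barcodes.
#' @export
crosstalkFraction <- function(object, result) {
  labels <- if (methods::is(result, "SpeciesCallResult"))
    setNames(result@calls$label, result@calls$barcode) else result
  tot <- perSpeciesTotals(object, names(labels))
  species <- colnames(tot)
  out <- setNames(rep(NA_real_, length(species)), species)
  for (s in species) {
    pure <- names(labels)[labels == s]
    if (!length(pure)) next
    sub <- tot[pure, , drop = FALSE]
    out[s] <- sum(sub[, species != s]) / sum(sub)
  }
  out
}

#' Expected multiplet composition from cluster sizes
#'
#' Probability (in percent) that one GEM co-encapsulates one cell from
#' each member cluster, up to a constant: the product of the member
#' clusters' relative sizes.
#'
#' @param clusterFractions named fractions in \[0, 1\].
#' @param members cluster names to co-encapsulate.
#' @return expected fraction, in percent.
#' @export
expectedMultipletComposition <- function(clusterFractions, members) {
  missing <- setdiff(members, names(clusterFractions))
  if (length(missing))
    stop("unknown cluster(s): ", paste(missing, collapse = ", "))
  f <- clusterFractions[members]
  stopifnot(all(f >= 0 & f <= 1))
  100 * prod(f)
}
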