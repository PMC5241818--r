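# dropletCounts

Digital counting, cell calling and genotype demultiplexing for
droplet-based 3' single-cell RNA-seq.

In droplet scRNA-seq, each cell is captured in a GEM (gel bead in
emulsion) whose bead tags every cDNA with a 14 nt cell barcode from a
designed whitelist and a 10 nt unique molecular identifier (UMI).
Turning the resulting reads into a trustworthy molecule count matrix —
and then into biology — takes a chain of small, exacting decisions:
which observed barcodes are sequencing errors of real ones, which UMIs
are valid, which reads are PCR copies, which barcodes contain cells,
how many droplets caught two cells, and (for pooled or transplant
samples) which cell came from which person. `dropletCounts` implements
that chain end to end for people building or validating scRNA-seq
processing pipelines, with seeded synthetic-data generators so every
step is testable against a known truth without any sequencing data.

## What it computes

**Barcode correction.** A non-whitelist barcode is corrected to a
whitelist sequence at Hamming distance 1 when the posterior

&nbsp;&nbsp;&nbsp;&nbsp;P(c | obs) ∝ prior(c) · 10^(−q/10)

(q the Phred quality at the mismatched base, prior from the observed
barcode count distribution) reaches 0.975. UMIs must have all base
qualities > 10 and not be homopolymers; a UMI one substitution away
from a richer UMI of the same cell and gene is collapsed into it; one
record is kept per (barcode, UMI, gene). Cell calling keeps every
barcode above 10% of the rank-n barcode's total UMIs, n being 1% of
the expected cell count.

**Barnyard analytics.** With two species mixed, a barcode significant
in both species' UMI distributions (inside the top 99% of each) is a
cross-species multiplet, and the inferred multiplet rate is twice the
observed mixed fraction. Crosstalk is the other-species UMI fraction
in pure barcodes.

**Expression analytics.** Median-of-totals normalization with ln(1+x),
per-gene standardization, variable-gene ranking by binned normalized
dispersion |d − median_bin(d)| / MAD_bin(d), PCA + k-means clustering
with an SSE scree, cluster markers by mean-vs-pooled-median difference,
Spearman classification against purified reference profiles with a
subset tie-break, and mean-profile comparison between samples.

**Genotype demultiplexing.** Per-cell ref/alt UMI counts at
transcriptome SNVs are modelled as a mixture of K ∈ {1, 2} genomes;
at each site the alt count is Binomial(r+a, p) with p ∈ {ε, ½, 1−ε}
for genotypes R/R, R/A, A/A and ε = 0.001. A Gibbs sampler (Rcpp) with
spectral initialization alternates cell-to-genome assignment and
per-genome genotype updates; Stephens relabelling removes label
switching; K = 2 is accepted only when ≥ 90% of cells have assignment
posterior > 0.75. Genotype groups are matched to pure samples by
percent MAP-genotype agreement over shared sites (~98% within an
individual, ~73% between unrelated individuals).

## Worked example

Simulate a human-mouse barnyard experiment with 2% doublets and 0.5%
per-base barcode errors, count it, call cells, and estimate the
multiplet rate; then demultiplex a simulated 90:10 two-donor mixture
from its SNV allele counts:

```r
library(dropletCounts)
set.seed(1)
cfg <- readSimConfig(
  populations = list(
    human = list(nCells = 300, species = "hg19",
                 genes = setNames(rgamma(200, 2), paste0("hg19:G", 1:200))),
    mouse = list(nCells = 300, species = "mm10",
                 genes = setNames(rgamma(200, 2), paste0("mm10:G", 1:200)))),
  umiMean = 400, errorRate = 0.005, doubletRate = 0.02, seed = 1)
sim <- simulateReads(cfg)
res <- countPipeline(sim$records, sim$whitelist)
res$matrix
#> GeneBarcodeMatrix: 400 genes x 600 barcodes
#>   total UMIs: 237293
#>   species: hg19, mm10
cells <- callCells(res$matrix, expectedCells = 600)
cells
#> CellSet: 599 cells called of 600 barcodes (UMI threshold > 84.3)
classifySpecies(res$matrix, cells)
#> SpeciesCallResult: 599 barcodes; hg19=296, mixed=7, mm10=296
#>   observed mixed fraction: 0.01169 -> inferred multiplet rate: 0.02337

mix <- simulateTwoDonorAlleles(donorSimConfig(nCells = 2000,
                                              mixFraction = 0.1, seed = 1))
fit2 <- fitMixture(mix$counts, K = 2, seed = 1)
sel <- selectModel(fitMixture(mix$counts, K = 1), fit2)
evaluateDemux(mix$truth$donor, sel)[c("sensitivity", "ppv",
                                      "calledMixFraction")]
#> $sensitivity [1] 1   $ppv [1] 1   $calledMixFraction [1] 0.1
```

Reading the numbers: 600 GEMs were simulated with a 2% doublet rate;
7 of 599 called barcodes show significant UMI counts from both
species, and doubling that observed fraction (same-species doublets
are invisible in a barnyard design) recovers an inferred multiplet
rate of 2.3%, consistent with the injected 2%. The demultiplexer
separates the 90:10 donor mixture perfectly and calls the minor
fraction at exactly 0.10.

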