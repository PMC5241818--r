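---
title: "Digital counting and genotype demultiplexing for droplet scRNA-seq: models and methods"
author: "dropletCounts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital counting and genotype demultiplexing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropletCounts)
```

# Scope

`dropletCounts` turns aligned reads from droplet-based 3' scRNA-seq into
deduplicated gene-barcode UMI matrices and provides the downstream
analytics that such experiments rely on: cell calling, species-mixing
(barnyard) multiplet estimation, normalization/clustering/classification,
and genotype-free demultiplexing of donor mixtures from transcriptome
SNVs. Alignment and variant calling are upstream of this package: it
consumes aligned records (a TSV dialect or a minimal SAM subset) and SNV
site tables (a minimal VCF subset), never raw reads.

This vignette explains the models, their assumptions, the tunable
parameters, and the design decisions taken where reasonable alternatives
existed. It also describes what the bundled synthetic-data generators do
and, as importantly, what they do not emulate.

# The counting model

Each GEM (gel bead in emulsion) tags all cDNA from its cell with a
14-base cell barcode drawn from a designed whitelist, and each molecule
with a 10-base UMI (a 5-base dialect is supported via configuration).
Counting a molecule means observing at least one read with a valid
barcode, a valid UMI, and a confident, unique gene assignment; reads
sharing (barcode, UMI, gene) are PCR copies of one molecule.

## Barcode correction

An observed barcode on the whitelist is taken at face value. Otherwise
every whitelist sequence at Hamming distance exactly 1 is a candidate
`c`; with `q` the Phred quality at the mismatched base, the likelihood
that `c` was sequenced as the observation is the error probability
`10^(-q/10)`, and

```
posterior(c) = prior(c) * 10^(-q_c/10) / sum over candidates
```

where the prior is the observed frequency of `c` among exact whitelist
matches, plus one pseudocount so that designed barcodes never seen in
the data remain reachable. The correction is accepted only when the
best posterior reaches `posteriorThreshold` (default 0.975); exact ties
go to the lexically first candidate. The observed non-whitelist
sequence itself never competes: it is by definition not a real barcode.

Two modelling choices deserve a note. First, only Hamming-distance-1
neighbours are considered; two sequencing errors in 14 bases are rare
enough (and the posterior small enough) that the extra candidates buy
nothing. Second, priors are computed from all exact matches in the
input before any filtering, so the prior reflects the library's barcode
usage, not the subset that survives later filters.

## UMI validation and collapse

A UMI is valid when every base quality strictly exceeds `umiMinQual`
(default 10, i.e. better than 90% per-base accuracy), it is not a
homopolymer, and contains no N. The quality rule is applied per base —
the conservative reading of a "sequencing quality score" — so one bad
base invalidates the UMI.

Within each (corrected barcode, gene) group, a UMI with strictly fewer
reads than a Hamming-1 neighbour is relabelled to that neighbour. All
decisions are made against the pre-collapse read counts in one pass:
no chains (A to B to C), no action on ties. This guarantees termination
and makes the operation order-independent.

## Duplicates, the matrix, and its metrics

After collapse, exactly one record per (barcode, UMI, gene) triple is
kept; matrix entry (g, b) is the number of distinct retained molecules.
Only confidently mapped reads (MAPQ equal to `confidentMapq`, default
255, the STAR unique-mapper convention) with a unique gene assignment
are counted; reads with ambiguous gene assignments are dropped rather
than rescued. The pipeline reports the stage fractions (valid barcode,
valid UMI, confidently mapped) whose product with the cell-associated
fraction gives the usable-read fraction.

# Cell calling

Cell-containing barcodes are separated from ambient background by the
shape of the total-UMI distribution: with `n = max(1,
round(0.01 * expectedCells))`, every barcode whose total strictly
exceeds 10% of the rank-`n` barcode's total is called. Ranks use
descending totals with ties broken by barcode lexical order, choices
the rule itself does not dictate but reproducibility does. The rule is
monotone: raising a called barcode's total can never un-call it.
Ambient-RNA modelling and knee-point detection variants are explicitly
out of scope.

Downsampling to a target mean UMI count per cell draws each cell's
retained molecules without replacement (multivariate hypergeometric
across its genes), with the per-cell draw `round(rate * total)`. The
package downsamples molecules, not reads; when a protocol speaks of
reads per cell, molecule-level thinning is an approximation that
ignores the read-depth-dependent part of PCR duplication.

# Barnyard analytics

In a two-species mixing experiment only cross-species multiplets are
visible. A barcode's count for species X is *significant* when it
exceeds the 1st percentile of the species-X totals among barcodes whose
majority species is X — i.e. the count sits inside the top 99% of that
species' distribution; the percentile is exposed as a parameter. A
barcode significant in both species is a mixed barcode, and the
inferred multiplet rate is twice the mixed fraction, on the assumption
that the two cell types are roughly equally loaded so same-species
multiplets are as frequent as cross-species ones. That assumption is
documented, not enforced. Crosstalk — ambient RNA appearing under the
wrong barcode — is the fraction of other-species UMIs among purely
labelled barcodes.

The expected composition of a multiplet cluster is the product of the
member clusters' relative sizes (the co-encapsulation probability up to
a constant), reported in percent.

# Expression analytics

Normalization divides counts by the cell total, multiplies by the
median of totals, and applies `ln(1 + x)`; the pseudocount is the
minimal fix for zeros under a natural log. Each gene is then
standardized to mean 0, sd 1; zero-variance genes are excluded and
listed. Variable genes are ranked by normalized dispersion: dispersion
(variance/mean) is computed on the median-scaled — not logged, not
standardized — counts, because variance/mean is a count-scale
statistic; genes are placed in 20 equal-frequency bins by mean
(equal-width bins collapse for skewed means), and each gene's
dispersion is centred by its bin median and scaled by the bin's raw
median absolute deviation (no 1.4826 consistency factor; a zero MAD is
guarded by 1e-12). Ties and orderings always fall back to gene ID, so
results are invariant to input gene order.

PCA runs on the standardized matrix of the selected genes; k-means with
ten restarts on the first 50 PCs (fewer when the data are smaller)
labels the cells, with the within-cluster SSE over a k range serving as
the scree for choosing k. tSNE is available for visualization when the
Rtsne package is installed, and is deliberately decorative: nothing
downstream consumes it and no test asserts its coordinates.

Cluster markers are scored as the cluster's mean log-normalized
expression minus the *median* over the cells pooled from all other
clusters; a mean over the other cells is available as an option (the
two readings both appear in common practice; the median is robust to a
single divergent cluster). Cluster relationships are summarized by
average-linkage hierarchical clustering on one minus the Pearson
correlation of cluster mean profiles.

Classification against purified reference profiles assigns each cell
the population with the highest Spearman correlation (average ranks on
ties). Because some purified populations contain others (CD4+ T-helper
cells include all CD4+ subsets), a containment map records the subset
relations, and when the winner contains the runner-up the cell is
reassigned to the runner-up — once, mirroring how overlapping sorted
populations are disambiguated in practice.

Sample-level comparison reduces each sample to per-gene mean counts
over genes detected in either sample, reporting their Pearson
correlation and the genes whose mean ratio exceeds a fold threshold
with a pseudocount of one on both means to guard empty denominators.

# Genotype demultiplexing

The per-cell allele counts at biallelic transcriptome SNVs are modelled
as a mixture of K genomes (K = 1 or 2). At a site with `r` reference
and `a` alternate UMIs, the alt count is Binomial(r + a, p) with `p`
fixed by the genotype: the error rate for R/R (default 0.001), 0.5 for
R/A, one minus the error rate for A/A. Sites are independent given the
genotypes; uncovered sites contribute nothing. Priors are uniform over
the three genotypes per site per genome and uniform over genome
assignment — deliberately minimal, since the model-selection rule, not
the prior, gates detection.

For K = 1 the posterior factorizes and is computed in closed form: the
per-site genotype posterior is the normalized pooled-count likelihood.
For K = 2 a Gibbs sampler alternates (i) sampling each cell's genome
from its likelihood under the current genotype sets and (ii) sampling
each genome's genotype at each site from its assigned cells' counts.
The default schedule is 500 sweeps with 200 discarded as burn-in, two
independent chains, all configurable.

## Initialization

A mixture sampler of this shape has a symmetric mode in which both
genomes adopt the majority genotypes and every cell's assignment
posterior hovers at 0.5. With thousands of cells that mode is
effectively absorbing: a genome's genotype update pools so many cells
that a fluctuation large enough to specialize one genome toward a small
minority never occurs. Random initialization therefore cannot separate
even a balanced mixture reliably at scale. The package instead seeds
each chain spectrally: per-site Pearson residuals of the alt-allele
fraction against the pooled site frequency form a sparse cells-by-sites
matrix in which a second genotype is a rank-one signature; power
iteration extracts the leading singular pair, a deterministic 1-D
2-means split of the per-cell score seeds the assignment, and each
genome's genotypes are initialized at the pooled MAP of its own seed
cells. When no second genome is present the leading direction is noise,
the two seeded genotype sets coincide, and the chain settles into the
symmetric mode — which is exactly what the selection rule then reads as
"no mixture".

## Label switching, selection, and comparisons

Mixture posteriors are invariant under permutation of genome labels, so
per-iteration assignment probabilities are relabelled by Stephens'
decision-theoretic scheme: iteratively choose each iteration's
permutation (for K = 2, flip or keep) to minimize the Kullback-Leibler
divergence to the running average, until the permutations stabilize.
Chains are then aligned to each other by their mean assignment
probabilities and merged; posteriors are post-burn-in sample
frequencies, and a cell's confidence is the posterior frequency of its
MAP genome.

The two-genome model is selected only when at least 90% of cells have a
MAP posterior strictly above 0.75; otherwise K = 1 is reported and the
mixture is below the detection level. Both thresholds are parameters.
On data of the kind the bundled generator produces (6,000 cells, about
50 covered sites per cell, 73% between-donor genotype agreement), the
selection rule accepts K = 2 down to a 1% minority; the practical
detection floor on real data is higher, because variant-calling errors,
allele-specific expression, doublets and uneven coverage all blunt the
spectral signature in ways the generator deliberately omits.

Genotype sets are compared by percent agreement of MAP genotypes over
shared informative sites (posterior above the uniform 1/3); an
expected-dosage correlation is available as an alternative but off by
default, since agreement over sites is the directly interpretable
quantity. Same-individual pairs sit near 98% agreement, unrelated pairs
near 73%, which is what makes the comparison useful for matching an
inferred genotype group to a pure reference sample.

A simpler SNV path covers the two-cell-line design: sites passing
quality filters (QUAL at least 100, at least 10 supporting UMIs from at
least 2 cells) and observed exclusively in one of two known groups
score each cell by its fraction `f` of group-B-enriched observations;
`f` below 0.2 labels the cell A, above 0.8 labels it B, the band
between is a multiplet, and the inferred multiplet rate again doubles
the observed one.

# Synthetic data: what it does and does not show

Every input format has a seeded generator with full truth bookkeeping,
so the entire pipeline is testable offline.

The read generator emulates: negative-binomial per-cell UMI totals
(size 10 by default, giving the 30-45% coefficient of variation range
typical of cell lines), population-specific gene weights with optional
species tags, doublets (a GEM capturing a second cell drawn in
proportion to population sizes), ambient molecules drawn from the
pooled gene distribution, per-base substitution errors on barcodes and
UMIs, and PCR read duplication. Base qualities are two-level by design
— Q30 everywhere, Q10 at the substituted positions — so the posterior
correction path is exercised deterministically rather than across a
continuum of qualities. UMIs within a (cell, gene) group are
rejection-sampled to be pairwise more than one substitution apart and
never homopolymers; this makes the generator's truth table exactly the
set the pipeline should recover at zero error rate, turning "pipeline
equals truth" into an exact assertion instead of a probabilistic one.

The donor generator draws per-site alt frequencies uniformly on
[0.1, 0.9], genotypes in Hardy-Weinberg proportions within each donor,
and copies the first donor's genotype at an identity-by-state fraction
of sites (0.73 between unrelated donors; 0.98 emulates a
same-individual replicate); coverage is sparse (about 50 covered sites
per cell by default) with 1 + Poisson(1) UMIs per covered site and
binomial allele observation error 0.001.

Not emulated, deliberately: transcript length/GC bias, splicing,
library-depth gradients, variant-calling artefacts, allele-specific or
bursty allelic expression, doublets in the allele counts, and
cell-type-dependent SNV coverage. Passing tests on this synthetic data
therefore demonstrate the correctness of the algorithms under their own
stated model, not their field performance on real libraries; the
detection floor of the demultiplexer in particular is optimistic here
relative to real transcriptomes.

# Numerical choices and degenerate inputs

* Binomial log-likelihoods use `lchoose` directly; no-coverage sites
  contribute exactly 0.
* The Stephens relabelling averages are clamped away from 0/1 by 1e-12
  before logs; non-convergence after 100 rounds returns the current
  labelling with a warning.
* Power iteration runs 30 sweeps; an exactly zero singular vector
  (possible only in degenerate toy data) falls back to a random split.
* Zero-total cells are dropped with a warning before normalization;
  all-zero and zero-variance genes are excluded and listed.
* Empty record streams produce empty matrices with NA stage metrics,
  not errors.
* All randomized routines take explicit seeds; k-means uses a fixed
  seed with ten restarts, and the Gibbs sampler uses R's RNG so that
  `set.seed` governs the C++ chain too.

# Problem sizes used in the test-suite

The package's own validation runs at sizes chosen to exercise the
operating points that matter while staying desk-scale: counting-core
round trips at 40-120 simulated cells; clustering recovery at 120-180
cells with planted effects of eight- to ten-fold; and demultiplexing at
the full 6,000-cell design with about 50 covered sites per cell for the
3% operating point, five seeds for the averaged sensitivity/PPV figures
and ten seeds for the detection-floor property. The acceptance script
reruns the 6,000-cell experiment end to end.

# Known limitations

* K is limited to one or two genomes; pooled designs with more donors
  need a different selection procedure.
* Doublets are not modelled inside the mixture; they surface only
  through the separate SNV-fraction labelling path.
* The multiplet-rate doubling assumes balanced two-population loading.
* Molecule-level downsampling approximates read-level subsampling.
* The 5-base UMI dialect shortens, but does not re-tune, the UMI
  validity rules.
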