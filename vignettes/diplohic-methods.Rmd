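---
title: "Haplotype-resolved 3D genome analysis with diplohic: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-resolved 3D genome analysis with diplohic: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`diplohic` implements a complete desk-scale pipeline for haplotype-resolved
chromatin-conformation analysis in F1 hybrids: contacts tagged with
informative SNV votes are assigned to parental haplotypes, the resulting
diploid maps are normalized and segmented into compartments and TADs,
promoter-enhancer interactions (PEIs) are called against a domain-aware
background, and allelic differences are tested along three axes -
developmental stage, parent of origin, and parental breed - together with
allele-specific expression and population sequence-divergence statistics.
Every stage is validated against a synthetic diploid generator that plants
recoverable structure, so the pipeline is testable end to end without any
external data.

This vignette records the models, the tunable parameters, and the design
choices made where the design was genuinely open. It states no empirical
result that the package's tests and `scripts/acceptance.R` do not themselves
compute.

# The synthetic diploid generator

The generator is first-class, tested code: its defaults define the study
conditions every recovery property is measured under.

**Variants.** Heterozygous SNV counts per chromosome are
Poisson(length in kb x density), with density defaulting to 4.42 per kb -
the density characteristic of broiler x layer F1 hybrid chickens. Variants
are uniformly placed, phased (`0|1` / `1|0` at random), and written as a
minimal VCF-like TSV. Coordinates are 0-based, half-open throughout.

**Contacts.** Cis contact probability over binned pairs follows
`d^decay_exponent` (default -1.0, the classic fractal-globule slope), with
the diagonal placed at half a bin so the realized bin-level decay is an
exact power law. The probability is modulated multiplicatively by a planted
compartment checkerboard (same-label pairs enriched), planted TAD blocks
(co-domain pairs enriched), and planted promoter-enhancer peaks; a uniform
random-ligation fraction (default 2%) models library noise. A configured
fraction of contacts is routed between homologs (default 4.62%, the
fraction observed in hybrid chicken maps) with near-diagonal elevation
inside planted pairing blocks, and a small fraction connects non-homologous
chromosomes (default 0.26%). Each read end spans 150 bp (paired-end 150
sequencing) and collects one haplotype vote per overlapping SNV; votes flip
with probability 0.1% to exercise conflict handling. True haplotype labels
are carried alongside for benchmarking.

The generator emulates the marginal statistics that matter for the methods
under test - decay, checkerboard, block, peak and pairing structure, vote
sparsity and error. It does not emulate restriction-fragment geometry,
duplicate reads, mappability variation, copy-number differences, or
distance-dependent noise correlations; passing tests therefore demonstrate
correctness of the inference machinery under a clean generative model, not
robustness to every artifact of real libraries.

**Expression and populations.** Per-gene maternal/paternal counts are
binomial splits of Poisson totals. Planted breed effects act on the
haplotype of the given breed in every sample, so reciprocal crosses see the
effect flip parental role; parent-of-origin effects (off by default - the
avian null) act on the maternal haplotype in both directions. Expression is
coupled to planted enhancers via a per-enhancer boost (default 1.5x),
which is what makes the RPS-expression association testable. Two-breed
genotypes are drawn from Balding-Nichols frequencies: given ancestral
frequency `p` and per-site target FST `F`, population frequencies are
`Beta(p(1-F)/F, (1-p)(1-F)/F)`.

# Phasing

Read-end labels follow unanimity: all votes for one haplotype assign it,
no votes leave the end unknown, mixed votes mark a conflict. Contact
routing accepts single-end evidence for same-chromosome pairs (cis contacts
dominate diploid maps, so a single informative end is reliable evidence),
requires both ends phased to opposite haplotypes for an inter-homolog call,
sends any-evidence inter-chromosomal pairs to the heterolog table, and
discards conflicted records outright rather than down-weighting them -
simpler and conservative. Both-unknown cis pairs enter a pool that local
imputation allocates to the two haplotypes in proportion to phased counts
in a +/-5-bin window around both anchors (windows with no signal split
50/50), using stochastic rounding so totals are conserved exactly and the
allocation is correct in expectation. The window half-width is a parameter;
+/-5 bins is wide enough to stabilize the ratio at typical coverage and
narrow enough to track local haplotype structure.

Map resolution follows the standard rule: the smallest candidate bin size
at which at least 80% of bins contain at least 1000 reads.

# Normalization and concordance

Knight-Ruiz balancing solves `x_i (Mx)_i = 1` by the inexact-Newton
inner-CG scheme, followed by a damped fixed-point refinement
(`x <- x / sqrt(rowsum)`) that certifies a row-sum coefficient of variation
below tolerance (default 1e-8); zero-marginal bins are masked first and the
mask propagates downstream. Quantile normalization operates within genomic
distance strata by default, because contact values are decay-confounded:
each sample's nonzero values are mapped to the mean order statistics of all
samples (rank ties broken by first occurrence, which keeps output multisets
identical across equal-length samples). The pipeline order is KR first,
then quantile - balancing corrects within-sample biases; quantile
normalization then aligns cross-sample distributions.

Concordance between maps is scored in the random-walk style: both matrices
are row-normalized to transition matrices, walked `t = 3` steps, and scored
`1 - sum|R1^t - R2^t| / mean(nnz rows)`. Identical maps score exactly 1.

# Homolog pairing

The homolog pairing score of bin `i` is the log2 ratio of the
inter-homolog intensity in the aligned-diagonal window `(i +/- 2, i +/- 2)`
to the chromosome-wide mean of such windows. Two numerical choices make the
printed definition exact in practice: the matrix is depth-normalized to a
canonical total of one million inter-homolog contacts before the
one-contact pseudocount is added, so the track is exactly invariant to
library depth; and bins whose window is truncated by the chromosome end are
masked, because truncated windows have inflated variance (the same reason
insulation tracks mask their edges). Tightly-paired loci are bins above
Q3 + 1.5 x IQR of the genome-wide score (type-7 quartiles, pinned because
the rule is threshold-sensitive), merged across runs and across single
masked bins. Feature enrichment uses Fisher's exact test for binary
features and the Wilcoxon rank-sum test for continuous ones.

# Compartments

Per chromosome, the balanced matrix is converted to observed/expected by
distance, its Pearson correlation matrix is eigendecomposed, and the first
component is oriented so bins with the higher orientation covariate (gene
density or GC content) load positive: positive index = A, the active
compartment. When PC1 tracks the covariate poorly (|r| < 0.2, typically
when it captures chromosome arms), PC2 is substituted and flagged.
Chromosome tracks are concatenated and scaled to genome-wide SD 1 - the
unit in which the differential thresholds are meaningful. Differential
calling between paired groups classifies bins as *switched* (group means
of opposite sign, both exceeding 0.1 in magnitude so noise-level sign flips
are not called) or *variable* (same sign, |difference| above the axis
threshold - 1.0 between neighboring stages, 0.3 between breeds or parents
of origin - with paired t-test p < 0.05). Calling runs at 20-kb bins at a
single scale; chicken microchromosomes are short, and the planted-truth
tests show single-scale calling recovers block structure cleanly.

# TADs

The directionality index of a bin contrasts its upstream and downstream
window sums A and B (window 500 kb): with `E = (A+B)/2`, the index is
`sign(B-A) ((A-E)^2 + (B-E)^2)/E`. The insulation index is the mean
contact in the square crossing the bin (offsets 1..s each side, 100-kb
square), as log2 ratio to the chromosome mean. The consensus caller is the
package's own combination rule: insulation minima with windowed prominence
at least 0.1 are boundary candidates, retained when the directionality
index switches from a negative to a positive regime within +/-2 bins (one
domain ending, the next beginning); domains shorter than 3 bins are
dropped, so gaps are allowed. Threshold regime detection was chosen over
HMM segmentation of the DI track: it is deterministic, has two transparent
parameters, and recovers planted boundaries within one bin.

The local boundary score is
`LBS = 1 - mean(cross-square) / mean(flanking within-side triangles)`,
clipped to [0, 1], so the differential threshold |dLBS| >= 0.2 (with
paired t p < 0.05) lives on an absolute insulation scale. Note that on
distance-decaying matrices the LBS of a non-boundary is positive (cross
pairs are longer-range than within pairs); differences, not absolute
values, carry the signal. Partition similarity implements the Measure of
Concordance on overlap lengths (defined as 1 when both partitions are a
single domain) and the Variation of Information over length-weighted domain
distributions in natural log.

# Promoter-enhancer interactions and the regulatory potential score

The expected model is two-level: a decay fit inside each TAD (domains with
fewer than 20 pair observations fall back to the background) and a
genome-wide fit for cross-domain pairs. Each fit is a power law with an
additive constant, `mu(d) = A d^b + c`, estimated by weighted nonlinear
least squares on the per-distance means (zero pairs included in the means);
the constant absorbs the uniform random-ligation background, which a pure
log-log line cannot represent - it tilts the slope and systematically
miscalls the distance extremes. The full hierarchical domain-merging of
PSYCHIC-style callers is deliberately replaced by this two-level model plus
a Poisson upper-tail test per promoter-candidate pair within the bridging
window of 25 kb to 1 Mb, with BH-FDR (default 0.05) across all tested
pairs: the same inferential target, fully specified, and desk-scale.
Promoters are the TSS bin (TSS +/- 2.5 kb at 5-kb binning); multi-TSS
genes use the most upstream TSS.

The regulatory potential score aggregates a gene's called PEIs as
`RPS = log2(1 + sum max(O/E - 1, 0))`: monotone in both enhancer count and
intensity, zero for genes with no PEIs, and on the scale where the printed
differential thresholds (3 between stages, 0.3 between breeds or parents)
are meaningful. O/E excess rather than raw intensity is the default
aggregation (a raw-intensity mode is exposed) because it is invariant to
depth and to the distance profile of a gene's enhancers.

# Allelic expression and the imprinting screen

Gene-level allelic counts are sums over exonic heterozygous SNVs; genes
without informative exonic SNVs, with fewer than 20 informative reads, or
below 0.5 TPM in every sample are untestable. Bias is a two-sided exact
binomial test against 0.5 with BH-FDR, and a biased call additionally
requires the allelic ratio outside [0.3, 0.7] - the q-value alone flags
biologically negligible imbalances at high depth. The reciprocal-cross
screen is the key identification step: a gene biased toward the same
parental role in both cross directions is an imprinting candidate; a gene
biased toward the same breed haplotype in both directions (which means
opposite parental roles) is a breed effect. The generator's default plants
no parent-of-origin effect, mirroring the avian null, and the screen's
null calibration is asserted over 200 simulated genomes.

# Sequence divergence

The identity score of a region is `1 - mismatched/length`, counting one
base per differing SNV site and indel lengths clipped to the region;
insertions contribute their inserted length at the anchor point (a
convention the field leaves open; by-length counting matches the
"percentage of identical nucleotides" reading). Per-site FST is the
Weir-Cockerham 1984 variance-components estimator `a/(a+b+c)`; monomorphic
sites and sites with an uncalled population are missing. The genome-wide
summary is the weighted (ratio-of-sums) estimate - the standard multi-site
Weir-Cockerham summary - which is also the quantity that recovers
Balding-Nichols targets; the unweighted mean of per-site ratios is biased
toward zero. The high-FST screen keeps sites with FST >= 0.75 (the
threshold value itself is retained), and the enrichment report runs its
five tests raw, mirroring figure-wise testing.

# Pipeline, determinism, and problem sizes

`run_pipeline()` chains all stages on one config and writes plain-text
outputs (sparse triplets, BED/bedGraph/BEDPE, TSV) plus a summary; the log
records every pinned threshold. All randomness derives from the single
config seed (stage seeds are fixed offsets), and stochastic rounding in
imputation draws from the same stream, so a rerun with the same config is
byte-identical - asserted by checksum in the tests.

Test and acceptance problem sizes are chosen to make each property
measurable with comfortable margins while staying desk-scale: one million
contacts for phasing precision and pairing recovery (a 20-Mb chromosome at
20-kb bins, 5% of the genome planted at 10x pairing), a 20-Mb chromosome
for compartment sign agreement, ten 200-800-kb TADs for boundary recovery,
fifty simulated 5-Mb genomes at 5-kb bins with 5x peaks of at least 20
expected counts for PEI recall/FDR, 200 simulated genomes each for the
imprinting and differential-compartment null rates, and 2000 sites at
n = 12 + 12 for FST recovery.

# Known limitations

The generator's independence assumptions (Poisson counts, independent
vote errors, uniform ligation noise) are idealizations; FDR control under
correlated real-data noise is not demonstrated here. The compartment
caller returns a single PC per chromosome and does not call
sub-compartments. TAD calling is single-level (no nesting, no loops). The
PEI caller takes enhancer candidates as given rather than discovering
them from chromatin marks. The imprinting screen tests direction-pooled
counts and does not model family-level random effects.
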