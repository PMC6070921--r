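---
title: "Methods: targeted profiling of AR splice variants and gene aberrations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: targeted profiling of AR splice variants and gene aberrations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Castration-resistant prostate cancer (CRPC) frequently retains androgen
receptor (AR) signalling through a spectrum of AR aberrations: amplification
of the AR locus, ligand-binding-domain point mutations (L702H, H875Y,
T878A), genomic structural rearrangements with a breakpoint inside the AR
gene (AR-GSRs), and constitutively active splice variants (AR-Vs) that join
a canonical exon to a cryptic exon and lack the ligand-binding domain.
`arvprofiler` implements the analysis layer of a targeted DNA + RNA
sequencing assay that measures all of these in tandem, together with a
synthetic-data generator so that every stage can be validated against known
truth.

## Splice-variant quantification

**Signatures.** Each catalogued splice junction `u -> d` is represented by a
signature sequence: the last 130 bp of the upstream exon concatenated with
the first 130 bp of the downstream exon (truncated if an exon is shorter).
With 150 bp reads this is long enough that any read genuinely spanning the
junction fits inside the signature.

**Assignment.** Reads are matched ungapped against the signature set on both
strands with a mismatch budget (default 3, about 2% of a 150 bp read,
matching the substitution-only error model of the simulator). A valid
alignment must place the read fully inside the signature and cover at least
`min_overhang` (default 10) bases on each side of the exon boundary. Reads
whose best alignment is tied across two or more signatures are discarded as
ambiguous rather than fractionally allocated; ties are broken by mismatch
count first, so only true ties are lost. Restricting alignments to fully
contained reads means that, with 130 bp flanks and 150 bp reads, the
effective overhang floor on one side is `read length - flank = 20` bp; the
rule is symmetric across all signatures sharing an upstream exon, so
fractions are unaffected, and the contract is identical in the production
matcher and in the brute-force oracle used to test it.

The production matcher is a seed-and-extend kernel (pigeonhole: a read with
at most 3 mismatches split into 4 chunks has one error-free chunk, whose
first 16-mer locates the alignment exactly in a k-mer index of the
signatures). The test suite compares it read-for-read against an
independent brute-force kernel that scans every signature at every offset.

**Fractions.** For variant `v` with junction `u -> d`, the reported fraction
is `count(u -> d) / sum(count(u -> *))` over all catalogued junctions
sharing the upstream exon `u` — the variant's share of AR transcript at that
donor site. The denominator is taken literally over the catalog (not over
all reads anchored in `u`), which is the defensible reading of a
signature-file-based counting scheme. The combined AR-V fraction is the sum
of the AR-V3, AR-V7 and AR-V9 point estimates, each over its own
denominator.

**Confidence.** The assay reports the lower endpoint of the two-sided exact
95% binomial (Clopper-Pearson) interval as a conservative per-variant value,
computed as `qbeta(0.025, x, n - x + 1)` (0 when `x = 0`). The interval
family is a package choice: it is valid at the small counts typical of
low-expressed variants and reproducible exactly. Samples whose denominator
is zero are reported not-quantifiable, never as zero.

## Copy-number estimation

Aligned read starts are counted in overlapping 400 bp windows tiled over
the targets (step 200 bp, i.e. 50% overlap — the tiling density is a package
default since only "overlapping" is inherent to the design). Window counts
are scaled by the sample's total on-target reads, divided by the median
scaled control-gene window count (within-sample normalisation needs no
reference cohort and cancels library depth), and the median of these AR
ratios is the copy-number estimate. Because AR is X-linked (one copy in a
male genome) while the control genes are autosomal, the ratio is rescaled
by the configured control ploidy so an unaltered male sample reports 1.0.

Labels apply the rule `> 1` copy = gain, `> 2` copies = amplification to the
estimate. Note that the simulated truth levels 1 and 2 sit exactly on these
thresholds, so for an unbiased estimator the label at those levels is
determined by sampling noise around the boundary; the estimate itself is
accurate to a few percent at the default depths, and levels above 2 label
unambiguously.

## Structural rearrangements

A Breakfast-style split-read caller. Reads that fail to map contiguously
(more than twice the per-segment mismatch budget at their recorded
position) are split-aligned exhaustively against the panel locus: the read
is cut into a prefix and a suffix, each mapped ungapped on either strand
with at most 2 mismatches and at least 25 bp, maximising matched length.
Junction micro-homology makes the split position ambiguous; the split
minimising total mismatches is chosen, leftmost on ties, and truth
comparisons therefore use a small (±5 bp) tolerance. Because a junction
read sequenced from the opposite strand reports the mirrored split, splits
are canonicalised — `(-,-)` folds onto `(+,+)` with breakpoints swapped,
mixed-strand breakpoints are ordered — before clustering.

Splits agreeing in orientation and both breakpoints within 10 bp merge into
events (median breakpoints, support = cluster size). Orientation and
breakpoint order type the event: forward skip = deletion, backward link =
tandem duplication, opposite strands = inversion, different gene regions =
translocation. Events need at least one breakpoint in the AR region and at
least 10 supporting split reads (the assay's cut-off, configurable). VAF is
split support over split support plus contiguous reads spanning the
breakpoint by at least 25 bp on each side. Discordant-pair-only evidence is
deliberately not used to call events: the support threshold is phrased in
split reads.

## Hotspot mutations

A minimal pileup caller over the DNA targets: per-position A/C/G/T counts
from contiguously aligned reads, then a call wherever the most frequent
non-reference allele has depth ≥ 50, VAF ≥ 5% and ≥ 5 alternate reads
(package defaults, exposed as arguments — upstream filtering pipelines vary
and these values keep a 0.2% substitution error rate silent at depths up to
a few thousand). Calls matching a configured hotspot position and alternate
base carry the hotspot's protein-level name (L702H, H875Y, T878A analogs);
naming is a table lookup, not codon translation, since the panel fixes the
nucleotide positions.

## AR-signalling score

Expression counts of the five androgen-responsive genes (KLK3, FKBP5,
TMPRSS2, ACPP, SLC45A3) are divided by the geometric mean of the sample's
three housekeeping genes (TBP, STARD7, DDX1) with a 0.5 pseudocount — a
robust reference-gene scaling; the pseudocount guards dropouts at the cost
of exact scale invariance (negligible above ~50 counts). Per gene, z-scores
are computed across the cohort (n − 1 denominator; a zero-variance gene
contributes 0), and a sample's AR-signalling score is the sum of its five
z-scores. Scores require at least 3 samples. The combined AR-V fraction
classifies samples as negative (0), low (≤ 5% of AR transcript) or high
(> 5%); the 5% boundary goes to "low" because both published inequalities
are strict and a deterministic rule is required.

## Cohort statistics

Group comparisons of the combined AR-V fraction use the two-tailed unpaired
Mann-Whitney U test: exact (network algorithm, via `wilcox.test`) when the
pooled sample size is ≤ 20 without ties, otherwise the normal approximation
with tie and continuity correction. The exact/asymptotic switch point is a
tractability choice. Spearman correlations (each variant's fraction against
the AR-FL junction count of its upstream-exon group, and variant counts
pairwise) use the asymptotic t approximation
`t = rho * sqrt((n - 2) / (1 - rho^2))` on n − 2 degrees of freedom. Raw
p-values are reported for the handful of planned comparisons (a Holm
adjustment is available but off by default). Missing assays are excluded
pairwise-complete, never imputed.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
not the chemistry that produced it:

* **RNA**: transcripts are assembled from the exon catalog (full-length =
  all canonical exons; a variant = canonical exons through its upstream
  exon plus its cryptic exon). Reads (150 bp, single-end — junction counting
  does not need pairs) start uniformly along each transcript; `depth` is
  the expected junction-spanning read count at a full-length-only junction.
  Variant fractions are controlled exactly through isoform abundances
  solved per upstream-exon group.
* **DNA**: 150 bp FR read pairs with truncated-normal fragment lengths
  (mean 180, sd 30, mirroring a 150-200 bp fragment-size protocol),
  fragments placed so that any overlap with a capture target is retained —
  this keeps read-start density uniform across target interiors, which the
  window estimator relies on. Coverage scales with region copy number.
  For each engineered rearrangement, the stated fraction of fragments
  overlapping the breakpoint derives from the rearranged allele, and reads
  crossing it carry the junction sequence with the orientation implied by
  the type. Hotspot alternate alleles are Bernoulli per covering read.
* **Errors** are independent per-base substitutions only (default 0.2%),
  with constant base quality; no indels, PCR duplicates, GC bias or
  per-bait capture-efficiency variation. Coverage is uniform within
  targets.
* **Cohorts**: group-level parameter distributions (fraction ranges, depth
  ranges, alteration probabilities) mirror the study design: hormone-naive
  groups with low variant fractions and unaltered AR versus CRPC-like
  groups with higher fractions, roughly threefold higher AR-FL abundance,
  frequent gains/amplifications and occasional GSRs and hotspot mutations.
  Within a group, variant fractions optionally share a latent quantile with
  the sample's depth (plus jitter), emulating AR-locus expression driving
  variant expression — this is what makes the variant-versus-AR-FL
  correlation a testable property. Negative-binomial draws (size 10)
  around group means provide the expression counts. One master seed drives
  everything; per-sample seeds are derived by a stable string hash, so any
  sample regenerates independently.

Passing tests on these simulations demonstrate correctness of the counting,
estimation and calling machinery under the stated error model; they do not
demonstrate robustness to alignment artefacts, indels, capture bias or
degraded-RNA effects present in real libraries.

## Mock panel and fixture

The shipped mock locus is a deterministic pseudo-random sequence (a local
congruential generator, so building the panel never perturbs R's RNG):
eight canonical exons, five cryptic exons in the intron downstream of exon
3, control-gene targets (FOXA1/SPOP stand-ins) for normalisation, and three
hotspot positions. The exon composition of each named variant (e.g. AR-V7 =
E3->CE3, AR-V9 = E3->CE5, AR-V3 = E2->CE4) is configuration data and a
stand-in: true assay signature sequences are proprietary to a panel design,
and the analysis never depends on which cryptic exon a name maps to. The
fixture file `inst/extdata/mock_ar_panel.yaml` is the same panel serialised;
`load_panel()`/`write_panel()` round-trip it exactly.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open throughout; VCF export converts to
  1-based.
* Zero denominators (fractions, VAF) are reported `NA`, never 0.
* A fully tied Mann-Whitney input returns p = 1 directly (the tie-corrected
  normal statistic is 0/0 there).
* Constant input to the Spearman correlation is an error, not `NA`.
* A saturated upstream-exon group (variant fractions summing to 1) is the
  single-isoform limit: the full-length transcript is dropped.
* Window tiling drops windows that would extend past a target's end; a
  step larger than the window is rejected.

## Problem sizes

The test-suite and acceptance-script simulations use a ~19 kb locus,
junction depths of 150-2400 (20-sample oracle cohorts at depth 2000,
200-replicate recovery runs at depth 1400), DNA coverage 150-2000 with
50-replicate clean-sample screens at depth 500, and 20-seed cohort power
runs at 15 + 15 samples — sizes chosen so each property is measured with
comfortable statistical margin on a single CPU.

## Known limitations

* Ungapped matching only: indel-containing reads are unassignable (RNA) or
  discarded (DNA); there is no novel-junction discovery or transcript-level
  deconvolution.
* The CNV caller reports one summary estimate per sample — no segmentation,
  focal per-exon calls or purity correction.
* The rearrangement caller detects one junction per event and does not use
  discordant pairs as primary evidence; insertions are out of scope.
* Labels at the gain/amplification thresholds are noise-determined when the
  true copy number sits exactly on a threshold (see above).
* The expression model is cohort-relative: z-scores (and thus signalling
  scores) change when the cohort composition changes.
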