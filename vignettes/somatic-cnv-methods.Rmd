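---
title: "Models and methods behind somaticmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind somaticmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(somaticmap)
```

somaticmap analyses a tumor genome against a matched normal using three
coupled procedures: a read-depth copy-number map, paired
genotype-likelihood somatic labelling, and a cancer-gene prioritization
funnel. This vignette records the models, their assumptions, every
tunable that matters, and the design decisions taken where more than one
reasonable choice existed. Nothing here claims an empirical result beyond
what the package's tests and `scripts/acceptance.R` themselves compute.

## The copy-number map

### Binning by mappable bases

Bins accumulate a fixed number of *mappable* reference positions
(`target_mappable`, default 10,000), so genomic bin widths stretch over
unmappable gaps rather than diluting the count signal. GC fraction is
computed over mappable positions only. The last bin of each chromosome
keeps the remainder. Fragments are assigned to bins by their midpoint
under half-open `[start, end)` intervals — each fragment counts exactly
once, and a midpoint on a bin boundary belongs to the bin that starts
there. Fragments on unknown chromosomes or in inter-bin gaps are tallied
and discarded, never fatal.

Coordinates are 0-based half-open everywhere internally and in BED/TSV
output; VCF interaction is 1-based as that format requires.

### GC correction

Coverage depends smoothly on GC content in short-read data. We model the
expected count per bin as an unknown smooth function of GC and estimate
it with `stats::lowess` — locally weighted linear regression with three
bisquare robustness iterations — evaluated on a 201-point grid and
interpolated linearly (constant beyond the observed GC range). The
normalized ratio is `count / curve(gc)`.

* `smoothing_fraction` (span), default **0.3**: wide enough to average
  hundreds of bins at any GC in a genome-scale run, narrow enough to
  track an exponential-shaped bias. The robustness iterations matter in
  the tumor: bins inside copy-altered segments are outliers at their GC
  and are down-weighted, so the curve tracks the dominant (diploid)
  state and ratios remain on the `c/2` scale. This assumes most of the
  genome is at baseline ploidy; a genome that is mostly aneuploid would
  shift the baseline, a standard limitation of depth-only CNV calling.
* Degenerate inputs: a single distinct GC value yields a constant curve
  at the mean count; bins with zero mappable bases or a non-positive
  fitted value get a missing ratio and are excluded from segmentation,
  not imputed.

### Circular binary segmentation

Segmentation operates on `log2(ratio + pseudocount)` with
`pseudocount = 1e-3` — the log scale makes states multiplicatively
equidistant and stabilizes variance; the pseudocount keeps
zero-coverage (copy-0) bins finite. Within each current segment the arc
`(i, j]` maximizing the pooled two-sample t statistic against its
complement is found by an exhaustive `O(n²)` scan (compiled, in
`src/cbs_scan.cpp`); arcs touching a segment end reduce to single change
points. The split is accepted when its permutation p-value
`(1 + #{perm ≥ obs}) / (1 + B)` is below `alpha`, and recursion continues
on the pieces.

* `alpha` = **0.01**, `n_permutations` = **1000**: conventional values
  for permutation-based CBS; both exposed.
* `min_width` = **2** bins for the arc and its complement, so a t
  statistic is always defined.
* Permutations stop early once the exceedance count already guarantees
  `p ≥ alpha`; this cannot change any accept/reject decision, only the
  time spent on splits that will be rejected.
* After recursion, adjacent segments whose log2 means differ by less
  than `merge_threshold` (**0.1**, about a seventh of the one-copy
  spacing at diploid) are merged, smallest gap first — this prunes
  borderline splits that survive the permutation test but are too small
  to be a copy-state change.
* Degenerate inputs: constant series, series shorter than
  `2*min_width`, or all-missing series return a single segment. A
  zero-variance split (noiseless step) has infinite t and is accepted
  against permutations that also reach infinity.
* Missing bins are dropped with index bookkeeping and re-attached to the
  spanning segment afterwards, so segments always tile the chromosome's
  bin index range.

### Copy-state genotyping

Segment mean ratios (ratio scale, not log) are modelled as a 1-D
Gaussian mixture, each segment weighted by its number of contributing
bins — the segment is the observational unit, but a 300-bin segment
carries more information than a 3-bin one. EM uses k-means
initialization with 5 restarts, a shared component variance floored at
`1e-4` (segment means can be nearly noiseless, and an unbounded
likelihood would otherwise favor degenerate components), and BIC over
`k = 1 .. max_copy + 1` components with effective sample size equal to
the total bin weight. Non-convergence after 200 iterations keeps the
best restart with a warning, as overfit `k` values commonly oscillate
and are rejected by BIC anyway.

A component with mean `m` maps to the copy state `c` in `0..max_copy`
(default **6**) minimizing `|m − c/2|`, ties to the smaller state;
components landing on the same state are merged. Each segment takes the
state of its maximum-posterior component together with that posterior.
A single segment (or a single distinct mean) bypasses model selection:
its state is `round(2·mean)` clipped to the valid range.

## Somatic labelling

Each record carries log10 genotype likelihoods for (hom-ref, het,
hom-alt) per sample, under the usual diploid read model: a read supports
the alternate allele with probability `ε` (hom-ref), `1/2` (het) or
`1 − ε` (hom-alt), and the binomial coefficient is omitted because it
cancels in posteriors.

Site filters run first, in the order `no_coverage` (both depths zero),
`min_alt_reads` (≥ 2 supporting reads in the best sample), `min_af`
(allele fraction ≥ 0.1 in at least one sample), `min_site_qual` (QUAL
strictly > 5); the first violated rule is reported. The order puts the
read-support rule before the fraction rule so a 1-read site is reported
as under-supported rather than low-fraction.

Labelling then converts each sample's GL triple to flat-prior posteriors
`P(g) ∝ 10^GL(g)` (normalized in log space) and computes two evidence
scores: the Phred-scaled posterior that the tumor is non-reference and
that the normal is reference. Working on posteriors rather than raw
likelihoods makes the threshold scale-invariant — FreeBayes-style GL
vectors are defined only up to a per-site constant. Both scores are
capped at **200** Phred to avoid infinities when posteriors saturate in
double precision.

Rules, in order of precedence:

1. `shared_low_frequency`: tumor AF < `low_af_cutoff` (**0.25**) *and*
   the normal has ≥ 1 alternate read at AF < `low_af_cutoff`. Applied
   before the evidence rule because its purpose is to remove
   contamination-like artifacts that can carry strong likelihoods.
2. `somatic`: both evidence scores ≥ `min_evidence_phred` (**10**,
   i.e. posterior 0.9).
3. `germline`: the normal's non-reference posterior reaches the same
   threshold.
4. `reference` otherwise; `failed_site_filter` (with reason) when a
   filter fired or a sample has no finite GL.

PL input is accepted and converted as `GL = −PL/10`; the integer
rounding of PL can flip a label only when a posterior sits exactly at
the threshold, which the tests exercise by comparing GL- and PL-encoded
copies of the same records. Multi-allelic records are split into
biallelic ones before labelling: allele `k` keeps the GL entries for
genotypes `0/0`, `0/k`, `k/k` and the allele-depth pair
`(ref, depth_k)`.

## Gene prioritization

Somatic calls join impact annotations on (chrom, pos, ref, alt); pairs
with QUAL strictly > 20 and impact HIGH or MODERATE survive. Gene
symbols map to human homologs through a user-supplied two-column table
(source symbols must be unique; renames are counted
case-insensitively), and the mapped symbols intersect a two-tier cancer
gene census table. The report keeps exactly the census genes with at
least one passing variant, sorted by symbol, with validation columns
rendered `unknown` unless a validation table is supplied. Quality and
impact thresholds are strict inequalities throughout; the same QUAL
field feeds both the site-level (> 5) and gene-level (> 20) filters,
deliberately exposed as two knobs of one quantity.

## The synthetic generator

The generator emulates the statistical structure each stage assumes,
not reads or alignments:

* **Genome**: i.i.d. bases with a piecewise-constant target GC fraction
  per 50 kb window (defaults cycle 0.35/0.45/0.55/0.65), giving bins a
  broad, multimodal GC distribution like a real genome's.
* **Coverage**: normal bins draw `Poisson(μ · f(gc))`, tumor bins
  `Poisson(μ · (c/2) · f(gc))` with `μ = 100` fragments/bin and bias
  `f(gc) = exp(a(gc−0.5) + b(gc−0.5)²)`, default `a = 2, b = 0`. The
  log-linear/quadratic family is the simplest shape the nonparametric
  LOWESS must recover without being told; the bias is shared between
  samples so the expected tumor/normal ratio is exactly `c/2` at any GC.
* **Copy-number truth**: defaults plant states 1, 3 and 4 (segments of
  50–100 bins) on a 4×5 Mb diploid genome — 2,000 bins, large enough
  for stable curve fits and segment statistics while keeping a test run
  in seconds.
* **Variants**: 100 germline (het/hom split at random), 50 somatic
  (tumor het, normal reference) and 20 shared low-frequency artifact
  sites (AF drawn uniformly in 0.05–0.20, identical in both samples —
  the contamination signature rule (b) targets). Depth is
  `Poisson(30)` per sample, `ε = 0.01`; read support is binomial at the
  error-perturbed allele fraction, GLs follow the diploid model, and
  QUAL is the Phred-scaled flat-prior probability that at least one
  sample is non-reference, capped at 200. Zero-depth sites are dropped
  with a message.
* **Gene tables**: each variant is assigned a gene from a 30-gene
  universe with impacts drawn over the four severity classes; the
  homolog table maps most symbols to their uppercase form, renames
  every fifth and omits every tenth, and the census holds every mapped
  third gene, alternating tiers. Deterministic by construction, so the
  end-to-end gene report has an exactly computable truth.

All randomness flows through one seed; each stage derives its own
sub-stream (`derive_seed`) so stages rerun in isolation reproduce
byte-identical artifacts.

What the generator does **not** emulate — and what passing tests
therefore do not demonstrate on real data: mapping artifacts and
repeat-driven coverage structure, overdispersed (non-Poisson) depth,
strand or cycle error biases, indels and multi-nucleotide variants,
subclonal copy number or allele fractions, and contamination with a
genuine biological mechanism. The artifact class is a statistical
stand-in for whatever produces shared low-frequency signal in practice.

## Problem sizes and numerical notes

The test suite and acceptance script use the default 2,000-bin genome
and 170-site VCF, 100 single-step series of 50 bins for the
segmentation-boundary check and 200 pure-noise series of 100 bins for
the false-split check — sizes at which every property they assert is
statistically stable across seeds while a full run stays within a few
minutes on one CPU.

Numerical corner cases handled explicitly: posterior normalization in
log space (no underflow at GL differences of hundreds); Phred caps at
200; the CBS pseudocount for zero ratios; the GMM variance floor;
nearest-state ties broken toward the smaller copy number;
`round(2·mean)` for a lone segment; missing bins excluded, never
imputed. Scale equivariance holds end to end: multiplying all raw
counts by a constant leaves boundaries and copy states unchanged, since
LOWESS fits, ratios and t statistics all scale through.

## Known limitations

Depth-only copy calling cannot separate states whose ratios coincide
under normalization drift, and assumes a predominantly diploid genome
for its baseline; allele-fraction (BAF) refinement is out of scope. The
labeller trusts the input likelihoods — it does not recalibrate them —
and treats multi-allelic sites per-allele without joint modelling.
Homolog and census tables are consumed as given; no transcript-level
resolution is attempted beyond the one impact per (variant, gene) the
annotation supplies.
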