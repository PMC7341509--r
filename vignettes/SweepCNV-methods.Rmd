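---
title: "SweepCNV: models, estimators and design choices"
author: "SweepCNV authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SweepCNV: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SweepCNV)
```

# Scope

SweepCNV implements the downstream computational analysis of a small
case-control whole-genome resequencing design — the setting where a handful
of affected individuals (here, two) are compared against a modest panel of
controls (six). Five analysis stages are covered:

1. SNP site filtering and transition/transversion (ts/tv) accounting;
2. a windowed Fst selective-sweep scan with Z-transformation;
3. read-depth copy-number estimation on sliding windows, CNV-region
   merging, integer genotyping and Vst-based case/control differentiation;
4. a depth-normalized presence/absence test for a candidate deletion
   region;
5. hypergeometric gene-set over-representation with FDR control.

Everything upstream — read QC, alignment, SNP and raw CNV calling — is out
of scope: the package consumes a VCF, window read-count matrices and
per-base depth tracks. A cohort simulator generates all of these with
planted, labelled ground truth, so each stage is verifiable without any
external download.

# The simulator: what it emulates, and what it does not

`simulateCohort()` draws biallelic SNP genotypes under Hardy–Weinberg
equilibrium *within group* at independent sites. Outside planted sweep
intervals both groups share a baseline alternate-allele frequency drawn
from Beta(0.8, 0.8) — a U-shaped folded frequency spectrum typical of
genome-wide SNP calls, which also exercises the monomorphic-site code
paths. Inside a planted sweep the groups use the interval's `caseFreq` and
`controlFreq`. Sites are independent: there is no linkage disequilibrium.
That is deliberate — every downstream statistic here uses site frequencies
only, so linkage would change the variance of window summaries but not
their expectation. Consequently, passing recovery tests demonstrate
correctness of the estimators and calling logic, not power on real, LD
structured genomes, where effective per-window information is lower.

Read depth is generated directly at the window level: counts are Poisson
with mean `meanDepth × CN / 2`, where the true copy number CN is 2
everywhere except in planted CNV intervals. Published depth summaries in
this design report per-base depths roughly between 5 and 20, with no
distributional detail; Poisson is the simplest defensible choice and is an
assumption, not a fact about any particular sequencer. Real depth tracks
are overdispersed and GC-biased; the normalization step supports an
optional GC-decile correction, but the generator only produces a GC effect
implicitly through its absence (multiplier 1.0).

Per-base tracks for the presence test are emitted separately
(`simulateDeletionTrack()`), covering the deletion interval plus a
configurable flank — the regional extract `samtools depth -r` would
produce. Affected samples draw Poisson with mean
`residualFraction × baseDepth` inside the interval.

Determinism: one master seed; each output file draws from its own stream
derived by labelled sub-seeding, so identical `(config, seed)` pairs are
byte-identical and adding a planted CNV does not perturb the simulated
genotypes.

Alternate alleles are the transition partner of the reference base with
probability 0.7 (the remaining mass split over the two transversion
partners), giving the ts:tv ratio around 2–3 seen in real genome-wide SNP
calls; this only matters for the accounting stage and is configurable.

# SNP filtering and mutation-type accounting

Sites are kept when read depth is *strictly greater than* 4 and quality is
*at least* 20 — the asymmetry mirrors how such filters are conventionally
stated ("reads > 4", "quality ≥ 20"), and the boundary behaviour is pinned
by tests. Whether the depth filter should be per-sample rather than
per-site is genuinely ambiguous in this design; per-site was chosen
because the filter fields live on the site record, and the thresholds are
arguments, so a stricter policy can be applied upstream.

Classification is by unordered base pair: A/G and C/T exchanges are
transitions, the four other pairs transversions. Fractions are reported at
one-decimal percent, matching the conventional presentation.
`summarizeMutationTypes()` accepts either a site stream or a named count
vector, so published count tables can be fed straight in.

# The windowed sweep scan

## Estimator

With two pools of 2 and 6 diploids, many Fst estimators are badly behaved.
The default is Hudson's two-population estimator in per-site
numerator/denominator form,

$$N_s = (p_1-p_2)^2 - \frac{p_1(1-p_1)}{n_1-1} - \frac{p_2(1-p_2)}{n_2-1},
\qquad D_s = p_1(1-p_2) + p_2(1-p_1),$$

with $p_i$ the alternate-allele frequency and $n_i$ the number of called
alleles in group $i$. It is nearly unbiased at very small $n$, does not
depend on the ratio of sample sizes, and reaches exactly 1 at a fixed
difference. Windows combine sites as a **ratio of sums**
$F_{ST}^{win} = \sum_s N_s / \sum_s D_s$, the recommended way to combine
Hudson components across sites (averaging per-site ratios is noisier and
biased). A Weir–Cockerham style variance-components estimator on allele
counts is available behind `estimator = "wc"`; the two coincide at fixed
differences. Sites with fewer than two called alleles in either group are
skipped; monomorphic sites identical in both groups contribute (0, 0).

The tests cross-check the Hudson route against an independent
heterozygosity formulation ($1 - H_w/H_b$) and verify estimator symmetry
under label swap.

## Windows, Z-transformation, candidates

Windows tile each chromosome from coordinate 1 with 1-based inclusive
ends (150 kb by default, so windows run 1–150000, 150001–300000, ...).
Windows need at least `minSnps = 10` informative SNPs to enter the
Z-transform — an addition the published scans are silent on, which
prevents single-SNP windows from dominating the upper tail. ZFst is the
usual standardization (sample SD, $n-1$); "top 1%" is made precise as an
empirical order statistic: with $k = \lceil 0.01\,n \rceil$, every window
whose ZFst reaches the $k$-th largest value is a candidate, ties
included. Gene annotation reports any gene whose interval intersects a
candidate window by at least 1 bp.

# Copy number, region merging and Vst

## Normalization and initial calls

Window counts (800 bp span, 400 bp step) are scaled per sample by the
genome-wide median so the typical window sits at copy number 2. Initial
calls are maximal runs of at least 3 consecutive windows in which *any*
sample reaches 2.75 (gain) or 1.25 (loss). These three values are internal
to depth-based CNV callers and rarely printed; 2.75/1.25 sit
three-quarters of the way to the next integer state, and 3 windows
(= 1600 bp of unique sequence at 800/400 windows) suppress single-window
Poisson excursions. All three are exposed as arguments.

## Merging

Adjacent same-chromosome calls merge when the gap is strictly less than
20% of their combined length **and** the Pearson correlation across
samples of the two calls' mean copy-number vectors is significant at
p = 0.01 (two-sided test of r = 0, n = sample count). Merging iterates
left-to-right to a fixed point; the result is checked against an
all-pairs brute-force oracle and shown to be independent of input order.
With fewer than 3 samples the correlation test is impossible and the
distance rule decides alone (with a warning); the same fallback applies to
degenerate constant vectors, where r is undefined.

## Genotypes and Vst

Integer copy number is the rounded per-sample mean copy number over the
region, with *half-away-from-zero* rounding — stated explicitly because
2.5 is a live boundary between two and three copies. Codes follow the
conventional CNV genotype notation: 0 → `D`, 1 → `Ad`, 2 → `AA`
(diploid), 3 → `AB`, 4 → `BB`, ≥ 5 → `M`.

Each sample's region value for Vst is its mean over region windows of
$\log_2(\mathrm{CN}/2)$, with CN floored at 0.05 before the log so
homozygous deletions stay finite. Then

$$V_{ST} = \frac{V_T - V_S}{V_T},$$

where $V_T$ is the population variance (divide by $N$) of all samples'
values and $V_S = (n_1 V_1 + n_2 V_2)/N$ the **size-weighted** mean of the
within-group population variances. "Average variance within populations"
is ambiguous between weighted and unweighted means; the size-weighted
form was chosen because the law of total variance then guarantees
$V_T \ge V_S$, hence $V_{ST} \in [0, 1]$, for every input. The unweighted
variant ($V_S = (V_1+V_2)/2$) is available behind `weighted = FALSE` but
can leave the unit interval for unbalanced groups. Vst is checked against
a brute-force between/within decomposition, and for shift invariance and
label symmetry.

Candidate regions are screened at length strictly greater than 2000 bp and
Vst strictly greater than 0.25. X-chromosome and unplaced-scaffold regions
are excluded from candidate reporting by default (the convention for this
kind of scan, where X depth is confounded by dosage); `autosomesOnly =
FALSE` restores them. Region-to-gene annotation reports overlap at
distance 0, otherwise the nearest gene with the gap in nt and an
upstream/downstream label relative to the region.

Published per-region Vst values from any particular study are not
reproducible without that study's raw depth matrices, so the recovery
tests target the *pattern* instead: a planted case-only gain (CN 3 vs 2)
must come out as `AB, AB` for cases and `AA` for all controls with
Vst > 0.9.

# Region presence/absence

Per-base depth inside a queried region is divided by the sample's
genome-wide mean depth, computed from the track *excluding the region
itself* — on a small simulated genome a true deletion would otherwise
dilute its own baseline. The per-sample verdict is a deterministic
function of the mean normalized ratio: below 0.05 → `absent` (the
operational reading of "read depth essentially zero"); in [0.05, 0.75) →
`heterozygous_loss` (one copy lost sits near 0.5); at or above 0.75 →
`present`. The heterozygous band is an addition — the biology of
recessive-lethal region deletions allows carriers — and both thresholds
are arguments. Verdicts are monotone in the ratio by construction.

How "total depth of sequencing" becomes a correction factor is another
genuinely open point; the per-sample genome-wide *mean* was chosen (the
total would only rescale all samples by track length). `intervalLength()`
exists because region lengths circulate under two conventions — 1-based
inclusive (`end − start + 1`) and plain difference (`end − start`) — and
both appear in published descriptions of the same loci.

# Enrichment

`hypergeometricEnrichment()` is a generic local over-representation test
against a user-supplied term-to-gene map (GMT or two-column TSV): for each
term, the upper-tail hypergeometric probability of an overlap at least as
large as observed, with Benjamini–Hochberg adjustment across terms. BH was
chosen for "FDR correction" as the standard step-up procedure; the test is
one-sided because only over-representation is reported in this design.
The background universe defaults to the union of all term genes and is
configurable, since the appropriate universe (all annotated genes vs all
testable genes) is study-specific. Ortholog mapping between species is out
of scope — the term map is an input.

Because the hypergeometric null is discrete, the attained level at
p < 0.05 is below 0.05 and depends on term and query sizes; with 200-gene
terms, 500-gene queries and a 5000-gene background the attained level is
≈ 0.040, which is what the null-calibration tests check against a
0.05 ± 0.02 band.

# Numerical and degenerate-input choices

* Window Fst with zero denominator sum: reported but flagged
  non-retained; Z-transform over retained windows only; zero variance
  across windows is an error, not a silent NaN.
* `vstStatistic()` returns 0 when total variance is 0 (all samples
  identical).
* Copy number floored at 0.05 before `log2`; all-zero depth samples are a
  named error at normalization.
* Ties at the ZFst candidate threshold are all included; ties in
  enrichment output are ordered by term id so results are independent of
  input order.
* All planted-interval coordinates are 1-based inclusive; depth windows
  snap calls to window boundaries, so recovered region edges are within
  one 400 bp step of truth.

# Problem sizes used by the test and acceptance suites

The suites are sized for a desk-scale replication of the study design:
sweep recovery uses 3 chromosomes × 15.15 Mb (303 windows of 150 kb) at
2 × 10⁻⁴ SNPs/bp with 3 planted fixed-difference windows, over 20 seeded
replicates; CNV recovery uses a 200 kb chromosome at 100× window depth
with one planted 3.2 kb case-only gain, over 20 replicates; the presence
test uses an 8.8 kb deletion at 10× base depth; enrichment calibration
uses 1000 null queries against 40 terms. These sizes were chosen so that
each recovery property has comfortable statistical margin while the whole
suite runs in a couple of minutes on one CPU.

# Known limitations

* No linkage disequilibrium, no read-level simulation, no sequencing
  error model: the simulator validates estimators and calling logic, not
  power on real genomes.
* Depth is Poisson; real short-read depth is overdispersed and GC-biased.
  The GC correction hook exists but the generator does not produce a GC
  covariate.
* The sweep scan is frequency-based only; haplotype statistics (iHS,
  XP-EHH) are out of scope.
* Absolute copy-number inference from allele balance, and split-read or
  paired-end structural-variant evidence, are out of scope; copy number
  is depth-only.
* With two samples per group, per-region Vst takes few distinct values
  and should be read as a screening statistic, not an estimate with
  useful confidence bounds.
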