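---
title: "Dissecting miRNA-mediated repression: models and methods"
author: "ribomech developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting miRNA-mediated repression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

MicroRNAs silence complementary mRNAs through two distinguishable modes:
destabilisation of the transcript (visible as a drop in mRNA abundance) and
repression of translation (visible as a drop in ribosome occupancy beyond
what the mRNA change explains). Paired mRNA-Seq and ribosome-profiling
(Ribo-Seq) experiments can separate the two: if a miRNA mainly destabilises
its targets, mRNA and ribosome-protected-fragment (RPF) fold changes move
together and translational efficiency (TE = RPF abundance scaled to mRNA
abundance) is flat; if it mainly represses translation, the RPF level moves
alone and TE drops.

`ribomech` implements this dissection as a reusable pipeline: canonical
seed-site prediction and context scoring in 3'UTRs and coding sequences,
negative-binomial differential expression at the mRNA and RPF levels,
differential TE, target-stratified distribution-shift analysis against a
no-site background, ribosome-profiling quality control, and qPCR panel
analysis for seed-sharing miRNA families. A synthetic-data generator plants
sites with known effects so that every stage is testable end to end without
external data.

## Seed sites and the context-score surrogate

Canonical site types on the target strand are defined from the miRNA seed
(nucleotides 2-7) and position 8: `6mer` (reverse complement of nt 2-7),
`7mer-1a` (6mer followed by an adenosine opposite position 1), `7mer-m8`
(reverse complement of nt 2-8), and `8mer` (7mer-m8 plus the 1A adenosine).
Every canonical site contains the 6mer core, so the scanner enumerates core
occurrences (including self-overlapping ones) and classifies each locus once
as its strongest type (8mer > 7mer-m8 > 7mer-1a > 6mer). Coordinates are
0-based within each region.

The trained 14-feature context++ model behind published target predictions
is *not* re-implemented. Scores come from a documented three-feature
surrogate,

```
score = base(type) + w_AU * (AU fraction in +/-30 nt flanks - 0.5)
      + w_pos * min(distance to region boundary, 1500) / 1500
```

with defaults `base = (-0.31, -0.16, -0.10, -0.02)` for (8mer, 7mer-m8,
7mer-1a, 6mer), `w_AU = -0.1`, `w_pos = +0.05`; all coefficients are
configurable, and externally produced predicted-target tables can be
supplied through `read_targetscan()` to bypass the surrogate entirely. The
surrogate preserves the qualitative structure that matters for the analysis
logic (type hierarchy, AU-context benefit, positional effect) but its
within-type spread is narrower than the real model's. Per-gene aggregates
are plain sums: CWCS over 3'UTR sites, TCS over CDS sites; genes pass
filtration when the aggregate is strictly below -0.2, and region-specific
analyses exclude genes with sites in the other region. A consequence of the
surrogate worth knowing: a single 7mer-1a site cannot reach -0.2, so
filtered single-7mer-1a strata are empty by construction (the source study
observed the same for its CDS predictions).

Conservation (Pct, the probability of conserved targeting) is not computable
from single-species sequence; it is an input annotation, either assigned by
the simulator or read from prediction tables. Stratum boundaries follow the
conventions used in this literature: Pct > 0.5 high, 0 < Pct <= 0.5 low,
Pct = 0 non-conserved; CWCS quartiles are computed on the filtered target
set with boundary values assigned to the lower (more repressive) quartile;
the seed-type scheme labels genes with more than one site `multi_site` and
excludes genes whose only site is a 6mer.

## Differential expression

Counts are normalised to library size only (counts per million), matching
the normalisation the analysis emulates; TMM factors (`tmm_factors()`) are
available as an option for strongly asymmetric perturbations, where pure
CPM absorbs part of the effect into the normalisation (composition bias).
The low-expression filter converts "5 raw counts in the smallest library"
into a CPM threshold `5 / min(library size) * 1e6` and keeps genes at or
above it in at least as many samples as the smallest condition group.

The exact test is a documented simplification of quantile-adjusted
conditional ML: columns are scaled to the geometric-mean library size,
group sums rounded, per-gene dispersions phi estimated by method of moments
within conditions and shrunk toward a lowess mean-dispersion trend with 20
prior degrees of freedom, and the two-sided p-value computed from the
conditional distribution of one group's sum given the total (beta-binomial
form for NB group sums with sizes n/phi; binomial in the Poisson limit),
summing the probabilities of all splits no more likely than the observed
one. Fold changes use group means with a 0.5 pseudo-count — the pseudo-count
never enters testing. Significance combines BH FDR < 0.05 with
|log2 fold change| > 0.5; both thresholds are configurable.

Differential TE is an interaction GLM: per gene, an NB log-linear model
`assay + condition + assay:condition` is fitted by IRLS on
library-size-equalised counts with fixed per-gene dispersion; the TE log2
fold change is the interaction coefficient over ln 2. Equalising the
columns (instead of using offsets) makes an exact identity hold: if RPF
counts are a per-sample scalar multiple of mRNA counts, the RPF block of
the likelihood becomes identical to the mRNA block and the fitted
interaction is exactly zero. The likelihood-ratio statistic of the
interaction is referred to **F(1, n_samples - 4)** rather than
chi-square(1): with 14-16 libraries the chi-square reference was measurably
anticonservative in null simulation (empirical type-I ~0.06 at nominal
0.05, uniformity rejected at some seeds), while the F reference is
calibrated. Genes whose fit fails to converge are flagged and reported with
p = 1, never dropped. A model-free estimate (`te_ratio`, the difference of
RPF and mRNA log2 fold changes from equalised group means) is emitted
alongside the GLM estimate, since it is ambiguous which variant published
TE fold-change plots use.

## Distribution-shift analysis and the mechanism call

Each stratum's fold changes are compared with the expressed no-site
background by the two-sided two-sample Kolmogorov-Smirnov test. For
`min(n, m) <= 10` the p-value is exact, by lattice-path enumeration of all
C(n+m, n) interleavings; the dynamic programme propagates path
*probabilities* of the equivalent hypergeometric walk, which keeps all
quantities in [0, 1] and avoids count overflow for unbalanced sizes. Above
the threshold the asymptotic two-sample formula with Stephens' small-sample
adjustment is used. The exact mode can be forced with `exact_limit`; note
that the asymptotic formula's O(n^-1/2) CDF error, though smaller than the
unadjusted formula's, is reliably detectable by a 10^4-draw uniformity
check at any practical sample size, so calibration tests exercise the exact
mode. Exactness assumes no ties; with ties the enumeration p is an
approximation (fold-change data make exact ties essentially impossible).

Median shifts carry percentile-bootstrap 95% CIs (2000 resamples, seeded;
the CI method in the source literature is unstated, so the bootstrap is this
package's choice). Strata smaller than 10 genes are reported descriptively
but not tested. Raw KS p-values are reported as in the literature; a BH
adjustment across strata is added as a convenience column. Within-stratum
Pearson correlation between mRNA and RPF fold changes is computed on all
stratum genes (correlating only significant genes is exposed through the
`selection` argument of `cross_condition_correlation()`).

The mechanism call is a deliberately simple decision rule on the three
median shifts (m, r, t) with floor delta = 0.1: destabilisation-dominant if
`m < -delta` and `|t| <= |m|/2`; translation-dominant if `t < -delta` and
`|m| <= |t|/2`; mixed if both m and t are below `-delta` otherwise; none
otherwise. It is plumbing for summarising simulations, not a published
statistic.

## Ribosome-profiling QC

Footprints are transcript-coordinate records (0-based 5' end, end, length).
P-site offsets per read length are the modal distance from the 5' end to
annotated start codons among start-overlapping reads (a stand-in for the
calibration performed by dedicated tools, whose exact procedure the source
methods do not specify); classes with fewer than 500 such reads fall back
to the global mode and are flagged. Sub-codon phasing is computed over
P sites in the CDS interior, excluding the first and last codons so
initiation/termination pile-ups cannot inflate one frame (standard
practice; the frame indexed 0 here corresponds to "frame 1" in figures that
count from one). Region-alignment proportions assign Ribo-Seq reads by
P site and mRNA-Seq reads by fragment midpoint. Metagene profiles normalise
each transcript's windowed coverage to unit mean before summation, so deep
transcripts do not dominate.

## qPCR panels and seed families

Technical replicates are averaged in Ct space; dCt subtracts the arithmetic
mean of the reference Cts (U6 and U44 by default), which equals the
geometric mean of reference expression on the linear scale. -ddCt estimates
the log2 fold change (one cycle = one log2 unit) and is tested with the
equal-variance two-sample t-test (Welch by flag); zero-variance degenerate
input yields p = 1 with a flag rather than an error. Multiple testing uses
the Benjamini-Krieger-Yekutieli two-stage step-up procedure with
q' = q/(1+q) in both stages (the original definition; a common paraphrase
uses q in stage 2). Its native output is reject/accept; rescaled stage-2
adjusted values are emitted as a labelled extension such that
`adjusted <= q` reproduces the flag. Seed families group mature miRNAs by
exact identity of nucleotides 2-8 and report distance-1 seed pairs as
"similar".

## The synthetic world

The generator emulates the statistical structure of the study design:
biological quadruplicate mRNA-Seq and triplicate Ribo-Seq, NB counts with
dispersion phi (default 0.1 — per-library dispersions are not identifiable
from published summaries, so this is a stated free parameter), planted
seed sites whose repressive effect acts on mRNA abundance (s_g <= 0) and/or
TE (t_g <= 0), optionally proportional to the aggregate context score,
footprints 25-40 nt with a fixed P-site offset (default 12 nt), fraction
`periodicity` in the canonical frame, and a 10% initiation pile-up that
anchors offset calibration. Treatment means are scaled by `2^s_g` (mRNA)
and `2^(s_g+t_g)` (RPF), so expected mRNA/RPF/TE log2 fold changes are
s_g, s_g + t_g and t_g by construction — this makes parameter-recovery
tests analytic. Background sequence is rejection-sampled so the focal
miRNA has *no* chance seed matches in scanned regions; planted sites are
written in by overwriting sequence and re-verified against the scanner, so
truth tables are exact. Other miRNAs may match by chance.

Realism choices worth stating: per-gene GC content varies +/-0.12 around
the configured mean and 3'UTR lengths are lognormal (sdlog 0.6) around a
1 kb mean, as in real transcriptomes. Both matter beyond cosmetics — with
near-constant lengths and uniform GC the surrogate score of single-8mer
genes collapses to a point mass, which makes CWCS-quartile boundaries
structurally degenerate in a way real score distributions are not.
Multi-site target genes carry 2-3 sites. Pct values are assigned by group
(30% high, 40% low, 30% non-conserved among targets).

What the generator does **not** emulate: read-level sequencing error, rRNA
contamination, 3'-supplementary or non-canonical pairing, batch effects,
and gene-correlated expression. A green end-to-end test therefore
establishes that the analysis recovers planted effects under the stated
noise model, not that it is robust to artefacts outside that model. One
such artefact is deliberately present: with strong asymmetric perturbations
CPM normalisation absorbs part of the effect (composition bias), which is
visible in recovery tests at high target fractions and is why TMM is
offered as an option.

## Numerical and design choices

* Seeds: every stochastic routine takes an explicit seed and restores the
  caller's RNG state; the pipeline derives per-stage seeds from the master
  seed by fixed offsets, so identical configs give byte-identical outputs.
* Pseudo-counts: 0.5 on group means, for fold changes only.
* Boundary rules: filtration keeps genes *at* the CPM threshold; quartile
  boundary values go to the lower quartile; the conditional exact test
  counts the observed split itself (p = 1 when the observed split is the
  mode).
* Degenerate inputs: zero-variance t-tests and n < 3 bootstrap CIs return
  flagged results, not errors; empty KS inputs and missing qPCR references
  are errors naming the offender.
* The mRNA-Seq midpoint rule and the Ribo-Seq P-site rule for region
  assignment are this package's documented conventions (the source methods
  are silent).
* Tolerances asserted in tests were chosen from the statistical resolution
  of the simulated worlds (Monte-Carlo half-widths), never tuned to
  observed outcomes; where a property is boundary-sharp (e.g. the BKY
  global-null no-rejection probability is 1 - q/(1+q) = 0.952 against a
  0.95 requirement), the test asserts the property minus the Monte-Carlo
  half-width and says so.

## Limitations

The scorer is a surrogate: absolute score values are not comparable to
published context++ scores, only their structure. The exact test and TE GLM
are simplifications of the packages used in the original analyses and are
validated by calibration, not by numerical identity to those tools.
Real-data headline numbers from the source study (thousands of DE genes,
specific correlations) depend on raw sequencing data and external databases
and are out of scope; the acceptance surface is property-based.
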