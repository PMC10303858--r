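---
title: "Replicate-free locus-level L1 expression analysis: models and design"
author: "retroDE maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replicate-free locus-level L1 expression analysis: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retroDE)
```

## The problem

Full-length (FL) LINE-1 (L1) retrotransposons — copies longer than 5 kb,
belonging to the evolutionarily young L1HS and L1PA subfamilies — can be
transcribed as independent units, and their locus-level upregulation in
postmortem brain tissue has been associated with neurodevelopmental
conditions. Cohorts of postmortem tissue typically offer one RNA-seq
library per subject and region: there are no biological replicates, so
the standard negative-binomial differential-expression machinery does
not apply per subject. `retroDE` implements the replicate-free
alternative — scoring every sample individually against the control
distribution — together with the genomic-context machinery needed to
interpret the calls: which L1 loci sit in introns of which genes, whether
host genes move in the opposite direction, whether read pairs tie an L1
locus into its neighboring exons (exonization), whether retained introns
explain the signal, and how chromatin-mark or protein-binding signal
distributes over the loci.

Because locus-level L1 quantification requires large external sequencing
archives, the package ships a seeded synthetic-data generator that
reproduces the statistical structure of such cohorts, so that every
stage is testable end to end on a laptop with no downloads.

## The per-sample z-score model

Raw counts are normalized with median-of-ratios size factors: the
reference for feature $i$ is its geometric mean across samples (features
with any zero are excluded from the reference), and sample $j$'s factor
is

$$ s_j = \mathrm{median}_i \; \frac{c_{ij}}{(\prod_k c_{ik})^{1/m}} . $$

The median is taken on the ratio scale. For a feature $i$ and case
sample $j$ with normalized value $x_{ij}$,

$$ z_{ij} = \frac{x_{ij} - \bar{x}_{i,\mathrm{ctrl}}}{s_{i,\mathrm{ctrl}}} $$

where mean and standard deviation are computed over the control samples
(sample sd, $n-1$ denominator; a population-sd switch is provided since
the convention is not universal). Controls are scored leave-one-out:
each control is compared against the distribution of all other
controls, so every sample receives a z. A feature is called upregulated
in a sample when $z > 3$ and downregulated when $z < -3$, both strict;
entries with zero control sd are `undefined` and never called. The
per-sample *net upregulation* is the number of up calls minus the
number of down calls; log2 fold changes are
$\log_2((x + \varepsilon)/(\bar{x}_{\mathrm{ctrl}} + \varepsilon))$
with $\varepsilon = 1$ by default (zero handling is not standardized;
the pseudocount is configurable).

z-scores are computed on normalized linear values, not log counts: the
statistic is defined directly on normalized expression. No
multiple-testing correction is applied — the fixed threshold *is* the
decision rule — but the expected number of false calls per sample under
the t reference (below) is annotated in the pipeline report.

### Calibration: what |z| > 3 means with 9 controls

With $n$ controls and Gaussian noise, the case statistic is

$$ \frac{x - \bar{x}_{\mathrm{ctrl}}}{s_{\mathrm{ctrl}}}
   \sim t_{n-1}\sqrt{1 + 1/n}, $$

because the case observation carries its own sampling variance. For
$n = 9$ the tail probability corresponding to the $|z| > 3$ rule is
$2\,P(t_8 > 3/\sqrt{1+1/9}) \approx 2.2\%$ per (feature, sample) — an
order of magnitude above the Gaussian 0.27%. This is the package's
calibration reference: the test suite asserts that the empirical null
call rate on simulated cohorts (9 controls, negative-binomial dispersion
0.05, cohort-sized locus set) stays below 1.5 times this reference.
Negative-binomial skewness (skewness $\to 2\sqrt{\alpha} \approx 0.45$
for $\alpha = 0.05$) and estimated size factors push the empirical rate
to roughly 2.4–2.6%, within the band. The practical reading: with small
control groups the rule is an outlier screen, not a familywise-error
procedure, and downstream interpretation (context, anticorrelation,
enrichment) is what gives calls their meaning.

## Genomic context and host genes

Introns are constructed by subtracting exon coordinates from gene
bodies; intergenic space by subtracting gene bodies from the chromosome.
All overlap operations are strand-blind (no strand-orientation
preference is assumed between L1s and host genes) and use the 1-bp
minimum-overlap convention of bedtools. Each L1 locus receives exactly
one context: *exonic* if it touches an exon (exon contact is the
stronger claim and takes precedence; a switch reverses this), else
*intronic*, else *intergenic*. The host gene is the gene with the
largest body overlap, ties broken by smaller start — deterministic
output was preferred over any biological tie heuristic.

Three derived per-sample sets follow:

* **overlap pairs** — upregulated L1s ($z > 3$) inside differentially
  expressed genes ($|z| > 3$), with the gene's direction from the sign
  of its z. Any overlap qualifies (full containment is not required;
  the bedtools default);
* **anticorrelated genes** — genes with *any* negative z hosting an
  intronic L1 with $z > 3$. The asymmetry (hard cutoff on the L1, none
  on the gene) is deliberate: the hypothesis concerns the host gene's
  response to L1 activation, not its own significance;
* **reference-set overlaps** — expressed loci matched against named
  interval sets (e.g. L1Base2-style intactness classes); one locus may
  match several sets.

## Expressed-feature filters

A locus enters the analysis universe when its mean raw count across all
samples is at least 200 (inclusive), its length strictly exceeds
5000 bp, and its subfamily matches the L1HS/L1PA whitelist (globs such
as `L1PA*` are supported). For genes the same mean-count rule applies
without the length/subfamily filters; a more permissive 15-read variant
is exposed as a parameter because both conventions circulate and
neither is hard-coded. Boundary semantics (``at least'' inclusive,
``longer than'' strict) are unit-tested. The retained-intron filter
keeps introns with IRratio ≥ 0.1, IntronDepth ≥ 3 (both inclusive), a
clean warnings field, and no overlap with known features.

## Resampling enrichment

The enrichment of a target gene set against an annotation set is scored
against `n = 1000` equally sized random draws (uniform, without
replacement) from the expressed-gene universe — the same universe the z
scores were computed on:
$z = (\mathrm{obs} - \mu_{\mathrm{null}})/\sigma_{\mathrm{null}}$,
conventionally called at $z > 3$ ($z > 5$ for stricter variants). Under
this design the null overlap count is hypergeometric with expectation
$|T| \cdot |A| / |U|$; the exact hypergeometric tail is reported
alongside as a cross-check of the resampled null (it is an addition of
this implementation, clearly flagged in the output). A degenerate null
($\sigma = 0$, e.g. annotation = universe) yields an explicit flag, not
a z. The interval-based variant swaps random *gene sets* into the
overlap count of L1 loci against gene bodies.

## The exonization statistic

For a locus pair $(A, B)$ and a table of properly paired fragments with
mapping quality ≥ 30: (1) collect read ids with at least one mate fully
contained in $A$; (2) count all mates of those ids — two per id — as the
*total fragments*; (3) count the ids with at least one mate overlapping
$B$ by any amount as *shared*. The statistic is
$100 \cdot \mathrm{shared} / \mathrm{total}$, so perfect co-splicing
yields 50 (one shared id per two fragments) and an independent
transcriptional unit yields 0. The containment/any-overlap asymmetry
between steps 1 and 3 follows the statistic's definition. Three
pairings put an observed value in context: random expressed exons vs
their closest exon (positive control), upregulated L1s vs their closest
exon, and random 6-kb intronic segments vs their closest exon (negative
control). Distributions are compared with a two-sided rank-sum test —
the comparison only needs a distribution-free location test. PCR
duplicates are assumed removed upstream; a `(id, coordinates)` dedup
flag is available but off by default.

## Scale-regions signal profiles

A profile matrix rescales each region body into `bodyBins` equal
real-valued bins (default 60) and adds fixed-size flank bins (default
5000 bp at 50 bp/bin) on both sides. A bin's value is the
length-weighted mean of the signal runs it intersects, with uncovered
positions contributing zero; minus-strand regions are reversed so bin 1
is always the 5' upstream edge. Length-weighting makes the binning
mass-conserving: a constant track produces a flat profile regardless of
region length heterogeneity, which the suite asserts, together with
strand-mirroring invariance and per-base oracle equality. Bin sizes and
the averaging statistic (`mean`, with `max`/`sum` behind a flag) are
declared defaults, not inferred values.

## The synthetic cohort generator

`SimParams` fixes the study conditions; the defaults are the conditions
under which the acceptance properties are evaluated:

| parameter | default | what it emulates |
|---|---|---|
| `nControls`, `nCases` | 9, 9 | the postmortem single-region cohort layout |
| `affectedCases` | 3 of 9 | the subset of cases carrying L1 upregulation |
| `l1Fold` | 8 | strong locus upregulation in affected samples |
| `l1UpFraction` | 0.4 | share of intronic FL loci upregulated (30–50% was observed in strongly affected samples) |
| `nbDispersion` | 0.05 | NB noise, variance $\mu + \alpha\mu^2$ (bulk RNA-seq scale) |
| `baseMeanRange` | 300–2000 | locus baseline means around the 200-read expression threshold |
| `sizeFactorRange` | 0.6–1.6 | library-scale spread of real cohorts |
| `flFraction` | 0.5 | loci on both sides of the 5-kb full-length cut |
| `l1ContextProps` | 0.6/0.1/0.3 | intronic-dominated placement of upregulated loci |
| `anticorrFactor` | 2 | host-gene repression when its L1 is active |

Genes are laid out non-overlapping on a single linear chromosome (a
multi-chromosome mode was considered and rejected: nothing in the
analyses dispatches on chromosome identity), with 2–5 exons of
150–400 bp separated by 8–20-kb introns so every gene can host a
full-length locus. MilliDiv (mismatches per thousand against the
subfamily consensus, a proxy for evolutionary age) is drawn so young
subfamilies are less diverged, and within a subfamily loci with a
higher latent expression propensity are less diverged; the same
propensity scales baseline means, so the expressed stratum comes out
younger — the qualitative pattern expected of real annotation.
Upregulated loci are drawn from the intronic full-length stratum and
floored at a baseline mean of 400 so that injected signal lives inside
the expressed universe, mirroring the fact that upregulation is only
observable among expressed loci. Ground truth (which features, which
samples, which couplings) is always emitted as a sidecar table so tests
never re-derive it.

Everything is a pure function of `(SimParams, seed)`; generators save
and restore the caller's RNG state.

What the generator does **not** emulate — and therefore what passing
tests do *not* establish about real data: multimapping ambiguity of
repeat-derived reads (the central practical difficulty of locus-level
TE quantification), GC and length biases, correlated gene–gene
expression structure, batch effects, and single-cell sparsity. The
suite validates the *procedure*, not the upstream quantification.

## Numerical and convention choices

* **Coordinates.** All in-memory containers are `GRanges` (1-based,
  closed), the native convention of the Bioconductor stack this package
  is built on; BED/BEDPE/bedGraph files are 0-based half-open on disk
  and converted exactly once at the I/O boundary. Every converter is
  exercised on a 1-bp feature. Tab is the only field separator; writers
  end files with a newline; round trips are byte-identical.
* **Median-of-ratios.** Geometric means are computed in log space;
  features containing any zero are excluded from the reference; an
  all-zero-containing matrix is an error instructing the caller to
  pre-filter. The median is taken on the ratio scale, which for an even
  feature count interpolates arithmetically rather than geometrically —
  the two conventions agree on odd counts and differ by well under a
  percent otherwise.
* **Ties.** `closestFeature` breaks ties by smaller start, then
  lexicographic id; host-gene assignment by larger overlap, then
  smaller start. Deterministic output everywhere.
* **Degenerate inputs.** Zero control sd → `undefined` status;
  zero-variance correlation vectors → flagged, excluded from summaries;
  no qualifying fragment in locus A → `NA` percentage with a zero
  total; degenerate resampling null → flagged, no z.
* **Problem sizes.** The test suite runs its multi-seed statistical
  properties on compact instances chosen to keep the full suite in the
  minutes range: 30–40 genes and 40 loci for recovery properties, 150
  loci (the size of a real expressed-locus set) for calibration, 50
  seeds for null-rate averaging, 20 for recovery, 10^4 resamples for
  the hypergeometric check. These sizes are stated here as the
  package's test design.

## Limitations

The z-score rule is an exploratory outlier screen; with 8 df its tails
are heavy and single-sample calls should be treated as hypotheses.
Host-gene assignment is gene-level, not transcript-level, so isoform
effects are invisible. The exonization statistic counts shared read
ids, not spliced alignments, so it cannot distinguish read-through
transcription from splicing. Reference-set overlap assumes both sets
are on the same assembly — no liftover is performed.
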