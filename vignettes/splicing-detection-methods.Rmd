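---
title: "Robust detection of alternatively spliced exons on exon-junction arrays"
author: "rasa package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust detection of alternatively spliced exons on exon-junction arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rasa)
```

## The problem

Modern transcriptome arrays interrogate not only every exon of a gene
but also the exon-exon junctions between them. Junction probes are more
specific to individual isoforms than exon probes, but they are also
harder to design: a junction region is only ~30 bp long, so its 4-8
probes are nearly identical in sequence and tend to perform well or
fail *together*, whereas the 8-10 probes of a ~120 bp exon are
individually optimized. Two consequences drive the design of this
package:

1. A gene expression index computed from *all* exons absorbs the signal
   of any differentially spliced exon, biasing the reference against
   which splicing is measured.
2. Junction evidence is valuable for confirming exon-level calls, but a
   substantial fraction of junction probesets simply does not report,
   and calls must not be silently lost when that happens.

The workflow is a two-condition comparison (multi-group studies are run
pairwise) on log2 expression indices. "Fold change" throughout means
the difference of log2 condition means, second condition minus first in
lexicographic label order.

## Stage 0: preprocessing

Probe-level matrices are median-scaled per sample (each column shifted
so its median equals the mean of the original column medians) and
summarized per probeset by Tukey median polish. The polish alternates
row and column median sweeps, rows first, with the even-length median
taken as the mean of the two central values; it stops when the largest
absolute adjustment in a full sweep falls below `1e-6` or after 30
sweeps. These conventions are fixed for bit-reproducibility: median
polish on even-sized blocks approaches its fixed point through slowly
decaying adjustments, so a loosely specified stopping rule would make
results depend on implementation details. The per-sample index is the
overall effect plus the column effect.

Presence is assessed by detection-above-background (DABG) p-values,
which are an *input* (the package defines only their aggregation): the
group-level DABG p-value is the geometric mean of the per-sample
p-values within a condition, and a probeset is present in a condition
when that value is at or below 0.01. Sample p-values are clamped to
`[1e-16, 1]` so the geometric mean is always defined.

## Stage 1: putatively constitutive exons

For each gene, exons absent in either condition are set aside. Among
the remaining exons the mean `m` and sample standard deviation `s`
(n-1 denominator; `s = 0` for a single exon) of the exon log2 fold
changes are computed, and any exon whose fold change falls strictly
outside `[m - d*s, m + d*s]` is flagged. The boundary is inclusive so
that a gene whose exons all share one fold change (`s = 0`) keeps all
of them. `m` and `s` are recomputed over the surviving exons and the
process repeats until no exon is newly flagged. Removal is monotone —
a flagged exon is never re-admitted — which guarantees termination in
at most one iteration per exon; allowing re-admission could cycle. The
default sensitivity is `d = 2`, retaining roughly 95-97% of truly
constitutive exons under Gaussian noise.

The gene expression index is then median-polished from the surviving
exons only: from their pooled probes when probe-level data are
available, otherwise from their probeset index rows. Genes with no
constitutive exon fall back to all exons present in both conditions
(flagged `fallback`), because a sizeable fraction of genes would
otherwise be untestable; genes with no present exon at all are excluded
from testing.

## Stage 2: junction-supported calls

Each exon and junction probeset is tested by a one-way ANOVA on the
gene-normalized per-sample values `nv[s] = probeset[s] - gene[s]`
(the MIDAS construction; the test function is deliberately simple and
pluggable). Subtracting the per-sample gene index makes the test
invariant to sample-wise shifts shared by probeset and gene. The
splicing index of a probeset is its fold change minus its gene's fold
change; its sign is the direction of the change. Testing is two-sided;
direction is handled separately through the splicing-index sign.

Exons are called significant at `p <= 0.01`. Because junction p-values
are systematically larger than exon p-values (fewer, noisier probes),
junctions use an adjusted threshold obtained by quantile mapping: with
`f` the fraction of exon p-values at or below `p`, the junction
threshold `p'` is the `ceiling(f * N_junc)`-th smallest junction
p-value (`0` when no exon passes). This convention guarantees exactly
the smallest junction pass-fraction at or above `f`; the empirical
quantile is not interpolated. On data with noisier junctions `p' < p`,
and on clean symmetric data `p'` reproduces the exon pass count.

A significant exon becomes a **junction-supported** confident candidate
when at least one of its junctions is significant at `p'` and
direction-consistent: an *inclusion* junction (one endpoint at the
exon) must share the exon's direction, an *exclusion* junction
(skipping over the exon) must change in the opposite direction. A
probeset with splicing index exactly zero has no direction and can
neither support nor be supported. An exon supported only by an
exclusion junction still counts as supported; the support type is
recorded in the output. The junction search is restricted to the
exon's own inclusion and exclusion junctions as defined by the
annotation topology.

## Stage 3: unreliable junctions

A properly measured junction should respond at least as strongly as
its exon, because the junction is specific to the changing isoform
while the exon may be shared. For each significant exon the *best
junction* is the one with the largest absolute splicing index in the
exon's direction; if none changes in that direction the junction
change is truncated to zero. The fold-change difference
`|si_exon| - |si_best|` is compared against an empirical null built
from the stage-2 supported exons — pairs where exon and junction
demonstrably both work. The cutoff is the top-`q` order statistic of
that null (`k = ceiling((1 - q) * N)`-th smallest, default
`q = 0.05`), and a significant unsupported exon whose difference
*strictly* exceeds the cutoff is reported as an
**unreliable-junction candidate**; ties fall inside the null. The
stage requires at least 20 null values (a quantile from fewer points is
meaningless) and is otherwise disabled with a message while stage-2
calls are still emitted.

Every testable exon receives exactly one category:
`junction_supported`, `unreliable_junction_candidate`,
`exon_only_not_called`, `not_significant` or `absent` (below the
presence threshold in both conditions). Exons absent in exactly one
condition are tested normally — absence in one condition is itself a
splicing signal — and flagged `presence_flag` in the output.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `p` | 0.01 | exon significance threshold (raw ANOVA p-value) |
| `d` | 2 | trimming width in standard deviations of exon fold changes |
| `q` | 0.05 | top quantile of the null defining the rescue cutoff |
| `presenceThreshold` | 0.01 | group DABG presence threshold |
| `minNullSize` | 20 | smallest null sample before stage 3 activates |
| `minConstitutive` | 1 | constitutive exons required before fallback |

Raw p-values are thresholded deliberately (no FDR gate): the junction
requirement, not multiplicity correction, is the false-positive control
of this design.

## The simulator

`simulateSpliceArray()` generates the study the defaults describe: 200
genes laid out as linear chains of 10 exons with adjacent junctions
`(i, i+1)`, three replicates per condition, probe-level log2 values
`gene abundance + probeset offset + splicing shift + probe affinity +
noise`. Five percent of internal exons are planted as spliced with
splicing-index magnitude 2 (direction random); each planted exon also
receives the skip junction `(e-1, e+1)` its skipping isoform would
produce, with inclusion junctions shifted along the exon and the
exclusion junction shifted oppositely. Exon probesets have 8 probes at
noise sd 0.25, junction probesets 4 probes at sd 0.4 — junctions
noisier and fewer-probed, as on real arrays. Absent exons (5%) and
failed junction probesets sit flat at the background level. DABG
p-values follow a seeded logistic model of signal-above-background.
Two failure parameters exist because they answer different questions:
`junctionFailureRate` drops junction probesets independently (ambient
unreliability), while `failedExonFraction` fails *all* junctions of a
fraction of the planted exons — the junctions of a short genomic
region failing together, which is the scenario the rescue stage exists
for and the one an i.i.d. failure model essentially never produces.

The simulator separates *structure* (gene layout, planted events,
offsets, probe affinities — drawn from `seed`) from *measurement
noise* (optionally re-drawn from `noiseSeed`). Replicating noise at
fixed truth is what allows estimating the *bias* of an estimator
rather than its single-realization error.

What the simulator does not model: alternative 5'/3' splice sites,
retained introns, multi-exon skips, sequence-driven probe affinity,
cross-hybridization, or correlated probe noise. Passing tests on this
generator therefore demonstrate the internal consistency and
calibration of the algorithm under its own assumptions, not
performance on hybridization data.

## Design notes and numerical choices

- **Bias of the gene index.** With ten exons and one planted spliced
  exon, median polish already absorbs most of the contamination: the
  single-realization fold-change error of the all-exon index is
  dominated by noise shared with the constitutive index, and comparing
  the two on one dataset is close to a coin flip. The meaningful
  comparison is estimator *bias*, measured here by averaging signed
  fold-change errors over 20 measurement-noise replicates at fixed
  truth: the constitutive index then shows several-fold smaller
  absolute bias (typically ~0.015 vs ~0.07 log2 units on genes with one
  planted exon), and is less biased for over 95% of such genes.
- **Null contamination in stage 3.** The empirical null assumes
  supported exons' junctions behave properly. Under heavy independent
  junction failure (about half the junctions or more), spuriously
  supported exons contaminate the null's upper tail and the cutoff
  degrades; the rescue stage is calibrated for ambient failure rates
  well below that.
- **Degenerate inputs.** Zero within-group variance in the ANOVA gives
  p = 1 when the group means agree and p = 0 otherwise; one sample per
  group is untestable (`NA`), not an error. A gene whose exons are all
  absent is excluded; its exons are reported as `absent`.
- **Problem sizes.** The test suite runs the full pipeline at the
  default 200-gene scale (seconds per run) and uses 10,000-replicate
  loops for the statistical calibration checks; these sizes give
  binomial standard errors small enough to detect miscalibration of a
  5% rate at the +/-3 SE level.

## Limitations

Calls are exon-level: the package does not assemble events into
isoforms, does not handle designs with more than two conditions in one
run, and starts from probe- or probeset-level matrices (CEL-file
parsing and GC background correction are upstream concerns). The
ANOVA-based test assumes approximately Gaussian gene-normalized values;
heavy-tailed probe behaviour is better served by substituting a rank
test through the same interface.
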