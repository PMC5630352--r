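---
title: "Bivalency transition analysis: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bivalency transition analysis: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bivalency)
```

## The model

A promoter is *bivalent* when it carries both the activating H3K4me3 and
the repressive H3K27me3 histone marks. This package models bivalency as a
binary, presence/absence property per gene and condition: a mark is present
at a gene when any called peak for that mark overlaps the gene's promoter
window by at least one base pair under half-open interval semantics. Peak
scores are deliberately ignored — score thresholds belong upstream, in peak
calling, and the classification downstream of it is purely combinatorial.

With two marks this yields four chromatin states per condition
(`K4_ONLY`, `K27_ONLY`, `BIVALENT`, `UNMARKED`). Genes bivalent in the
second (mesenchymal) condition B are partitioned into transition groups by
their first-condition state: Group I was K4-only (gained H3K27me3),
Group II was K27-only (gained H3K4me3), Group III was unmarked (acquired
both), Group IV was already bivalent. The partition invariant — group
counts sum to the number of B-bivalent genes — is asserted on every run.
Counting is always per *gene* (one canonical promoter per gene), and output
labels say so: published analyses sometimes count *domains*, and the two
units need not coincide.

## Coordinates and promoters

All intervals are 0-based half-open internally (the BED convention); GTF
input (1-based closed) is converted on read, once, so no off-by-one
arithmetic leaks into the analysis. The promoter window extends
`upstream` bp against transcription and `downstream` bp with it:
`[tss − upstream, tss + downstream)` on the plus strand and its mirror
about the TSS base on the minus strand, clamped at zero. The default,
TSS ± 2000 bp, is a conventional choice for bivalency analyses — the
window that generated any particular published peak-to-gene assignment is
usually not recoverable — and is therefore a configuration parameter
surfaced in every entry point, never a constant baked into results.
Annotations with several records per gene collapse to the first record
(duplicates are logged); chromosome-name dialects ("chr1" vs "1") are
compared literally, with an explicit normalization flag.

## Statistics

**Fisher / odds ratio.** Gene-set overlap uses the exact conditional test:
with margins fixed, the two-sided p sums hypergeometric probabilities of
all tables no more likely than the observed one (the minimum-likelihood
convention, stated here so results are comparable across implementations).
The odds ratio is ad/bc; zero cells get 0.5 added to every cell
(Haldane–Anscombe) so output stays finite and serializable, with a
`corrected` flag preserving honesty. The universe defaults to all genes
scored in the transition analysis — the same background convention used
for enrichment.

**Enrichment.** Two modes are provided because the two common usages of
GO servers differ: a *two-list* mode (target set vs background; p is the
hypergeometric tail, computed in log space) and a *ranked mHG* mode, where
the statistic is the minimum hypergeometric tail over all proper prefixes
of a ranked binary membership vector and its exact p-value comes from the
standard dynamic programme over the (rank, hits) lattice that excludes
paths entering the rejection region. Which mode a published figure used is
often ambiguous; results are therefore labeled with their mode and neither
is privileged beyond two-list being the default. Raw p is primary
(a Bonferroni column is provided); no GO database ships with the package —
term annotations are user-supplied GMT files, keeping the artifact
download-free and database-version-independent.

**Expression.** "Lower expression" is a strict FPKM inequality with no
fold-change or significance threshold, because the classification it
mirrors states none; ties are not "lower". The expression filter is
strictly greater-than (FPKM > 10 excludes exactly 10). Group differences
are per-gene `FPKM_B − FPKM_A`, summarized by mean ± SEM; distributions are
compared by Mann-Whitney U (exact by enumeration when `n + m ≤ 20` and
tie-free, otherwise a tie-corrected normal approximation with continuity
correction). The default pairing is Group I against each other group; an
all-pairs mode exists. Missing values are excluded pairwise, never imputed.
"Cumulative expression" of a gene set is the per-sample sum by default
(mean is available) — the aggregation behind published cumulative plots is
typically not defined, so both are explicit options. Cohort arms come from
receptor status: TN requires all of ER, PR, HER2 definitively negative;
any definitive positive gives non-TN; anything else is excluded. Arms are
compared with Welch's unequal-variance t-test (two-sided, Welch–
Satterthwaite df), with the convention p = 1 when both samples are
constant and equal.

**qPCR.** Fold changes use the comparative Ct method, 2^−ΔΔCt, with
replicate Cts averaged per (target, sample) first. Significance for
reactivation panels is an unpaired Welch t-test on replicate ΔCt values per
comparison, Holm–Šidák-adjusted within each comparison panel across genes
by default (a per-gene family is available). The three-criterion
reactivation call requires, at adjusted p < α in the stated direction:
lower under the EMT inducer, higher after withdrawal, and lower under the
demethylase inhibitor during withdrawal; the full pattern is their
conjunction. ChIP-qPCR percent input adjusts the input Ct by
log2(1/input-fraction); H3 normalization subtracts the IgG background from
both target and H3 *before* dividing (the orderings are not equivalent;
the subtract-first form is symmetric in the two signals and is the
default, with a subtract-after mode for sensitivity checks). Negative
numerators floor at zero with a flag.

## The synthetic world

The generator's defaults are the stated conditions of the analysis, chosen
once: 2000 genes; 25% bivalent in condition B; group proportions over all
genes {I = 0.1175, II = 0.02, III = 0.02, IV = 0.0925, NONE = 0.75}, i.e.
a Group I share of 0.47 among B-bivalent genes; condition-A bivalency
equal to the Group IV proportion, so the expected bivalency fold change is
0.25 / 0.0925 = 2.7; and a Group I repression probability of 0.694. The
first and last anchors are the analysis' published shares; the Group IV
proportion is pinned by the fold-change anchor under the simplest reading
(no gene loses bivalency between conditions), and the residual II/III mass
is split evenly because nothing constrains it.

The chromatin channel is noiseless by default: peaks exactly realize the
planted states inside pairwise-disjoint promoter slots, so replaying the
classifier recovers the planted groups exactly — this is what lets
end-to-end tests assert equality rather than similarity. An optional peak
dropout rate exists for robustness experiments. Decoy peaks land in
inter-promoter gaps and must never change a call.

Expression baselines are log-normal (FPKM is long-tailed and positive;
meanlog 3, sdlog 1, configurable). Only Group I genes receive a planted
shift: down with the repression probability, up otherwise, with magnitude
`effect_scale` × U(0.5, 1.5) in log2 units over N(0, 0.1²) log2 noise.
Two consequences are deliberate. First, the planted fraction-lower equals
the repression probability itself rather than being diluted towards
(p + (1−p)/2) by coin-flip noise. Second, all other groups get noise only:
an earlier design that gave them direction-balanced log2 shifts produced a
systematic *positive* FPKM mean difference by Jensen's inequality,
contradicting "no systematic shift" in the units the summaries report.
With `effect_scale = 0` the planted effect vanishes and roughly half of
all genes land lower, which the tests verify.

The cohort generator depresses every gene-set gene by `delta` log2 units
(default 1) in TN-arm samples, over per-gene N(5, 1) log2 baselines and
unit log2 sample noise; receptor metadata is generated to round-trip
through the labeling rule. The Ct generator converts planted fold changes
to Ct shifts (−log2 fold) around a constant reference gene, with Gaussian
replicate noise (default SD 0.05 cycles, triplicates). At zero noise every
recovery is exact; at the default noise, borderline calls can flip because
a Welch test on triplicates has as few as two degrees of freedom, which
puts a floor on the attainable p that a Holm–Šidák family of ~50 genes
occasionally pushes past α — a faithful property of small-n qPCR panels,
not a defect, and the reason exact-recovery tests run on the zero-noise
channel. The default reactivation panel plants the nested per-group
pattern counts of a typical follow-up panel (e.g. Group I: 22 genes, 15
down, 10 re-expressed, 9 inhibitor-blocked).

What a green test does *not* establish: the generator does not emulate
read-level noise, peak-shape or width distributions, correlated expression
between genes, batch structure in cohorts, or amplification-efficiency
drift in qPCR. Conclusions about those belong to the upstream tools that
produce the package's inputs.

## Numerical choices

Hypergeometric tails accumulate in log space. Two mathematically equal
prefix tails can differ by ~1e−15 when computed from different prefixes,
so the mHG threshold rank picks the smallest prefix within a 1e−9 relative
band of the minimum. The mHG p-value DP propagates probability mass (not
path counts), which is stable for the N this package targets. Fisher's
minimum-likelihood rule uses the conventional (1 + 1e−7) relative slack
when comparing table probabilities. Mann-Whitney exact mode refuses ties
(falls back with a warning) and caps at n + m = 20; its null distribution
comes from the classic count recursion, while the test suite checks it
against full subset enumeration. Degenerate inputs are conventions, not
errors: Fisher with degenerate margins gives p = 1, Welch on two constant
equal samples gives p = 1, a zero denominator in fold change returns NA
with a warning.

## Known limitations

Two marks, two conditions, one promoter per gene; no probabilistic or
signal-weighted state calls; no GO DAG propagation; no confidence
intervals on odds ratios; no amplification-efficiency calibration. The
"any-promoter" multi-TSS option is limited to collapsing annotations at
read time. These boundaries are intentional: the package covers the
classification and statistics layer, not peak calling or quantification.
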