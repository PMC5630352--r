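# bivalency

Bivalent chromatin domains carry both the activating H3K4me3 and the
repressive H3K27me3 mark at the same promoter, holding a gene silent but
poised. During an epithelial–mesenchymal transition (EMT) many promoters
*become* bivalent; classifying how each bivalent promoter arose — and what
happens to the genes' expression — is the core of this package. It is aimed
at epigenomics analysts who already have peak calls for the two marks in two
conditions and want the downstream classification and statistics in a
reproducible, tested form.

## What it computes

Given H3K4me3 and H3K27me3 peak calls (BED) in two conditions A
(epithelial / reference) and B (mesenchymal), plus a gene annotation
(GTF or 6-column BED), each gene's promoter window (default TSS ± 2 kb,
configurable) is scored for mark presence (≥ 1 bp overlap), giving a
per-condition chromatin state in {K4-only, K27-only, bivalent, unmarked}.
Genes bivalent in condition B are partitioned by their condition A state:

| Group | state in A | interpretation |
|-------|------------|----------------|
| I     | K4-only    | premarked active promoter that gained H3K27me3 |
| II    | K27-only   | premarked repressed promoter that gained H3K4me3 |
| III   | unmarked   | acquired both marks de novo |
| IV    | bivalent   | constitutively bivalent |

Downstream modules then provide, in the field's standard notation:

* **Signature overlap** — per-group 2×2 tables against a reference bivalent
  signature; exact two-sided Fisher p (minimum-likelihood rule) and odds
  ratio OR = ad/bc with the Haldane–Anscombe 0.5 correction on zero cells.
* **Term enrichment** — two-list hypergeometric tail P[X ≥ k], and ranked
  minimum-hypergeometric (mHG) scores with their exact permutation p-value
  by the standard lattice-path dynamic programme.
* **Expression statistics** — strict FPKM > t filters, the fraction of a
  group expressed lower in B, per-group FPKM difference means ± SEM, exact
  (enumerated) and tie-corrected approximate Mann-Whitney U tests, Welch's
  unequal-variance t-test.
* **Cohort scoring** — triple-negative labeling from ER/PR/HER2 status
  (TN ⇔ all three definitively negative), per-sample cumulative gene-set
  scores, and TN vs non-TN Welch tests.
* **qPCR / ChIP-qPCR calculators** — comparative Ct (2^−ΔΔCt) fold changes,
  Holm–Šidák step-down adjustment, three-criterion MET-reactivation calls,
  percent input (input-fraction-adjusted), and H3-normalized
  IgG-subtracted ChIP enrichment with between-condition fold.
* **Synthetic data** — seeded generators planting every ground truth the
  pipeline can recover (transition groups, repression probability, cohort
  depression, Ct fold changes), used throughout the test suite.

## Worked example

Generate a synthetic dataset under the default stated world (2000 genes,
25% bivalent in B, Group I share 0.47, repression probability 0.694) and
replay the pipeline:

```r
library(bivalency)
spec <- synthetic_spec(seed = 1)
ds   <- generate_dataset(spec)
tt   <- classify_transitions(ds$annotation, ds$peaks, "vector", "twist")
tt
#> transition_table: 2000 genes (vector -> twist)
#>   bivalent genes: 191 in A, 525 in B
#>   Group I     237  (45.1% of bivalent-in-B)
#>   Group II     51  (9.7% of bivalent-in-B)
#>   Group III    46  (8.8% of bivalent-in-B)
#>   Group IV    191  (36.4% of bivalent-in-B)
bivalency_fold_change(tt)
#> [1] 2.748691
fl <- fraction_lower(ds$expression, "vector", "twist", group_members(tt, "I"))
sprintf("%d/%d = %.1f%%", fl$n_lower, fl$n_total, 100 * fl$fraction)
#> [1] "166/237 = 70.0%"
```

Reading the numbers: 525 genes are bivalent in the mesenchymal condition
versus 191 in the epithelial one (a 2.75-fold increase); 45.1% of them are
Group I (planted share 0.47, recovered within binomial error); and 70.0% of
Group I genes are expressed lower in the mesenchymal condition (planted
probability 0.694). The per-gene classification equals the planted truth
exactly because the chromatin channel of the generator is noiseless.

A configuration-driven runner (`run_transition_analysis`,
`run_cohort_analysis`, `run_qpcr_analysis`, `run_all_synthetic`) writes
TSV/JSON reports; a thin CLI wrapper lives at
`inst/cli/bivalency-cli.R` (subcommands `simulate`, `classify`, `overlap`,
`enrich`, `expression`, `cohort`, `qpcr`, `run-all`).

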