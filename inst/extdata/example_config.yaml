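# Example pipeline configuration. All thresholds and window sizes live
# here; nothing is hidden in code defaults beyond what this file shows.
conditions:
  a: vector        # epithelial / premarked reference condition
  b: twist         # mesenchymal condition (groups are defined on B)
promoter:
  upstream: 2000   # bp against transcription from the TSS
  downstream: 2000
thresholds:
  fpkm: 10         # strict >, the expression filter
  alpha: 0.05      # on Holm-Sidak-adjusted p for reactivation calls
chrom_style: asis  # or strip / add, to reconcile "chr1" vs "1"
seed: 1
output_dir: bivalency_out
cohort:
  statistic: sum   # cumulative gene-set score; or mean
  gene_set: data/group1.txt
qpcr:
  reference_gene: GAPDH
  family: per_panel
  comparisons:
    - [tgfb, vehicle]
    - [withdraw_dmso, tgfb]
    - [withdraw_gskj4, withdraw_dmso]
paths:
  annotation: data/genes.gtf
  k4_a: data/peaks_H3K4me3_vector.bed
  k27_a: data/peaks_H3K27me3_vector.bed
  k4_b: data/peaks_H3K4me3_twist.bed
  k27_b: data/peaks_H3K27me3_twist.bed
  expression: data/expression.tsv
  signature: data/signature.txt
  ontology: data/ontology.gmt
  cohort_matrix: data/cohort_matrix.tsv
  cohort_metadata: data/cohort_metadata.tsv
  ct_table: data/rtpcr_ct.tsv
  qpcr_truth: data/rtpcr_truth.tsv
  chip_table: data/chip_ct.tsv
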