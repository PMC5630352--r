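test_that("spec validation enforces proportions and fractions", {
  expect_error(synthetic_spec(group_proportions = c(I = 0.5, II = 0.2,
                                                    III = 0.2, IV = 0.2,
                                                    NONE = 0)), "sum to 1")
  expect_error(synthetic_spec(bivalent_fraction_a = 0.01), "Group IV")
  expect_error(synthetic_spec(n_genes = 0), "n_genes")
  s <- synthetic_spec()
  expect_equal(sum(s$group_proportions), 1)
  expect_equal(s$repression_prob_group_I, 0.694)
})

test_that("generated promoters are pairwise disjoint and deterministic", {
  spec <- synthetic_spec(n_genes = 60, seed = 19)
  ann <- generate_annotation(spec)
  expect_equal(nrow(ann), 60L)
  prom <- promoter_window(ann, spec$upstream, spec$downstream)
  for (chrom in unique(prom$chrom)) {
    p <- prom[prom$chrom == chrom, ]
    p <- p[order(p$start), ]
    if (nrow(p) > 1)
      expect_true(all(p$start[-1] >= p$end[-nrow(p)]))  # all-pairs via sort
  }
  expect_identical(ann, generate_annotation(spec))
  # TSS invariant: start (+) / end - 1 (-)
  plus <- ann$strand == "+"
  expect_equal(ann$tss[plus], ann$start[plus])
  expect_equal(ann$tss[!plus], ann$end[!plus] - 1L)
})

test_that("overcrowded chromosomes are rejected", {
  spec <- synthetic_spec(n_genes = 1000, chrom_sizes = c(chr1 = 1e6),
                         seed = 1)
  expect_error(generate_annotation(spec), "slots")
})

test_that("replaying the classifier recovers the planted groups exactly", {
  for (seed in c(3, 23)) {
    spec <- synthetic_spec(n_genes = 400, seed = seed)
    ds <- generate_dataset(spec)
    tt <- classify_transitions(ds$annotation, ds$peaks,
                               spec$condition_a, spec$condition_b,
                               spec$upstream, spec$downstream)
    truth <- ds$truth[match(tt$records$gene_id, ds$truth$gene_id), ]
    expect_equal(tt$records$group, truth$group)
    expect_equal(tt$records$state_a, truth$state_a)
    expect_equal(tt$records$state_b, truth$state_b)
  }
})

test_that("degenerate planting: all bivalent-in-B genes are Group I", {
  gp <- c(I = 0.4, II = 0, III = 0, IV = 0, NONE = 0.6)
  spec <- synthetic_spec(n_genes = 150, group_proportions = gp,
                         bivalent_fraction_a = 0, seed = 29)
  ds <- generate_dataset(spec)
  tt <- classify_transitions(ds$annotation, ds$peaks, "vector", "twist")
  expect_true(all(tt$records$group[tt$records$state_b == "BIVALENT"] == "I"))
  expect_equal(tt$counts[["II"]] + tt$counts[["III"]] + tt$counts[["IV"]], 0L)
})

test_that("decoy-only peak sets leave all genes unmarked", {
  gp <- c(I = 0, II = 0, III = 0, IV = 0, NONE = 1)
  spec <- synthetic_spec(n_genes = 80, group_proportions = gp,
                         bivalent_fraction_a = 0, seed = 31)
  ann <- generate_annotation(spec)
  pk <- generate_condition_peaks(ann, spec)
  # keep only decoys: drop peaks overlapping any promoter
  prom <- promoter_window(ann, spec$upstream, spec$downstream)
  keep <- rep(TRUE, nrow(pk$peaks))
  for (i in seq_len(nrow(prom)))
    keep <- keep & !(pk$peaks$chrom == prom$chrom[i] &
                       pk$peaks$start < prom$end[i] &
                       pk$peaks$end > prom$start[i])
  decoys <- pk$peaks[keep, ]
  expect_gt(nrow(decoys), 0)
  tt <- classify_transitions(ann, decoys, "vector", "twist")
  expect_true(all(tt$records$state_a == "UNMARKED"))
  expect_true(all(tt$records$state_b == "UNMARKED"))
})

test_that("generators are pure functions of the seed", {
  spec <- synthetic_spec(n_genes = 100, seed = 37)
  d1 <- generate_dataset(spec)
  d2 <- generate_dataset(spec)
  expect_identical(d1$peaks, d2$peaks)
  expect_identical(d1$expression, d2$expression)
  expect_identical(d1$cohort, d2$cohort)
  expect_identical(d1$ct_tables, d2$ct_tables)
  spec2 <- synthetic_spec(n_genes = 100, seed = 38)
  expect_false(identical(generate_dataset(spec2)$expression, d1$expression))
})

test_that("zero effect scale leaves the repression fraction near one half", {
  spec <- synthetic_spec(n_genes = 2000, effect_scale = 0, seed = 41)
  ds <- generate_dataset(spec)
  g1 <- ds$truth$gene_id[ds$truth$group == "I"]
  res <- fraction_lower(ds$expression, "vector", "twist", g1)
  # binomial 99% band around 0.5
  half_width <- 2.576 * sqrt(0.25 / res$n_total)
  expect_lt(abs(res$fraction - 0.5), half_width + 1e-9)
})

test_that("cohort receptor labels round-trip and the planted effect is detectable", {
  spec <- synthetic_spec(n_genes = 100, seed = 43,
                         cohort = list(n_tn = 50, n_non_tn = 50, delta = 1,
                                       n_background = 100))
  ds <- generate_dataset(spec)
  labels <- tnbc_label(ds$cohort$metadata$ER, ds$cohort$metadata$PR,
                       ds$cohort$metadata$HER2)
  expect_equal(labels, ds$cohort$metadata$arm)
  g1 <- ds$truth$gene_id[ds$truth$group == "I"]
  scores <- geneset_cumulative_score(ds$cohort$matrix, g1)
  tn <- ds$cohort$metadata$sample_id[ds$cohort$metadata$arm == "TN"]
  non <- ds$cohort$metadata$sample_id[ds$cohort$metadata$arm == "NON_TN"]
  r <- welch_t_test(scores[tn], scores[non])
  expect_lt(mean(scores[tn]), mean(scores[non]))
  expect_lt(r$p_value, 0.01)
  expect_error(generate_cohort("g", synthetic_spec(
    cohort = list(n_tn = 1, n_non_tn = 1, delta = 0, n_background = 5))),
    ">= 4")
})

test_that("large planted cohort effects reject essentially always", {
  hits <- 0
  for (seed in 1:20) {
    spec <- synthetic_spec(n_genes = 40, seed = seed,
                           cohort = list(n_tn = 50, n_non_tn = 50,
                                         delta = 2, n_background = 20))
    ann <- generate_annotation(spec)
    truth <- generate_condition_peaks(ann, spec)$truth
    gs <- truth$gene_id[truth$group %in% c("I", "IV")]
    co <- generate_cohort(gs, spec)
    sc <- geneset_cumulative_score(co$matrix, gs)
    tn <- co$metadata$sample_id[co$metadata$arm == "TN"]
    non <- co$metadata$sample_id[co$metadata$arm == "NON_TN"]
    if (welch_t_test(sc[tn], sc[non])$p_value < 0.05) hits <- hits + 1
  }
  expect_equal(hits, 20L)
})

test_that("planted qPCR folds are recovered through the ddCt chain", {
  patterns <- data.frame(target = c("up", "flat"), group = "I",
                         down_in_emt = c(TRUE, FALSE),
                         up_in_met = FALSE, blocked_by_inhibitor = FALSE)
  # zero noise: exact recovery of the planted fold
  spec0 <- synthetic_spec(ct_noise_sd = 0, seed = 47)
  ct0 <- generate_ct_tables(spec0, patterns = patterns, fold_down = 0.25)
  fc0 <- qpcr_fold_changes(ct0$rtpcr, ct0$reference_gene, "tgfb", "vehicle")
  expect_equal(fc0$fold_change[fc0$target == "up"], 0.25, tolerance = 1e-12)
  expect_equal(fc0$fold_change[fc0$target == "flat"], 1, tolerance = 1e-12)
  # low noise: recovery within noise
  spec1 <- synthetic_spec(ct_noise_sd = 0.05, seed = 47)
  ct1 <- generate_ct_tables(spec1, patterns = patterns, fold_down = 0.25)
  fc1 <- qpcr_fold_changes(ct1$rtpcr, ct1$reference_gene, "tgfb", "vehicle")
  expect_equal(fc1$fold_change[fc1$target == "up"], 0.25, tolerance = 0.2)
})

test_that("written datasets parse back through the package readers", {
  spec <- synthetic_spec(n_genes = 80, seed = 53)
  ds <- generate_dataset(spec)
  dir <- withr::local_tempdir()
  paths <- write_dataset(ds, dir)
  ann <- read_gene_annotation(paths[["annotation"]])
  expect_equal(sort(ann$gene_id), sort(ds$annotation$gene_id))
  k4b <- read_bed(paths[["k4_twist"]], "H3K4me3", "twist")
  expect_equal(nrow(k4b),
               sum(ds$peaks$mark == "H3K4me3" & ds$peaks$condition == "twist"))
  terms <- read_gmt(paths[["ontology"]])
  expect_equal(names(terms), names(ds$ontology))
  ct <- read_ct_table(paths[["rtpcr"]])
  expect_equal(nrow(ct), nrow(ds$ct_tables$rtpcr))
})
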