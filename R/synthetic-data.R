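# Synthetic datasets with planted ground truth for every pipeline stage.
# The chromatin channel is noiseless by default: peaks exactly realize the
# planted per-gene states, so replaying the classifier recovers the planted
# groups exactly. All generators are pure functions of (spec, seed).

#' Specification of a synthetic dataset
#'
#' Defaults encode the stated world of the bivalency analysis: 25% of genes
#' bivalent in the mesenchymal condition with a Group I share of 0.47,
#' condition-A bivalency chosen so the expected bivalency fold change is
#' 2.7, and a Group I repression probability of 0.694.
#'
#' @param n_genes number of genes (>= 1).
#' @param chrom_sizes named integer vector of chromosome lengths (bp).
#' @param group_proportions named fractions over `I`, `II`, `III`, `IV`,
#'   `NONE` summing to 1 (proportions of *all* genes).
#' @param bivalent_fraction_a fraction of genes bivalent in condition A;
#'   must be at least the Group IV proportion (extra mass is planted as
#'   condition-A-bivalent genes that lose a mark in B).
#' @param repression_prob_group_I probability that a Group I gene is
#'   expressed strictly lower in condition B.
#' @param effect_scale magnitude of the planted expression shift in log2
#'   units (0 disables the planted effect, leaving noise only).
#' @param noise_sd log2-scale expression noise SD.
#' @param baseline_meanlog,baseline_sdlog log-normal FPKM baseline
#'   parameters (long-tailed positive, as is conventional for FPKM).
#' @param condition_a,condition_b condition labels.
#' @param upstream,downstream promoter window used for peak planting.
#' @param n_decoy_peaks intergenic decoy peaks per mark and condition.
#' @param peak_dropout_rate probability a planted peak is dropped
#'   (default 0: noiseless chromatin channel).
#' @param cohort list: `n_tn`, `n_non_tn`, `delta` (log2 depression of the
#'   gene set in TN-like samples), `n_background` genes.
#' @param ct_noise_sd replicate noise SD (cycles) for RT-PCR Ct tables.
#' @param seed integer seed; every generator derives its stream from it.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_genes = 2000,
                           chrom_sizes = c(chr1 = 8e6, chr2 = 8e6),
                           group_proportions = c(I = 0.1175, II = 0.02,
                                                 III = 0.02, IV = 0.0925,
                                                 NONE = 0.75),
                           bivalent_fraction_a = 0.0925,
                           repression_prob_group_I = 0.694,
                           effect_scale = 1,
                           noise_sd = 0.1,
                           baseline_meanlog = 3,
                           baseline_sdlog = 1,
                           condition_a = "vector",
                           condition_b = "twist",
                           upstream = 2000, downstream = 2000,
                           n_decoy_peaks = 50,
                           peak_dropout_rate = 0,
                           cohort = list(n_tn = 50, n_non_tn = 50,
                                         delta = 1, n_background = 100),
                           ct_noise_sd = 0.05,
                           seed = 1) {
  if (n_genes < 1) stopf("synthetic_spec: n_genes must be >= 1")
  gp <- group_proportions[c("I", "II", "III", "IV", "NONE")]
  if (anyNA(gp)) stopf("group_proportions must name I, II, III, IV, NONE")
  if (abs(sum(gp) - 1) > 1e-9)
    stopf("group_proportions must sum to 1 (got %.12f)", sum(gp))
  if (any(gp < 0) || any(gp > 1))
    stopf("group_proportions must lie in [0, 1]")
  if (bivalent_fraction_a < gp[["IV"]] - 1e-12)
    stopf("bivalent_fraction_a (%.4f) cannot be below the Group IV proportion (%.4f)",
          bivalent_fraction_a, gp[["IV"]])
  stopifnot(repression_prob_group_I >= 0, repression_prob_group_I <= 1,
            peak_dropout_rate >= 0, peak_dropout_rate <= 1)
  spec <- list(n_genes = as.integer(n_genes), chrom_sizes = chrom_sizes,
               group_proportions = gp,
               bivalent_fraction_a = bivalent_fraction_a,
               repression_prob_group_I = repression_prob_group_I,
               effect_scale = effect_scale, noise_sd = noise_sd,
               baseline_meanlog = baseline_meanlog,
               baseline_sdlog = baseline_sdlog,
               condition_a = condition_a, condition_b = condition_b,
               upstream = upstream, downstream = downstream,
               n_decoy_peaks = as.integer(n_decoy_peaks),
               peak_dropout_rate = peak_dropout_rate,
               cohort = cohort, ct_noise_sd = ct_noise_sd,
               seed = as.integer(seed))
  class(spec) <- "synthetic_spec"
  spec
}

#' Generate a gene annotation with disjoint promoters
#'
#' Genes are laid on fixed-width slots along the configured chromosomes so
#' that promoter windows are pairwise disjoint by construction; strands and
#' body lengths are randomized under the spec seed. Errors when the
#' chromosomes cannot host `n_genes` slots.
#'
#' @param spec a `synthetic_spec`.
#' @return a `gene_annotation` data.frame.
#' @export
generate_annotation <- function(spec) {
  window <- spec$upstream + spec$downstream
  gap <- max(1000, window / 2)
  slot <- window + gap
  capacity <- floor(spec$chrom_sizes / slot)
  if (sum(capacity) < spec$n_genes)
    stopf("generate_annotation: chromosomes fit %d promoter slots, need %d",
          sum(capacity), spec$n_genes)
  with_seed(spec$seed, {
    n_per <- pmin(capacity,
                  ceiling(spec$n_genes * capacity / sum(capacity)))
    while (sum(n_per) > spec$n_genes)
      n_per[which.max(n_per)] <- n_per[which.max(n_per)] - 1L
    rows <- list()
    gi <- 0L
    for (ci in seq_along(spec$chrom_sizes)) {
      chrom <- names(spec$chrom_sizes)[ci]
      for (si in seq_len(n_per[ci])) {
        gi <- gi + 1L
        slot_start <- (si - 1L) * slot
        strand <- sample(c("+", "-"), 1L)
        # promoter window occupies [slot_start, slot_start + window)
        tss <- if (strand == "+") slot_start + spec$upstream
               else slot_start + spec$downstream - 1L
        len <- sample(2000:20000, 1L)
        if (strand == "+") {
          start <- tss; end <- tss + len
        } else {
          start <- max(0L, tss - len + 1L); end <- tss + 1L
        }
        rows[[gi]] <- data.frame(
          gene_id = sprintf("G%05d", gi), symbol = sprintf("G%05d", gi),
          chrom = chrom, start = as.integer(start), end = as.integer(end),
          strand = strand, tss = as.integer(tss), stringsAsFactors = FALSE)
      }
    }
    ann <- do.call(rbind, rows)
    class(ann) <- c("gene_annotation", "data.frame")
    ann
  })
}

state_for_group <- c(I = "K4_ONLY", II = "K27_ONLY",
                     III = "UNMARKED", IV = "BIVALENT")
marks_in_state <- function(state) {
  switch(state,
         K4_ONLY = "H3K4me3", K27_ONLY = "H3K27me3",
         BIVALENT = c("H3K4me3", "H3K27me3"), UNMARKED = character())
}

#' Plant transition groups and emit realizing peak sets
#'
#' Each gene is assigned a group by seeded sampling from the spec
#' proportions; condition A/B chromatin states follow from the group
#' semantics (`NONE` genes get a non-bivalent B state, and enough of them
#' are made bivalent in A to meet `bivalent_fraction_a`). One peak per
#' present mark is placed inside the promoter window; decoy peaks land in
#' the inter-promoter gaps.
#'
#' @param annotation output of [generate_annotation()].
#' @param spec the `synthetic_spec` used to build it.
#' @return list with `peaks` (a single `peak_set` covering 2 marks x 2
#'   conditions) and `truth` (data.frame `gene_id`, `group`, `state_a`,
#'   `state_b`).
#' @export
generate_condition_peaks <- function(annotation, spec) {
  n <- nrow(annotation)
  with_seed(spec$seed + 1L, {
    group <- sample(names(spec$group_proportions), n, replace = TRUE,
                    prob = spec$group_proportions)
    state_a <- ifelse(group == "NONE", NA_character_,
                      state_for_group[group])
    state_b <- ifelse(group == "NONE", NA_character_, "BIVALENT")
    none_idx <- which(group == "NONE")
    if (length(none_idx)) {
      state_b[none_idx] <- sample(c("K4_ONLY", "K27_ONLY", "UNMARKED"),
                                  length(none_idx), replace = TRUE)
      extra <- round((spec$bivalent_fraction_a -
                        spec$group_proportions[["IV"]]) * n)
      extra <- min(extra, length(none_idx))
      biv_a <- if (extra > 0) sample(none_idx, extra) else integer()
      state_a[biv_a] <- "BIVALENT"
      rest <- setdiff(none_idx, biv_a)
      state_a[rest] <- sample(c("K4_ONLY", "K27_ONLY", "UNMARKED"),
                              length(rest), replace = TRUE)
    }
    prom <- promoter_window(annotation, spec$upstream, spec$downstream)
    peak_rows <- list()
    add_peak <- function(chrom, wstart, wend, mark, condition) {
      width <- sample(300:1500, 1L)
      start <- wstart + sample.int(max(1L, wend - wstart - 300L), 1L) - 1L
      end <- min(start + width, wend + 200L)
      if (spec$peak_dropout_rate > 0 &&
          runif(1) < spec$peak_dropout_rate) return(NULL)
      data.frame(chrom = chrom, start = start, end = end, mark = mark,
                 condition = condition, score = round(runif(1, 10, 100), 2),
                 stringsAsFactors = FALSE)
    }
    k <- 0L
    for (i in seq_len(n)) {
      for (cond in c("a", "b")) {
        st <- if (cond == "a") state_a[i] else state_b[i]
        lab <- if (cond == "a") spec$condition_a else spec$condition_b
        for (m in marks_in_state(st)) {
          k <- k + 1L
          peak_rows[[k]] <- add_peak(prom$chrom[i], prom$start[i],
                                     prom$end[i], m, lab)
        }
      }
    }
    # decoys in the gaps between promoter slots (never overlap a window)
    window <- spec$upstream + spec$downstream
    gap <- max(1000, window / 2)
    slot <- window + gap
    for (m in MARKS) for (lab in c(spec$condition_a, spec$condition_b)) {
      for (d in seq_len(spec$n_decoy_peaks)) {
        ci <- sample(seq_along(spec$chrom_sizes), 1L)
        si <- sample.int(floor(spec$chrom_sizes[ci] / slot), 1L)
        gap_start <- (si - 1L) * slot + window + 100L
        k <- k + 1L
        peak_rows[[k]] <- data.frame(
          chrom = names(spec$chrom_sizes)[ci], start = gap_start,
          end = gap_start + min(500L, gap - 200L), mark = m,
          condition = lab, score = round(runif(1, 10, 100), 2),
          stringsAsFactors = FALSE)
      }
    }
    peak_rows <- peak_rows[!vapply(peak_rows, is.null, TRUE)]
    peaks <- do.call(rbind, peak_rows)
    peaks <- peaks[sample.int(nrow(peaks)), , drop = FALSE]  # shuffle order
    rownames(peaks) <- NULL
    class(peaks) <- c("peak_set", "data.frame")
    list(peaks = peaks,
         truth = data.frame(gene_id = annotation$gene_id, group = group,
                            state_a = state_a, state_b = state_b,
                            stringsAsFactors = FALSE))
  })
}

#' Generate a two-condition expression table with planted repression
#'
#' Baselines follow a seeded log-normal (long-tailed, positive). Each
#' Group I gene is shifted down in condition B with probability
#' `repression_prob_group_I` (and up otherwise); all other genes get a
#' direction-balanced shift. The shift magnitude scales with
#' `effect_scale`; with `effect_scale = 0` only the log-normal noise
#' remains and roughly half the genes land lower in B.
#'
#' @param truth truth data.frame from [generate_condition_peaks()].
#' @param spec the `synthetic_spec`.
#' @return expression data.frame: `gene_id` plus one FPKM column per
#'   condition label.
#' @export
generate_expression <- function(truth, spec) {
  n <- nrow(truth)
  with_seed(spec$seed + 2L, {
    baseline <- rlnorm(n, spec$baseline_meanlog, spec$baseline_sdlog)
    # only Group I carries a planted shift: down with the repression
    # probability, up otherwise (so the planted fraction-lower is the
    # repression probability itself, not diluted by coin-flip noise);
    # all other genes get log-scale noise with no systematic effect
    s <- ifelse(runif(n) < spec$repression_prob_group_I, -1, 1)
    delta <- ifelse(truth$group == "I",
                    spec$effect_scale * runif(n, 0.5, 1.5), 0)
    eps <- rnorm(n, 0, spec$noise_sd)
    value_b <- baseline * 2^(s * delta + eps)
    out <- data.frame(gene_id = truth$gene_id, a = baseline, b = value_b,
                      stringsAsFactors = FALSE)
    names(out)[2:3] <- c(spec$condition_a, spec$condition_b)
    out
  })
}

#' Generate a cohort matrix with a planted gene-set depression
#'
#' Builds a gene x sample FPKM-like matrix over the supplied gene set plus
#' background genes; TN-like samples have every gene-set gene depressed by
#' `delta` log2 units. Receptor metadata is generated consistently with the
#' arm labels (TN: all three negative; non-TN: at least one positive).
#'
#' @param gene_set character vector of gene ids carrying the planted
#'   effect.
#' @param spec the `synthetic_spec` (fields under `spec$cohort`).
#' @return list with `matrix` (data.frame `gene_id` x samples) and
#'   `metadata` (data.frame `sample_id`, `ER`, `PR`, `HER2`, `arm`).
#' @export
generate_cohort <- function(gene_set, spec) {
  co <- spec$cohort
  if (co$n_tn + co$n_non_tn < 4)
    stopf("generate_cohort: need n_tn + n_non_tn >= 4")
  with_seed(spec$seed + 3L, {
    genes <- c(unique(as.character(gene_set)),
               sprintf("BG%04d", seq_len(co$n_background)))
    n_g <- length(genes)
    n_s <- co$n_tn + co$n_non_tn
    arm <- c(rep("TN", co$n_tn), rep("NON_TN", co$n_non_tn))
    sample_id <- sprintf("S%03d", seq_len(n_s))
    mu <- rnorm(n_g, 5, 1)                      # per-gene log2 baseline
    vals <- matrix(rnorm(n_g * n_s, 0, 1), n_g, n_s) + mu
    in_set <- genes %in% gene_set
    vals[in_set, arm == "TN"] <- vals[in_set, arm == "TN"] - co$delta
    mat <- as.data.frame(2^vals)
    names(mat) <- sample_id
    mat <- cbind(data.frame(gene_id = genes, stringsAsFactors = FALSE), mat)
    er <- pr <- her2 <- rep("negative", n_s)
    for (i in which(arm == "NON_TN")) {
      pos <- sample(1:3, sample(1:3, 1L))
      st <- c("negative", "negative", "negative")
      st[pos] <- "positive"
      er[i] <- st[1]; pr[i] <- st[2]; her2[i] <- st[3]
    }
    metadata <- data.frame(sample_id = sample_id, ER = er, PR = pr,
                           HER2 = her2, arm = arm, stringsAsFactors = FALSE)
    list(matrix = mat, metadata = metadata)
  })
}

#' Generate a planted term ontology
#'
#' One "adhesion-like" term is over-populated with Group I genes; the
#' remaining terms draw members uniformly from all genes, so the planted
#' term should rank first when Group I is used as the enrichment target.
#'
#' @param truth truth data.frame.
#' @param spec the `synthetic_spec`.
#' @param n_terms number of background terms.
#' @param term_size members per term.
#' @return named list of term annotations (GMT-shaped, see [read_gmt()]).
#' @export
generate_ontology <- function(truth, spec, n_terms = 20, term_size = 50) {
  with_seed(spec$seed + 4L, {
    all_genes <- truth$gene_id
    g1 <- truth$gene_id[truth$group == "I"]
    n_from_g1 <- min(length(g1), ceiling(term_size * 0.6))
    planted <- unique(c(sample(g1, n_from_g1),
                        sample(all_genes, term_size - n_from_g1)))
    terms <- list(list(term_id = "T0001", term_name = "cell-cell adhesion (planted)",
                       members = planted))
    for (i in seq_len(n_terms)) {
      terms[[i + 1L]] <- list(
        term_id = sprintf("T%04d", i + 1L),
        term_name = sprintf("background process %d", i),
        members = unique(sample(all_genes, term_size)))
    }
    stats::setNames(terms, vapply(terms, `[[`, "", "term_id"))
  })
}

# Default RT-PCR panel: per-group gene counts and nested planted patterns
# (down in EMT; of those, up in MET; of those, blocked by the inhibitor),
# mirroring a typical bivalency qPCR follow-up panel.
default_qpcr_patterns <- function() {
  build <- function(group, n, n_down, n_up, n_block) {
    down <- c(rep(TRUE, n_down), rep(FALSE, n - n_down))
    up <- rep(FALSE, n); up[seq_len(n_up)] <- TRUE
    block <- rep(FALSE, n); block[seq_len(n_block)] <- TRUE
    data.frame(target = sprintf("%s_g%02d", group, seq_len(n)),
               group = group, down_in_emt = down, up_in_met = up,
               blocked_by_inhibitor = block, stringsAsFactors = FALSE)
  }
  rbind(build("I", 22, 15, 10, 9), build("II", 8, 6, 5, 5),
        build("III", 8, 5, 5, 4), build("IV", 10, 2, 2, 1))
}

#' Generate RT-PCR and ChIP-qPCR Ct tables with planted effects
#'
#' RT-PCR: a four-condition panel (`vehicle`, `tgfb`, `withdraw_dmso`,
#' `withdraw_gskj4`) in triplicate with a constant reference gene; planted
#' fold changes are converted to Ct shifts (`shift = -log2(fold)`), with
#' Gaussian replicate noise of SD `ct_noise_sd`. ChIP-qPCR: a single-locus
#' table (target mark, total H3, IgG, input per condition) realizing a
#' planted H3-normalized enrichment in each condition, noiseless.
#'
#' @param spec the `synthetic_spec`.
#' @param patterns data.frame of planted per-gene patterns (columns
#'   `target`, `group`, `down_in_emt`, `up_in_met`,
#'   `blocked_by_inhibitor`); defaults to a 48-gene panel across the four
#'   groups.
#' @param fold_down,fold_up,fold_block planted fold changes used when the
#'   respective pattern flag is on (off means fold 1).
#' @param chip_enrichment named numeric length-2: planted H3-normalized
#'   enrichment of the target mark in conditions A and B (default plants a
#'   2.4-fold B/A ratio).
#' @return list with `rtpcr` (replicate Ct data.frame), `patterns` (the
#'   planted truth), `comparisons` (list of the three case/control pairs),
#'   `reference_gene`, and `chip` (ChIP Ct data.frame with columns `locus`,
#'   `antibody`, `condition`, `ct`, `input_fraction`).
#' @export
generate_ct_tables <- function(spec, patterns = default_qpcr_patterns(),
                               fold_down = 0.3, fold_up = 3,
                               fold_block = 0.4,
                               chip_enrichment = c(a = 0.25, b = 0.6)) {
  with_seed(spec$seed + 5L, {
    ref <- "GAPDH"
    conditions <- c("vehicle", "tgfb", "withdraw_dmso", "withdraw_gskj4")
    rows <- list(); k <- 0L
    emit <- function(target, sample, ct_mean) {
      for (r in 1:3) {
        k <<- k + 1L
        rows[[k]] <<- data.frame(
          target = target, sample = sample, replicate = r,
          ct = ct_mean + rnorm(1, 0, spec$ct_noise_sd),
          stringsAsFactors = FALSE)
      }
    }
    for (cond in conditions) emit(ref, cond, 20)
    for (i in seq_len(nrow(patterns))) {
      base <- runif(1, 24, 28)
      f1 <- if (patterns$down_in_emt[i]) fold_down else 1
      f2 <- if (patterns$up_in_met[i]) fold_up else 1
      f3 <- if (patterns$blocked_by_inhibitor[i]) fold_block else 1
      ct_v <- base
      ct_t <- ct_v - log2(f1)
      ct_w <- ct_t - log2(f2)
      ct_g <- ct_w - log2(f3)
      emit(patterns$target[i], "vehicle", ct_v)
      emit(patterns$target[i], "tgfb", ct_t)
      emit(patterns$target[i], "withdraw_dmso", ct_w)
      emit(patterns$target[i], "withdraw_gskj4", ct_g)
    }
    rtpcr <- do.call(rbind, rows)
    # ChIP: percent-input signals realizing the planted normalized values
    h3_pct <- 10; igg_pct <- 0.5; input_fraction <- 0.01; ct_input <- 18
    adj <- ct_input - log2(1 / input_fraction)
    pct_to_ct <- function(pct) adj - log2(pct / 100)
    chip <- do.call(rbind, lapply(c(a = "a", b = "b"), function(cond) {
      lab <- if (cond == "a") spec$condition_a else spec$condition_b
      tgt_pct <- igg_pct + chip_enrichment[[cond]] * (h3_pct - igg_pct)
      data.frame(locus = "CDH1_TSS",
                 antibody = c("target_mark", "total_H3", "IgG", "input"),
                 condition = lab,
                 ct = c(pct_to_ct(tgt_pct), pct_to_ct(h3_pct),
                        pct_to_ct(igg_pct), ct_input),
                 input_fraction = input_fraction,
                 stringsAsFactors = FALSE)
    }))
    rownames(chip) <- NULL
    list(rtpcr = rtpcr, patterns = patterns,
         comparisons = list(c("tgfb", "vehicle"),
                            c("withdraw_dmso", "tgfb"),
                            c("withdraw_gskj4", "withdraw_dmso")),
         reference_gene = ref, chip = chip)
  })
}

#' Generate a full synthetic dataset
#'
#' Bundles every generator: annotation, planted peaks and truth, the
#' two-condition expression table, a cohort whose planted gene set is the
#' Group I genes, a planted ontology, and the Ct tables.
#'
#' @param spec a `synthetic_spec`.
#' @return a `synthetic_dataset` list with elements `spec`, `annotation`,
#'   `peaks`, `truth`, `expression`, `cohort`, `ontology`, `ct_tables`.
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  annotation <- generate_annotation(spec)
  pk <- generate_condition_peaks(annotation, spec)
  expression <- generate_expression(pk$truth, spec)
  group1 <- pk$truth$gene_id[pk$truth$group == "I"]
  cohort <- generate_cohort(group1, spec)
  ontology <- generate_ontology(pk$truth, spec)
  ct_tables <- generate_ct_tables(spec)
  out <- list(spec = spec, annotation = annotation, peaks = pk$peaks,
              truth = pk$truth, expression = expression, cohort = cohort,
              ontology = ontology, ct_tables = ct_tables)
  class(out) <- "synthetic_dataset"
  out
}

#' Write a synthetic dataset in the pipeline's file formats
#'
#' Emits GTF annotation, one BED per mark and condition, expression and
#' truth TSVs, cohort matrix and metadata TSVs, a GMT ontology, and the
#' RT-PCR / ChIP Ct TSVs, so generated datasets double as worked examples.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- dataset$spec
  paths <- c(annotation = file.path(dir, "genes.gtf"))
  write_gtf(dataset$annotation, paths[["annotation"]])
  mark_key <- c(H3K4me3 = "k4", H3K27me3 = "k27")
  for (m in MARKS) for (cond in c(spec$condition_a, spec$condition_b)) {
    key <- sprintf("%s_%s", mark_key[[m]], cond)
    p <- file.path(dir, sprintf("peaks_%s_%s.bed", m, cond))
    sel <- dataset$peaks[dataset$peaks$mark == m &
                           dataset$peaks$condition == cond, ]
    write_bed(sel, p)
    paths[[key]] <- p
  }
  paths[["expression"]] <- file.path(dir, "expression.tsv")
  write_tsv(dataset$expression, paths[["expression"]])
  paths[["truth"]] <- file.path(dir, "truth.tsv")
  write_tsv(dataset$truth, paths[["truth"]])
  paths[["cohort_matrix"]] <- file.path(dir, "cohort_matrix.tsv")
  write_tsv(dataset$cohort$matrix, paths[["cohort_matrix"]])
  paths[["cohort_metadata"]] <- file.path(dir, "cohort_metadata.tsv")
  write_tsv(dataset$cohort$metadata[, c("sample_id", "ER", "PR", "HER2")],
            paths[["cohort_metadata"]])
  paths[["ontology"]] <- file.path(dir, "ontology.gmt")
  write_gmt(dataset$ontology, paths[["ontology"]])
  paths[["rtpcr"]] <- file.path(dir, "rtpcr_ct.tsv")
  write_tsv(dataset$ct_tables$rtpcr, paths[["rtpcr"]])
  paths[["qpcr_truth"]] <- file.path(dir, "rtpcr_truth.tsv")
  write_tsv(dataset$ct_tables$patterns, paths[["qpcr_truth"]])
  paths[["chip"]] <- file.path(dir, "chip_ct.tsv")
  write_tsv(dataset$ct_tables$chip, paths[["chip"]])
  paths[["signature"]] <- file.path(dir, "signature.txt")
  # reference signature enriched for Groups II and IV (the planted pattern
  # expected to carry the highest odds ratios)
  sig <- with_seed(spec$seed + 6L, {
    tr <- dataset$truth
    unique(c(tr$gene_id[tr$group %in% c("II", "IV")],
             sample(tr$gene_id[tr$group == "I"],
                    ceiling(0.15 * sum(tr$group == "I"))),
             sample(tr$gene_id[tr$group == "NONE"],
                    ceiling(0.05 * sum(tr$group == "NONE")))))
  })
  writeLines(sig, paths[["signature"]])
  invisible(paths)
}
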