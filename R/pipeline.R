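# Configuration-driven orchestration: one declarative config (YAML or
# JSON) validated up front with aggregated errors; each runner writes TSV
# and JSON outputs plus a structured log carrying the config hash and seed.

default_config <- function() {
  list(
    conditions = list(a = "vector", b = "twist"),
    promoter = list(upstream = 2000, downstream = 2000),
    thresholds = list(fpkm = 10, alpha = 0.05),
    chrom_style = "asis",
    cohort = list(statistic = "sum", single_gene = NULL, gene_set = NULL),
    qpcr = list(reference_gene = "GAPDH",
                comparisons = list(c("tgfb", "vehicle"),
                                   c("withdraw_dmso", "tgfb"),
                                   c("withdraw_gskj4", "withdraw_dmso")),
                family = "per_panel"),
    seed = 1,
    output_dir = "bivalency_out",
    paths = list()
  )
}

#' Read and validate a pipeline run configuration
#'
#' The config is a single declarative YAML (or JSON) file; unset fields
#' fall back to documented defaults. Validation is performed up front and
#' all problems are reported in one aggregated error: referenced paths must
#' exist, `alpha` must lie in (0, 1), and the promoter window must have
#' positive width.
#'
#' @param path path to a YAML or JSON config file.
#' @return a validated `run_config` list with a `hash` attribute (digest of
#'   the normalized config).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  validate_run_config(raw)
}

#' @rdname read_run_config
#' @param config a config list (as parsed from file, or built in code).
#' @export
validate_run_config <- function(config) {
  cfg <- utils::modifyList(default_config(), config)
  errors <- character()
  alpha <- cfg$thresholds$alpha
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    errors <- c(errors, sprintf("thresholds.alpha must be in (0, 1), got %s",
                                alpha))
  up <- cfg$promoter$upstream; down <- cfg$promoter$downstream
  if (!is.numeric(up) || !is.numeric(down) || up < 0 || down < 0 ||
      up + down <= 0)
    errors <- c(errors, "promoter window must be non-negative with positive total width")
  for (key in names(cfg$paths)) {
    p <- cfg$paths[[key]]
    if (!is.null(p) && !file.exists(p))
      errors <- c(errors, sprintf("paths.%s does not exist: %s", key, p))
  }
  if (length(errors))
    stopf("invalid run configuration:\n  - %s",
          paste(errors, collapse = "\n  - "))
  cfg$seed <- as.integer(cfg$seed)
  attr(cfg, "hash") <- digest::digest(cfg, algo = "sha256")
  class(cfg) <- "run_config"
  cfg
}

run_log <- function(config, stage, extra = list()) {
  c(list(stage = stage,
         package_version = as.character(utils::packageVersion("bivalency")),
         config_hash = attr(config, "hash"),
         seed = config$seed),
    extra)
}

require_paths <- function(config, keys, stage) {
  missing <- keys[vapply(keys, function(k) is.null(config$paths[[k]]), TRUE)]
  if (length(missing))
    stopf("%s: config paths missing: %s", stage,
          paste(missing, collapse = ", "))
}

#' Run the transition analysis stage
#'
#' Reads the annotation and the four peak files, classifies transitions,
#' and (when the corresponding inputs are configured) computes signature
#' overlap, term enrichment per group, and group expression summaries.
#' Writes `transitions.tsv`, `transition_summary.json`, `overlap.tsv`,
#' `enrichment_group_<g>.tsv`, `group_expression.tsv`,
#' `group_expression_tests.tsv` and `log.json` under the output directory.
#'
#' @param config a validated `run_config` (see [read_run_config()]).
#' @return invisibly, a list with the in-memory results bundle.
#' @export
run_transition_analysis <- function(config) {
  config <- validate_run_config(unclass(config))
  require_paths(config, c("annotation", "k4_a", "k27_a", "k4_b", "k27_b"),
                "run_transition_analysis")
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  genes <- read_gene_annotation(config$paths$annotation,
                                chrom_style = config$chrom_style)
  cond_a <- config$conditions$a; cond_b <- config$conditions$b
  peaks <- rbind(
    read_bed(config$paths$k4_a, "H3K4me3", cond_a, config$chrom_style),
    read_bed(config$paths$k27_a, "H3K27me3", cond_a, config$chrom_style),
    read_bed(config$paths$k4_b, "H3K4me3", cond_b, config$chrom_style),
    read_bed(config$paths$k27_b, "H3K27me3", cond_b, config$chrom_style))
  tt <- classify_transitions(genes, peaks, cond_a, cond_b,
                             config$promoter$upstream,
                             config$promoter$downstream)
  out <- list(transitions = tt)
  summary <- write_transition_table(
    tt, file.path(config$output_dir, "transitions.tsv"),
    file.path(config$output_dir, "transition_summary.json"))
  if (!is.null(config$paths$signature)) {
    sig <- read_gene_list(config$paths$signature)
    out$overlap <- overlap_all_groups(tt, sig)
    write_tsv(out$overlap, file.path(config$output_dir, "overlap.tsv"))
  }
  if (!is.null(config$paths$ontology)) {
    terms <- read_gmt(config$paths$ontology)
    universe <- tt$records$gene_id
    out$enrichment <- lapply(c("I", "II", "III", "IV"), function(g) {
      members <- group_members(tt, g)
      if (length(members) == 0L) return(NULL)
      res <- enrich_terms(members, universe, terms, mode = "two_list")
      write_tsv(res, file.path(config$output_dir,
                               sprintf("enrichment_group_%s.tsv", g)))
      res
    })
    names(out$enrichment) <- c("I", "II", "III", "IV")
  }
  if (!is.null(config$paths$expression)) {
    expr <- read_expression(config$paths$expression)
    gds <- group_difference_summary(expr, cond_a, cond_b, tt)
    out$group_expression <- gds
    write_tsv(gds$summary,
              file.path(config$output_dir, "group_expression.tsv"))
    write_tsv(gds$pairwise_p,
              file.path(config$output_dir, "group_expression_tests.tsv"))
  }
  log <- run_log(config, "transition_analysis",
                 list(n_genes = nrow(genes), n_peaks = nrow(peaks),
                      summary = summary))
  jsonlite::write_json(log, file.path(config$output_dir, "log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(out)
}

#' Run the cohort analysis stage
#'
#' Labels samples TN / non-TN / excluded from receptor metadata, then
#' compares the two arms by Welch's t-test on a single configured gene
#' (optional) and on the cumulative gene-set score. Requires at least two
#' samples per arm.
#'
#' @param config a validated `run_config`; needs `paths.cohort_matrix`,
#'   `paths.cohort_metadata`, and `cohort.gene_set` (path to a gene list)
#'   or `paths.gene_set`.
#' @return invisibly, a list with labels, scores and test results.
#' @export
run_cohort_analysis <- function(config) {
  config <- validate_run_config(unclass(config))
  require_paths(config, c("cohort_matrix", "cohort_metadata"),
                "run_cohort_analysis")
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  mat <- read_expression(config$paths$cohort_matrix)
  meta <- label_cohort(read_tsv(config$paths$cohort_metadata))
  tn <- meta$sample_id[meta$label == "TN"]
  non_tn <- meta$sample_id[meta$label == "NON_TN"]
  if (length(tn) == 0L && length(non_tn) == 0L)
    stopf("run_cohort_analysis: every sample is EXCLUDED by the TN rule (TN requires ER, PR and HER2 all definitively negative; non-TN requires at least one definitively positive)")
  if (length(tn) < 2 || length(non_tn) < 2)
    stopf("run_cohort_analysis: need >= 2 samples per arm (TN: %d, non-TN: %d)",
          length(tn), length(non_tn))
  out <- list(labels = meta)
  gene_set_path <- config$cohort$gene_set
  if (is.null(gene_set_path)) gene_set_path <- config$paths$gene_set
  if (is.null(gene_set_path))
    stopf("run_cohort_analysis: no gene set configured (cohort.gene_set)")
  gene_set <- read_gene_list(gene_set_path)
  scores <- geneset_cumulative_score(mat, gene_set,
                                     statistic = config$cohort$statistic)
  out$scores <- scores
  out$geneset_test <- welch_t_test(scores[tn], scores[non_tn])
  if (!is.null(config$cohort$single_gene)) {
    g <- config$cohort$single_gene
    row <- which(mat$gene_id == g)
    if (length(row) != 1L)
      stopf("run_cohort_analysis: single gene '%s' not in matrix", g)
    v <- as.numeric(mat[row, setdiff(names(mat), "gene_id")])
    names(v) <- setdiff(names(mat), "gene_id")
    out$single_gene_test <- welch_t_test(v[tn], v[non_tn])
  }
  write_tsv(meta, file.path(config$output_dir, "cohort_labels.tsv"))
  write_tsv(data.frame(sample_id = names(scores), score = unname(scores),
                       stringsAsFactors = FALSE),
            file.path(config$output_dir, "cohort_scores.tsv"))
  results <- list(
    arms = list(TN = length(tn), NON_TN = length(non_tn),
                EXCLUDED = sum(meta$label == "EXCLUDED")),
    geneset_test = out$geneset_test,
    geneset_means = list(TN = mean(scores[tn]),
                         NON_TN = mean(scores[non_tn])),
    single_gene_test = out$single_gene_test)
  jsonlite::write_json(c(run_log(config, "cohort_analysis"), results),
                       file.path(config$output_dir, "cohort_results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(out)
}

#' Run the qPCR / ChIP-qPCR analysis stage
#'
#' Computes per-gene fold changes and Holm-Sidak-adjusted p-values for the
#' configured three comparisons, the three-criterion reactivation-call
#' table with per-group counts, and (when a ChIP table is configured) the
#' percent-input / H3-normalized enrichment table with the between-
#' condition fold.
#'
#' @param config a validated `run_config`; needs `paths.ct_table`, and
#'   optionally `paths.chip_table` and `paths.qpcr_truth` (per-gene group
#'   labels).
#' @return invisibly, a list with the calls, counts and ChIP table.
#' @export
run_qpcr_analysis <- function(config) {
  config <- validate_run_config(unclass(config))
  require_paths(config, "ct_table", "run_qpcr_analysis")
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  ct <- read_ct_table(config$paths$ct_table)
  truth <- if (!is.null(config$paths$qpcr_truth))
    read_tsv(config$paths$qpcr_truth) else NULL
  res <- met_reactivation_table(
    ct, config$qpcr$comparisons, config$qpcr$reference_gene,
    alpha = config$thresholds$alpha, family = config$qpcr$family,
    truth = truth)
  write_tsv(res$calls, file.path(config$output_dir, "reactivation_calls.tsv"))
  out <- list(calls = res$calls, counts = res$counts)
  if (!is.null(config$paths$chip_table)) {
    chip <- read_tsv(config$paths$chip_table)
    conds <- unique(chip$condition)
    enr <- do.call(rbind, lapply(split(chip, chip$condition), function(cc) {
      get_ct <- function(ab) cc$ct[cc$antibody == ab][1]
      f <- cc$input_fraction[1]
      pi_tgt <- percent_input(get_ct("target_mark"), get_ct("input"), f)
      pi_h3 <- percent_input(get_ct("total_H3"), get_ct("input"), f)
      pi_igg <- percent_input(get_ct("IgG"), get_ct("input"), f)
      h <- h3_normalized_enrichment(pi_tgt, pi_h3, pi_igg)
      data.frame(locus = cc$locus[1], condition = cc$condition[1],
                 percent_input_target = pi_tgt, percent_input_h3 = pi_h3,
                 percent_input_igg = pi_igg, h3_normalized = h$value,
                 floored = h$floored, stringsAsFactors = FALSE)
    }))
    rownames(enr) <- NULL
    if (all(c(config$conditions$a, config$conditions$b) %in% enr$condition)) {
      enr_a <- enr$h3_normalized[enr$condition == config$conditions$a]
      enr_b <- enr$h3_normalized[enr$condition == config$conditions$b]
      out$chip_fold <- fold_enrichment(enr_b[1], enr_a[1])
    }
    out$chip <- enr
    write_tsv(enr, file.path(config$output_dir, "chip_enrichment.tsv"))
  }
  results <- list(counts = apply(res$counts, 1, as.list),
                  chip_fold = out$chip_fold)
  jsonlite::write_json(c(run_log(config, "qpcr_analysis"), results),
                       file.path(config$output_dir, "qpcr_results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(out)
}

#' Simulate a dataset and run every stage on it
#'
#' Convenience end-to-end driver: generates a synthetic dataset under the
#' configured seed, writes it to `<output_dir>/data`, builds a matching
#' config, and runs the transition, cohort and qPCR stages.
#'
#' @param config a `run_config` (only `seed`, `output_dir`, thresholds and
#'   conditions are used); or `NULL` for defaults.
#' @param spec optionally, a pre-built [synthetic_spec()] (its seed wins).
#' @return invisibly, a list with the dataset and each stage's bundle.
#' @export
run_all_synthetic <- function(config = NULL, spec = NULL) {
  cfg <- validate_run_config(if (is.null(config)) list() else
    unclass(config))
  if (is.null(spec))
    spec <- synthetic_spec(seed = cfg$seed,
                           condition_a = cfg$conditions$a,
                           condition_b = cfg$conditions$b,
                           upstream = cfg$promoter$upstream,
                           downstream = cfg$promoter$downstream)
  ds <- generate_dataset(spec)
  data_dir <- file.path(cfg$output_dir, "data")
  paths <- write_dataset(ds, data_dir)
  group1_path <- file.path(data_dir, "group1_genes.txt")
  writeLines(ds$truth$gene_id[ds$truth$group == "I"], group1_path)
  cfg$paths <- list(annotation = paths[["annotation"]],
                    k4_a = paths[["k4_" %+% spec$condition_a]],
                    k27_a = paths[["k27_" %+% spec$condition_a]],
                    k4_b = paths[["k4_" %+% spec$condition_b]],
                    k27_b = paths[["k27_" %+% spec$condition_b]],
                    expression = paths[["expression"]],
                    signature = paths[["signature"]],
                    ontology = paths[["ontology"]],
                    cohort_matrix = paths[["cohort_matrix"]],
                    cohort_metadata = paths[["cohort_metadata"]],
                    ct_table = paths[["rtpcr"]],
                    qpcr_truth = paths[["qpcr_truth"]],
                    chip_table = paths[["chip"]])
  cfg$cohort$gene_set <- group1_path
  cfg <- validate_run_config(unclass(cfg))
  list(dataset = ds,
       transition = run_transition_analysis(cfg),
       cohort = run_cohort_analysis(cfg),
       qpcr = run_qpcr_analysis(cfg))
}

`%+%` <- function(a, b) paste0(a, b)
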