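# Deterministic qPCR / ChIP-qPCR calculators: comparative Ct fold changes,
# Holm-Sidak step-down correction, the three-criterion MET-reactivation
# call, percent-input and H3-normalized ChIP enrichment.

#' Comparative Ct (2^-ddCt) fold change
#'
#' Replicate Cts must be averaged per (target, sample) before calling.
#' `dCt = ct_target - ct_ref` within each sample; `ddCt = dCt_cond -
#' dCt_ctrl`; the fold change is `2^-ddCt` of the condition relative to the
#' control.
#'
#' @param ct_target_cond,ct_ref_cond mean Cts of the target and reference
#'   gene in the condition of interest.
#' @param ct_target_ctrl,ct_ref_ctrl mean Cts in the control condition.
#' @return fold change (positive real).
#' @export
#' @examples
#' delta_delta_ct(25, 20, 24, 20)  # ddCt = +1 -> 0.5
delta_delta_ct <- function(ct_target_cond, ct_ref_cond,
                           ct_target_ctrl, ct_ref_ctrl) {
  for (v in list(ct_target_cond, ct_ref_cond, ct_target_ctrl, ct_ref_ctrl))
    if (length(v) != 1L || is.na(v) || !is.finite(v))
      stopf("delta_delta_ct: all four mean Cts must be single finite values")
  ddct <- (ct_target_cond - ct_ref_cond) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}

#' Holm-Sidak step-down adjustment
#'
#' Sorts the p-values ascending, applies `1 - (1 - p_(i))^(m - i + 1)`,
#' enforces monotone non-decreasing adjusted values down the sorted list,
#' caps at 1, and returns them in the original order. Adjusted values are
#' never below the raw ones.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order as `p`.
#' @export
holm_sidak_adjust <- function(p) {
  p <- as.numeric(p)
  if (length(p) == 0L) return(numeric())
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stopf("holm_sidak_adjust: p-values must be in [0, 1]")
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- 1 - (1 - sorted)^(m - seq_len(m) + 1)
  adj <- pmin(1, cummax(adj))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Three-criterion MET-reactivation call for one gene
#'
#' Encodes the summary-table logic for testing whether a gene is (1)
#' repressed during EMT (lower under TGFB than vehicle), (2) re-expressed
#' during MET (higher after TGFB withdrawal), and (3) blocked by the
#' demethylase inhibitor (lower under GSK-J4 than DMSO during withdrawal).
#' Each criterion requires the comparison to be significant at `alpha`
#' (adjusted p) *and* in the stated direction; `full_pattern` is the
#' conjunction of all three.
#'
#' @param p_adj numeric length-3: adjusted p-values for the EMT, MET and
#'   inhibitor comparisons (in that order).
#' @param fold numeric length-3: fold changes (case over control) for the
#'   same comparisons; `< 1` means lower in the case condition.
#' @param alpha significance threshold on the adjusted p (default 0.05).
#' @return list with `down_in_emt`, `up_in_met`, `blocked_by_inhibitor`,
#'   `full_pattern` (logicals).
#' @export
met_reactivation_call <- function(p_adj, fold, alpha = 0.05) {
  if (length(p_adj) != 3L || length(fold) != 3L || anyNA(p_adj) || anyNA(fold))
    stopf("met_reactivation_call: need complete p_adj and fold of length 3 (EMT, MET, inhibitor)")
  sig <- p_adj < alpha
  down_in_emt <- sig[1] && fold[1] < 1
  up_in_met <- sig[2] && fold[2] > 1
  blocked <- sig[3] && fold[3] < 1
  list(down_in_emt = down_in_emt, up_in_met = up_in_met,
       blocked_by_inhibitor = blocked,
       full_pattern = down_in_emt && up_in_met && blocked)
}

#' ChIP-qPCR percent input
#'
#' The input Ct is first adjusted for the fraction of chromatin used as
#' input (`adjusted = ct_input - log2(1 / input_fraction)`); percent input
#' is then `100 * 2^(adjusted - ct_ip)`.
#'
#' @param ct_ip Ct of the immunoprecipitated sample.
#' @param ct_input Ct of the input sample.
#' @param input_fraction fraction of chromatin used as input, in `(0, 1]`.
#' @return percent input (0-100 under normal signals; can exceed 100).
#' @export
percent_input <- function(ct_ip, ct_input, input_fraction) {
  if (any(input_fraction <= 0 | input_fraction > 1))
    stopf("percent_input: input_fraction must be in (0, 1]")
  adjusted <- ct_input - log2(1 / input_fraction)
  100 * 2^(adjusted - ct_ip)
}

#' H3-normalized, IgG-subtracted ChIP enrichment
#'
#' Normalizes a target-mark percent-input signal to total H3 after
#' subtracting the IgG background from both (`subtract_first`, default), or
#' normalizes first and then subtracts the IgG/H3 ratio
#' (`subtract_after`). Negative numerators are floored at 0 and flagged.
#'
#' @param signal_target,signal_h3,signal_igg percent-input values for the
#'   target mark, total H3, and the IgG control.
#' @param mode `"subtract_first"` or `"subtract_after"`.
#' @return list with `value` (>= 0) and `floored` (logical flag).
#' @export
h3_normalized_enrichment <- function(signal_target, signal_h3, signal_igg,
                                     mode = c("subtract_first",
                                              "subtract_after")) {
  mode <- match.arg(mode)
  if (signal_h3 <= signal_igg)
    stopf("h3_normalized_enrichment: H3 signal must exceed IgG background")
  if (mode == "subtract_first") {
    num <- signal_target - signal_igg
    den <- signal_h3 - signal_igg
  } else {
    num <- signal_target / signal_h3 - signal_igg / signal_h3
    den <- 1
  }
  floored <- num < 0
  list(value = max(0, num) / den, floored = floored)
}

#' Fold enrichment between two conditions
#'
#' @param value_b,value_a scalar signals (e.g. H3-normalized enrichment) in
#'   the condition of interest and the reference condition.
#' @return `value_b / value_a`; `NA` with a warning when `value_a` is 0.
#' @export
fold_enrichment <- function(value_b, value_a) {
  if (value_a == 0) {
    warnf("fold_enrichment undefined: reference value is 0")
    return(NA_real_)
  }
  value_b / value_a
}

#' Read a replicate Ct table
#'
#' TSV with columns `target`, `sample`, `replicate`, `ct`. Malformed rows
#' (non-numeric or non-positive ct) abort with line numbers.
#'
#' @param path path to the TSV.
#' @return data.frame of Ct measurements.
#' @export
read_ct_table <- function(path) {
  df <- read_tsv(path)
  need <- c("target", "sample", "replicate", "ct")
  if (!all(need %in% names(df)))
    stopf("Ct table %s needs columns: %s", path, paste(need, collapse = ", "))
  ct <- suppressWarnings(as.numeric(df$ct))
  bad <- which(is.na(ct) | ct <= 0)
  if (length(bad))
    stopf("Ct table parse error in %s: invalid ct on data row(s) %s",
          path, paste(bad, collapse = ", "))
  df$ct <- ct
  df
}

# Mean Ct per (target, sample) from a replicate table.
mean_ct <- function(ct_table, target, sample) {
  v <- ct_table$ct[ct_table$target == target & ct_table$sample == sample]
  if (length(v) == 0L)
    stopf("no Ct measurement for target '%s' in sample '%s'", target, sample)
  mean(v)
}

#' Per-gene expression fold changes from a replicate Ct table
#'
#' Averages replicate Cts per (target, sample), then applies the
#' comparative Ct method with the named reference gene.
#'
#' @param ct_table data.frame from [read_ct_table()].
#' @param targets character vector of target genes (defaults to every
#'   non-reference target present).
#' @param reference_gene reference (housekeeping) gene label, e.g. GAPDH.
#' @param condition,control sample labels to compare.
#' @return data.frame with `target`, `fold_change` (2^-ddCt of condition
#'   vs control).
#' @export
qpcr_fold_changes <- function(ct_table, reference_gene, condition, control,
                              targets = NULL) {
  if (is.null(targets))
    targets <- setdiff(unique(ct_table$target), reference_gene)
  if (!reference_gene %in% ct_table$target)
    stopf("reference gene '%s' missing from the Ct table", reference_gene)
  fc <- vapply(targets, function(tg)
    delta_delta_ct(mean_ct(ct_table, tg, condition),
                   mean_ct(ct_table, reference_gene, condition),
                   mean_ct(ct_table, tg, control),
                   mean_ct(ct_table, reference_gene, control)),
    numeric(1))
  data.frame(target = targets, fold_change = unname(fc),
             stringsAsFactors = FALSE)
}

#' Reactivation-call table from replicate Ct data
#'
#' Full significance engine for a three-comparison qPCR panel: per gene and
#' comparison, replicate dCt values (target Ct minus reference-gene Ct,
#' replicate-matched) are compared between the two conditions by an
#' unpaired two-sided Welch t-test; p-values are Holm-Sidak-adjusted within
#' each comparison panel across genes (default) or within each gene; fold
#' changes come from the comparative Ct method; and the three-criterion
#' call of [met_reactivation_call()] is made per gene.
#'
#' @param ct_table replicate Ct data.frame (see [read_ct_table()]).
#' @param comparisons list of three `c(case, control)` sample-label pairs,
#'   ordered EMT, MET, inhibitor.
#' @param reference_gene reference gene label.
#' @param alpha significance threshold on adjusted p.
#' @param family `"per_panel"` (adjust across genes within a comparison) or
#'   `"per_gene"` (adjust the three comparisons within each gene).
#' @param truth optional data.frame of per-gene planted group labels
#'   (columns `target`, `group`) merged into the output.
#' @return list with `calls` (data.frame: `target`, per-comparison fold and
#'   adjusted p, the four call booleans) and `counts` (per-criterion and
#'   full-pattern totals; split by `group` when `truth` is given). Genes
#'   missing any comparison are excluded with a message.
#' @export
met_reactivation_table <- function(ct_table, comparisons, reference_gene,
                                   alpha = 0.05,
                                   family = c("per_panel", "per_gene"),
                                   truth = NULL) {
  family <- match.arg(family)
  if (length(comparisons) != 3L)
    stopf("met_reactivation_table: exactly three comparisons required")
  genes <- setdiff(unique(ct_table$target), reference_gene)
  dct_reps <- function(tg, smp) {
    sub <- ct_table[ct_table$sample == smp &
                      ct_table$target %in% c(tg, reference_gene), ]
    tgt <- sub[sub$target == tg, ]
    ref <- sub[sub$target == reference_gene, ]
    if (nrow(tgt) == 0L || nrow(ref) == 0L) return(NULL)
    idx <- match(tgt$replicate, ref$replicate)
    if (anyNA(idx)) return(NULL)
    tgt$ct - ref$ct[idx]
  }
  rows <- list(); dropped <- character()
  p_raw <- matrix(NA_real_, nrow = length(genes), ncol = 3,
                  dimnames = list(genes, NULL))
  folds <- p_raw
  for (g in genes) {
    ok <- TRUE
    for (j in 1:3) {
      case <- dct_reps(g, comparisons[[j]][1])
      ctrl <- dct_reps(g, comparisons[[j]][2])
      if (is.null(case) || is.null(ctrl) ||
          length(case) < 2 || length(ctrl) < 2) { ok <- FALSE; break }
      p_raw[g, j] <- welch_t_test(case, ctrl)$p_value
      folds[g, j] <- 2^(-(mean(case) - mean(ctrl)))
    }
    if (!ok) dropped <- c(dropped, g)
  }
  if (length(dropped)) {
    message(sprintf("met_reactivation_table: %d gene(s) missing a comparison, excluded: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
    genes <- setdiff(genes, dropped)
    p_raw <- p_raw[genes, , drop = FALSE]
    folds <- folds[genes, , drop = FALSE]
  }
  if (length(genes) == 0L)
    stopf("met_reactivation_table: no gene has all three comparisons")
  p_adj <- p_raw
  if (family == "per_panel") {
    for (j in 1:3) p_adj[, j] <- holm_sidak_adjust(p_raw[, j])
  } else {
    for (g in genes) p_adj[g, ] <- holm_sidak_adjust(p_raw[g, ])
  }
  calls <- do.call(rbind, lapply(genes, function(g) {
    cl <- met_reactivation_call(p_adj[g, ], folds[g, ], alpha)
    data.frame(target = g,
               fold_emt = folds[g, 1], p_adj_emt = p_adj[g, 1],
               fold_met = folds[g, 2], p_adj_met = p_adj[g, 2],
               fold_inhib = folds[g, 3], p_adj_inhib = p_adj[g, 3],
               down_in_emt = cl$down_in_emt, up_in_met = cl$up_in_met,
               blocked_by_inhibitor = cl$blocked_by_inhibitor,
               full_pattern = cl$full_pattern, stringsAsFactors = FALSE)
  }))
  if (!is.null(truth)) {
    if (!all(c("target", "group") %in% names(truth)))
      stopf("met_reactivation_table: truth needs 'target' and 'group' columns")
    calls <- merge(calls, truth[, c("target", "group")], by = "target",
                   all.x = TRUE, sort = TRUE)
  }
  count_block <- function(df) c(
    n = nrow(df), down_in_emt = sum(df$down_in_emt),
    up_in_met = sum(df$up_in_met),
    blocked_by_inhibitor = sum(df$blocked_by_inhibitor),
    full_pattern = sum(df$full_pattern))
  counts <- if (!is.null(truth) && "group" %in% names(calls)) {
    t(vapply(split(calls, calls$group), count_block, numeric(5)))
  } else {
    t(count_block(calls))
  }
  list(calls = calls, counts = counts)
}
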