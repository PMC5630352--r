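# Promoter mark calls, per-condition chromatin states, and transition
# groups I-IV for genes bivalent in the second condition.

CHROMATIN_STATES <- c("K4_ONLY", "K27_ONLY", "BIVALENT", "UNMARKED")
TRANSITION_GROUPS <- c("I", "II", "III", "IV", "NONE")

#' Is a mark present at a promoter?
#'
#' A mark is called present when any peak overlaps the promoter by at least
#' 1 bp under half-open interval semantics. Peak order is irrelevant and
#' peak scores are ignored: the call is presence/absence.
#'
#' @param promoter a one-row data.frame with `chrom`, `start`, `end`.
#' @param peaks a `peak_set` data.frame; all rows must share one mark and
#'   one condition label (mixed labels are an error).
#' @return logical scalar.
#' @export
call_mark_presence <- function(promoter, peaks) {
  stopifnot(nrow(promoter) == 1L)
  if (nrow(peaks) == 0L) return(FALSE)
  if (length(unique(peaks$mark)) > 1L || length(unique(peaks$condition)) > 1L)
    stopf("call_mark_presence: peaks mix mark or condition labels")
  any(peaks$chrom == promoter$chrom &
        peaks$start < promoter$end &
        peaks$end > promoter$start)
}

#' Chromatin state from two mark calls
#'
#' @param k4_present,k27_present logical vectors (recycled to a common
#'   length): presence of H3K4me3 and H3K27me3 at the promoter.
#' @return character vector over `"BIVALENT"`, `"K4_ONLY"`, `"K27_ONLY"`,
#'   `"UNMARKED"`. A promoter is bivalent iff both marks are present.
#' @export
#' @examples
#' classify_state(TRUE, TRUE)   # "BIVALENT"
#' classify_state(TRUE, FALSE)  # "K4_ONLY"
classify_state <- function(k4_present, k27_present) {
  n <- max(length(k4_present), length(k27_present))
  k4 <- rep_len(as.logical(k4_present), n)
  k27 <- rep_len(as.logical(k27_present), n)
  ifelse(k4 & k27, "BIVALENT",
         ifelse(k4, "K4_ONLY",
                ifelse(k27, "K27_ONLY", "UNMARKED")))
}

#' Transition group from the two per-condition states
#'
#' Genes bivalent in condition B are partitioned by their condition A state:
#' Group I was premarked with H3K4me3 only (gains H3K27me3), Group II was
#' premarked with H3K27me3 only (gains H3K4me3), Group III was unmarked
#' (acquires both), and Group IV was already bivalent (no change). Genes not
#' bivalent in condition B get `"NONE"`.
#'
#' @param state_a,state_b character vectors of chromatin states (see
#'   [classify_state()]), recycled to a common length.
#' @return character vector over `"I"`, `"II"`, `"III"`, `"IV"`, `"NONE"`.
#' @export
assign_transition_group <- function(state_a, state_b) {
  n <- max(length(state_a), length(state_b))
  a <- rep_len(as.character(state_a), n)
  b <- rep_len(as.character(state_b), n)
  bad <- !(a %in% CHROMATIN_STATES) | !(b %in% CHROMATIN_STATES)
  if (any(bad)) stopf("unknown chromatin state: %s",
                      paste(unique(c(a, b)[c(bad, bad)]), collapse = ", "))
  out <- rep("NONE", n)
  biv <- b == "BIVALENT"
  out[biv] <- c(K4_ONLY = "I", K27_ONLY = "II",
                UNMARKED = "III", BIVALENT = "IV")[a[biv]]
  out
}

# Vectorized overlap call: which promoters carry >= 1 bp of peak overlap.
promoters_hit <- function(promoters, peaks) {
  if (nrow(peaks) == 0L) return(rep(FALSE, nrow(promoters)))
  levels <- unique(c(promoters$chrom, peaks$chrom))
  pr <- GenomicRanges::GRanges(
    factor(promoters$chrom, levels = levels),
    IRanges::IRanges(start = promoters$start + 1L, end = promoters$end))
  pk <- GenomicRanges::GRanges(
    factor(peaks$chrom, levels = levels),
    IRanges::IRanges(start = peaks$start + 1L, end = peaks$end))
  GenomicRanges::countOverlaps(pr, pk, minoverlap = 1L) > 0L
}

#' Classify genes into bivalency transition groups
#'
#' Calls mark presence at each gene's promoter window for both marks in both
#' conditions, assigns per-condition chromatin states, and partitions the
#' genes bivalent in condition B into Groups I-IV by their condition A
#' state. Counting is per gene; when the annotation carries several TSS
#' records per gene (see `multi_tss = "any"` in [read_gene_annotation()]),
#' a mark at any of the gene's windows marks the gene.
#'
#' @param genes a `gene_annotation` data.frame.
#' @param peaks a single `peak_set` data.frame carrying all four peak
#'   collections (2 marks x 2 conditions), e.g. produced by row-binding
#'   [read_bed()] results.
#' @param condition_a,condition_b condition labels present in
#'   `peaks$condition`; A is the premarked/reference (epithelial) condition.
#' @param upstream,downstream promoter window extents passed to
#'   [promoter_window()].
#' @return a `transition_table`: list with `records` (data.frame `gene_id`,
#'   `state_a`, `state_b`, `group`), `counts` (named vector over I-IV),
#'   `n_bivalent_a`, `n_bivalent_b`, and the window/condition parameters.
#' @export
classify_transitions <- function(genes, peaks,
                                 condition_a, condition_b,
                                 upstream = 2000, downstream = 2000) {
  if (is.null(genes) || nrow(genes) == 0L)
    stopf("classify_transitions: empty gene list")
  if (is.null(peaks))
    stopf("classify_transitions: peaks must be supplied")
  # A supplied-but-empty collection is legal (no peaks called); what we
  # reject is a non-empty peak table that never mentions a requested
  # condition label, which indicates a missing collection or a label typo.
  absent <- setdiff(c(condition_a, condition_b), unique(peaks$condition))
  if (nrow(peaks) > 0L && length(absent))
    stopf("classify_transitions: no peaks labeled for condition(s): %s",
          paste(absent, collapse = ", "))
  prom <- promoter_window(genes, upstream, downstream)
  sel <- function(m, cd) peaks[peaks$mark == m & peaks$condition == cd, ,
                               drop = FALSE]
  # a gene with several annotated TSS windows (multi_tss = "any") is
  # marked when any of its windows carries the mark
  gid <- factor(genes$gene_id, levels = unique(genes$gene_id))
  agg <- function(hits) as.logical(tapply(hits, gid, any))
  k4_a <- agg(promoters_hit(prom, sel("H3K4me3", condition_a)))
  k27_a <- agg(promoters_hit(prom, sel("H3K27me3", condition_a)))
  k4_b <- agg(promoters_hit(prom, sel("H3K4me3", condition_b)))
  k27_b <- agg(promoters_hit(prom, sel("H3K27me3", condition_b)))
  state_a <- classify_state(k4_a, k27_a)
  state_b <- classify_state(k4_b, k27_b)
  group <- assign_transition_group(state_a, state_b)
  records <- data.frame(gene_id = levels(gid), state_a = state_a,
                        state_b = state_b, group = group,
                        stringsAsFactors = FALSE)
  records <- records[order(records$gene_id), , drop = FALSE]
  rownames(records) <- NULL
  counts <- vapply(c("I", "II", "III", "IV"),
                   function(g) sum(records$group == g), integer(1))
  n_biv_b <- sum(state_b == "BIVALENT")
  stopifnot(sum(counts) == n_biv_b)  # partition invariant
  out <- list(records = records, counts = counts,
              n_bivalent_a = sum(state_a == "BIVALENT"),
              n_bivalent_b = n_biv_b,
              condition_a = condition_a, condition_b = condition_b,
              upstream = upstream, downstream = downstream)
  class(out) <- "transition_table"
  out
}

#' @export
print.transition_table <- function(x, ...) {
  cat(sprintf("transition_table: %d genes (%s -> %s)\n",
              nrow(x$records), x$condition_a, x$condition_b))
  cat(sprintf("  bivalent genes: %d in A, %d in B\n",
              x$n_bivalent_a, x$n_bivalent_b))
  shares <- group_shares(x)
  for (g in names(x$counts))
    cat(sprintf("  Group %-3s %5d  (%.1f%% of bivalent-in-B)\n",
                g, x$counts[[g]], 100 * shares[[g]]))
  invisible(x)
}

#' Per-group share of the genes bivalent in condition B
#'
#' @param table a `transition_table`.
#' @return named numeric vector over groups I-IV summing to 1 (all `NaN`
#'   when no gene is bivalent in B).
#' @export
group_shares <- function(table) {
  table$counts / table$n_bivalent_b
}

#' Fold change in the number of bivalent genes between conditions
#'
#' @param table a `transition_table`.
#' @return `n_bivalent_b / n_bivalent_a`; `NA` (with a warning) when no
#'   gene is bivalent in condition A. Counted on genes, not domains.
#' @export
bivalency_fold_change <- function(table) {
  if (table$n_bivalent_a == 0) {
    warnf("bivalency fold change undefined: no bivalent genes in condition A")
    return(NA_real_)
  }
  table$n_bivalent_b / table$n_bivalent_a
}

#' Serialize a transition table
#'
#' Writes the per-gene records as TSV and a JSON summary (gene-count based:
#' counts, condition-wise bivalent gene totals, fold change, group shares).
#'
#' @param table a `transition_table`.
#' @param tsv_path,json_path output paths (either may be `NULL` to skip).
#' @return invisibly, the JSON summary as a list.
#' @export
write_transition_table <- function(table, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) write_tsv(table$records, tsv_path)
  fc <- if (table$n_bivalent_a > 0)
    table$n_bivalent_b / table$n_bivalent_a else NA_real_
  summary <- list(
    unit = "genes",
    n_genes = nrow(table$records),
    counts = as.list(table$counts),
    n_bivalent_a = table$n_bivalent_a,
    n_bivalent_b = table$n_bivalent_b,
    bivalency_fold_change = fc,
    group_shares = as.list(group_shares(table)),
    condition_a = table$condition_a, condition_b = table$condition_b,
    upstream = table$upstream, downstream = table$downstream)
  if (!is.null(json_path))
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  invisible(summary)
}

#' Gene members of one transition group
#'
#' @param table a `transition_table`.
#' @param group one of `"I"`, `"II"`, `"III"`, `"IV"`, `"NONE"`.
#' @return character vector of gene ids.
#' @export
group_members <- function(table, group) {
  group <- match.arg(group, TRANSITION_GROUPS)
  table$records$gene_id[table$records$group == group]
}
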