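# Gene-set overlap against a reference signature: 2x2 contingency tables,
# Fisher's exact test (two-sided, minimum-likelihood rule) and odds ratios
# with Haldane-Anscombe correction for zero cells.

#' Build a 2x2 contingency table for two gene sets within a universe
#'
#' Cell layout: `a` = in both sets, `b` = in the group only, `c` = in the
#' reference only, `d` = in neither. Reference members outside the universe
#' are dropped (their count is reported via a message); the group must be a
#' subset of the universe.
#'
#' @param group_set,reference_set,universe character vectors of gene ids
#'   (duplicates removed).
#' @return a named list `a`, `b`, `c`, `d`, `n_dropped_reference` with class
#'   `contingency_2x2`; `a + b + c + d == length(unique(universe))`.
#' @export
build_contingency <- function(group_set, reference_set, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stopf("build_contingency: empty universe")
  group_set <- unique(as.character(group_set))
  reference_set <- unique(as.character(reference_set))
  if (!all(group_set %in% universe))
    stopf("build_contingency: group set contains %d gene(s) outside universe",
          sum(!group_set %in% universe))
  dropped <- sum(!reference_set %in% universe)
  if (dropped > 0)
    message(sprintf("build_contingency: %d reference gene(s) outside universe dropped",
                    dropped))
  reference_set <- intersect(reference_set, universe)
  a <- length(intersect(group_set, reference_set))
  b <- length(group_set) - a
  c_ <- length(reference_set) - a
  d <- length(universe) - a - b - c_
  out <- list(a = a, b = b, c = c_, d = d, n_dropped_reference = dropped)
  class(out) <- "contingency_2x2"
  out
}

#' Two-sided Fisher's exact p for a 2x2 table
#'
#' With fixed margins, sums the hypergeometric probabilities of every table
#' whose probability does not exceed that of the observed table (the
#' minimum-likelihood two-sided convention). Degenerate margins give p = 1.
#'
#' @param table a `contingency_2x2` (from [build_contingency()]) or a named
#'   list/vector with elements `a`, `b`, `c`, `d`.
#' @return p-value in `[0, 1]`.
#' @export
fisher_exact_p <- function(table) {
  a <- table$a; b <- table$b; c_ <- table$c; d <- table$d
  stopifnot(all(c(a, b, c_, d) >= 0))
  m <- a + b          # group size
  k <- a + c_         # reference size
  N <- a + b + c_ + d
  if (m == 0 || k == 0 || m == N || k == N) return(1)
  lo <- max(0L, m + k - N)
  hi <- min(m, k)
  support <- lo:hi
  probs <- dhyper(support, k, N - k, m)
  p_obs <- dhyper(a, k, N - k, m)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(1, p)
}

#' Odds ratio of a 2x2 table with zero-cell correction
#'
#' Returns `(a*d)/(b*c)`. When any cell is zero, 0.5 is added to every cell
#' (Haldane-Anscombe) so the ratio stays finite and serializable; the
#' `corrected` flag records that this happened.
#'
#' @param table as in [fisher_exact_p()].
#' @return list with `odds_ratio` (finite, >= 0) and `corrected` (logical).
#' @export
odds_ratio <- function(table) {
  cells <- c(table$a, table$b, table$c, table$d)
  stopifnot(all(cells >= 0))
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  list(odds_ratio = (cells[1] * cells[4]) / (cells[2] * cells[3]),
       corrected = corrected)
}

#' Signature overlap for every transition group
#'
#' Runs [build_contingency()], [fisher_exact_p()] and [odds_ratio()] for
#' Groups I-IV against a reference gene signature. The universe defaults to
#' all genes scored in the transition analysis (the same background
#' convention as the enrichment module).
#'
#' @param table a `transition_table`.
#' @param reference_set character vector of reference signature gene ids
#'   (e.g. read with [read_gene_list()]).
#' @param universe optional character vector; defaults to all genes in
#'   `table$records`.
#' @return data.frame with one row per group: `group`, `a`, `b`, `c`, `d`,
#'   `odds_ratio`, `corrected`, `p_value`, `empty_group` (flag for groups
#'   with zero members, which are reported, not dropped).
#' @export
overlap_all_groups <- function(table, reference_set, universe = NULL) {
  if (is.null(universe)) universe <- table$records$gene_id
  res <- lapply(c("I", "II", "III", "IV"), function(g) {
    members <- group_members(table, g)
    ct <- build_contingency(members, reference_set, universe)
    or <- odds_ratio(ct)
    data.frame(group = g, a = ct$a, b = ct$b, c = ct$c, d = ct$d,
               odds_ratio = or$odds_ratio, corrected = or$corrected,
               p_value = fisher_exact_p(ct),
               empty_group = length(members) == 0L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Read a one-gene-per-line signature file
#'
#' @param path path to a text file, one gene id per line (blank lines and
#'   `#` comments ignored).
#' @return character vector of unique gene ids.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- trimws(readLines(path))
  unique(lines[nzchar(lines) & !startsWith(lines, "#")])
}
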