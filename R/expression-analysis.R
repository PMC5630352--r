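# Group-wise expression statistics: the FPKM filter, fraction of genes
# repressed between conditions, per-group difference summaries with
# Mann-Whitney tests, cohort gene-set scoring, Welch's t-test and
# triple-negative receptor labeling.

#' Read an expression table
#'
#' TSV with a `gene_id` column followed by one numeric column per condition
#' or sample (FPKM; missing values allowed, negatives rejected).
#'
#' @param path path to the TSV.
#' @return data.frame with `gene_id` plus numeric columns.
#' @export
read_expression <- function(path) {
  df <- read_tsv(path)
  if (!"gene_id" %in% names(df))
    stopf("expression table %s lacks a gene_id column", path)
  num <- setdiff(names(df), "gene_id")
  for (cn in num) {
    v <- df[[cn]]
    if (any(v < 0, na.rm = TRUE))
      stopf("expression table %s: negative value in column %s", path, cn)
  }
  if (anyDuplicated(num)) stopf("duplicate column labels in %s", path)
  df
}

#' Genes with expression above a threshold
#'
#' Strict inequality: a gene at exactly the threshold is excluded (the
#' conventional "FPKM > 10" filter). Missing values never pass.
#'
#' @param table expression data.frame (see [read_expression()]).
#' @param column column label to filter on.
#' @param threshold FPKM cutoff, default 10.
#' @return character vector of gene ids with `value > threshold`.
#' @export
expression_filter <- function(table, column, threshold = 10) {
  if (!column %in% names(table))
    stopf("expression_filter: no column '%s'", column)
  v <- table[[column]]
  table$gene_id[!is.na(v) & v > threshold]
}

#' Fraction of a gene set expressed lower in condition B
#'
#' Counts genes whose expression in `col_b` is strictly below `col_a`
#' (ties are not "lower"; no fold-change or significance threshold is
#' applied). Genes absent from the table, or with a missing value in either
#' column, are skipped and counted.
#'
#' @param table expression data.frame.
#' @param col_a,col_b condition column labels (A = reference/epithelial).
#' @param gene_set character vector of gene ids to evaluate; defaults to
#'   all genes in the table.
#' @return list with `n_lower`, `n_total` (genes actually compared),
#'   `fraction` (`n_lower / n_total`), `n_skipped`.
#' @export
fraction_lower <- function(table, col_a, col_b, gene_set = NULL) {
  for (cn in c(col_a, col_b))
    if (!cn %in% names(table)) stopf("fraction_lower: no column '%s'", cn)
  if (is.null(gene_set)) gene_set <- table$gene_id
  gene_set <- unique(as.character(gene_set))
  idx <- match(gene_set, table$gene_id)
  a <- table[[col_a]][idx]
  b <- table[[col_b]][idx]
  ok <- !is.na(idx) & !is.na(a) & !is.na(b)
  n_total <- sum(ok)
  if (n_total == 0L)
    stopf("fraction_lower: no usable genes (all absent or missing)")
  n_lower <- sum(b[ok] < a[ok])
  list(n_lower = n_lower, n_total = n_total,
       fraction = n_lower / n_total, n_skipped = length(gene_set) - n_total)
}

#' Mann-Whitney U test (exact or normal approximation)
#'
#' `U` counts pairs with `x_i > y_j`, plus half a count per cross-sample
#' tie. Exact mode enumerates the null distribution of U over all
#' assignments of the pooled ranks (requires `|x| + |y| <= 20` and no
#' cross-sample ties; with ties it falls back to the approximation with a
#' warning); two-sided exact p is `min(1, 2 * min(P[U <= u], P[U >= u]))`.
#' The approximation uses the tie-corrected variance and a continuity
#' correction.
#'
#' @param x,y numeric samples (each non-empty).
#' @param mode `"auto"` (exact when permitted), `"exact"`, or
#'   `"normal_approx"`.
#' @return list with `U`, `p_value`, `method`.
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  x <- as.numeric(x[!is.na(x)]); y <- as.numeric(y[!is.na(y)])
  n <- length(x); m <- length(y)
  if (n < 1 || m < 1) stopf("mann_whitney_u: both samples must be non-empty")
  cmp <- outer(x, y, ">") + 0.5 * outer(x, y, "==")
  U <- sum(cmp)
  has_ties <- any(outer(x, y, "==")) ||
    anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  want_exact <- mode == "exact" || (mode == "auto" && n + m <= 20)
  if (want_exact && has_ties) {
    if (mode == "exact")
      warnf("mann_whitney_u: ties present, falling back to normal approximation")
    want_exact <- FALSE
  }
  if (want_exact && n + m > 20) {
    if (mode == "exact")
      stopf("mann_whitney_u: exact mode requires |x| + |y| <= 20")
    want_exact <- FALSE
  }
  if (want_exact) {
    counts <- mw_count_distribution(n, m)  # counts over U = 0..n*m
    total <- sum(counts)
    u <- round(U)
    p_le <- sum(counts[seq_len(u + 1)]) / total
    p_ge <- sum(counts[(u + 1):(n * m + 1)]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(U = U, p_value = p, method = "exact"))
  }
  pooled <- c(x, y)
  mu <- n * m / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties)
  v <- n * m / 12 * ((n + m + 1) - tie_term / ((n + m) * (n + m - 1)))
  if (v <= 0) return(list(U = U, p_value = 1, method = "normal_approx"))
  z <- (U - mu)
  z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(v)  # continuity correction
  list(U = U, p_value = 2 * pnorm(-abs(z)), method = "normal_approx")
}

# Null distribution of U for sample sizes (n, m) without ties: counts of
# rank assignments achieving each U in 0..n*m, via the classic recursion
# c(u; n, m) = c(u - m; n - 1, m) + c(u; n, m - 1).
mw_count_distribution <- function(n, m) {
  f <- vector("list", n + 1)
  for (i in 0:n) f[[i + 1]] <- vector("list", m + 1)
  rec <- function(ni, mi) {
    if (!is.null(f[[ni + 1]][[mi + 1]])) return(f[[ni + 1]][[mi + 1]])
    if (ni == 0 || mi == 0) {
      out <- 1  # single assignment, U = 0
    } else {
      a <- rec(ni - 1, mi)  # largest element from x: contributes mi... wait
      b <- rec(ni, mi - 1)
      out <- numeric(ni * mi + 1)
      # largest pooled element in x: adds m_i wins -> shift by mi
      out[(mi + 1):(ni * mi + 1)] <- a
      # largest pooled element in y: adds nothing
      out[seq_along(b)] <- out[seq_along(b)] + b
    }
    f[[ni + 1]][[mi + 1]] <<- out
    out
  }
  rec(n, m)
}

#' Welch's two-sided t-test with unequal variances
#'
#' @param x,y numeric samples with at least 2 values each.
#' @return list with `t`, `df` (Welch-Satterthwaite), `p_value`. When both
#'   samples have zero variance: `p = 1` for equal means, `p = 0` otherwise.
#' @export
welch_t_test <- function(x, y) {
  x <- as.numeric(x[!is.na(x)]); y <- as.numeric(y[!is.na(y)])
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stopf("welch_t_test: need >= 2 values per sample")
  v1 <- var(x); v2 <- var(y)
  md <- mean(x) - mean(y)
  if (v1 == 0 && v2 == 0) {
    if (md == 0) return(list(t = 0, df = n1 + n2 - 2, p_value = 1))
    return(list(t = sign(md) * Inf, df = n1 + n2 - 2, p_value = 0))
  }
  se2 <- v1 / n1 + v2 / n2
  t <- md / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p_value = 2 * pt(-abs(t), df))
}

#' Per-group expression difference summaries
#'
#' For each transition group, the per-gene FPKM difference
#' `d_g = value_b(g) - value_a(g)` is summarized by its mean and standard
#' error; group difference distributions are compared by Mann-Whitney
#' tests, either Group I versus each other group (default, matching the
#' usual presentation) or all pairs.
#'
#' @param table expression data.frame.
#' @param col_a,col_b condition column labels.
#' @param transition_table a `transition_table`.
#' @param pairing `"group_I_vs_rest"` or `"all_pairs"`.
#' @param mw_mode passed to [mann_whitney_u()].
#' @return list with `summary` (data.frame: `group`, `n_genes`, `n_lower`,
#'   `fraction_lower`, `mean_difference`, `sem_difference`, `tests_skipped`)
#'   and `pairwise_p` (data.frame: `group_a`, `group_b`, `p_value`).
#'   Genes missing from the expression table are skipped with a count.
#' @export
group_difference_summary <- function(table, col_a, col_b, transition_table,
                                     pairing = c("group_I_vs_rest",
                                                 "all_pairs"),
                                     mw_mode = "auto") {
  pairing <- match.arg(pairing)
  groups <- c("I", "II", "III", "IV")
  diffs <- lapply(groups, function(g) {
    ids <- group_members(transition_table, g)
    idx <- match(ids, table$gene_id)
    a <- table[[col_a]][idx]; b <- table[[col_b]][idx]
    ok <- !is.na(idx) & !is.na(a) & !is.na(b)
    list(d = b[ok] - a[ok], lower = sum(b[ok] < a[ok]),
         skipped = sum(!ok))
  })
  names(diffs) <- groups
  summary <- do.call(rbind, lapply(groups, function(g) {
    d <- diffs[[g]]$d
    n <- length(d)
    data.frame(group = g, n_genes = n, n_lower = diffs[[g]]$lower,
               fraction_lower = if (n) diffs[[g]]$lower / n else NA_real_,
               mean_difference = if (n) mean(d) else NA_real_,
               sem_difference = if (n >= 2) sd(d) / sqrt(n) else NA_real_,
               n_skipped = diffs[[g]]$skipped,
               tests_skipped = n < 2,
               stringsAsFactors = FALSE)
  }))
  pairs <- if (pairing == "group_I_vs_rest")
    list(c("I", "II"), c("I", "III"), c("I", "IV"))
  else combn(groups, 2, simplify = FALSE)
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    da <- diffs[[pr[1]]]$d; db <- diffs[[pr[2]]]$d
    p <- if (length(da) >= 2 && length(db) >= 2)
      mann_whitney_u(da, db, mode = mw_mode)$p_value else NA_real_
    data.frame(group_a = pr[1], group_b = pr[2], p_value = p,
               stringsAsFactors = FALSE)
  }))
  list(summary = summary, pairwise_p = pw)
}

#' Per-sample cumulative score of a gene set
#'
#' Aggregates each sample's expression over the gene set; sum (the default
#' "cumulative expression" reading) or mean.
#'
#' @param matrix expression data.frame: `gene_id` plus one column per
#'   sample.
#' @param gene_set character vector of gene ids; members absent from the
#'   matrix are dropped with a message (empty intersection is an error).
#' @param statistic `"sum"` or `"mean"`.
#' @return named numeric vector of per-sample scores.
#' @export
geneset_cumulative_score <- function(matrix, gene_set,
                                     statistic = c("sum", "mean")) {
  statistic <- match.arg(statistic)
  gene_set <- unique(as.character(gene_set))
  present <- intersect(gene_set, matrix$gene_id)
  if (length(present) == 0L)
    stopf("geneset_cumulative_score: no gene of the set is in the matrix")
  if (length(present) < length(gene_set))
    message(sprintf("geneset_cumulative_score: %d gene(s) missing from matrix",
                    length(gene_set) - length(present)))
  sub <- matrix[match(present, matrix$gene_id),
                setdiff(names(matrix), "gene_id"), drop = FALSE]
  fn <- if (statistic == "sum") colSums else colMeans
  fn(as.matrix(sub), na.rm = TRUE)
}

#' Triple-negative receptor-status label
#'
#' A sample is `TN` when ER, PR and HER2 are all definitively negative,
#' `NON_TN` when at least one is definitively positive, and `EXCLUDED`
#' otherwise (any indeterminate value without a positive).
#'
#' @param er,pr,her2 character vectors over
#'   `"positive"`, `"negative"`, `"indeterminate"` (recycled to a common
#'   length; unknown tokens are an error).
#' @return character vector over `"TN"`, `"NON_TN"`, `"EXCLUDED"`.
#' @export
#' @examples
#' tnbc_label("negative", "negative", "negative")  # "TN"
tnbc_label <- function(er, pr, her2) {
  n <- max(length(er), length(pr), length(her2))
  status <- cbind(rep_len(as.character(er), n),
                  rep_len(as.character(pr), n),
                  rep_len(as.character(her2), n))
  ok <- status %in% c("positive", "negative", "indeterminate")
  if (!all(ok))
    stopf("tnbc_label: unknown status token(s): %s",
          paste(unique(status[!ok]), collapse = ", "))
  any_pos <- rowSums(status == "positive") > 0
  all_neg <- rowSums(status == "negative") == 3
  ifelse(all_neg, "TN", ifelse(any_pos, "NON_TN", "EXCLUDED"))
}

#' Label a cohort metadata table
#'
#' @param metadata data.frame with columns `sample_id`, `ER`, `PR`, `HER2`.
#' @return the metadata with a `label` column added (see [tnbc_label()]).
#' @export
label_cohort <- function(metadata) {
  need <- c("sample_id", "ER", "PR", "HER2")
  if (!all(need %in% names(metadata)))
    stopf("cohort metadata needs columns: %s", paste(need, collapse = ", "))
  metadata$label <- tnbc_label(metadata$ER, metadata$PR, metadata$HER2)
  metadata
}
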