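# Term enrichment: two-list hypergeometric mode and ranked
# minimum-hypergeometric (mHG) mode with its exact permutation p-value,
# computed by the standard lattice-path dynamic programme.

#' Upper hypergeometric tail P[X >= k]
#'
#' Probability of drawing at least `k` marked elements when drawing `n`
#' elements without replacement from a universe of `N` containing `K`
#' marked ones. Accumulated in log space for numerical stability.
#'
#' @param k observed overlap (integer, `0 <= k <= min(n, K)`).
#' @param n target (draw) size.
#' @param K term (marked) size.
#' @param N universe size.
#' @return tail probability in `[0, 1]`.
#' @export
#' @examples
#' hypergeometric_tail(2, 2, 2, 4)  # 1/6
hypergeometric_tail <- function(k, n, K, N) {
  if (any(c(k, n, K, N) < 0) || k > min(n, K) || n > N || K > N)
    stopf("hypergeometric_tail: need 0 <= k <= min(n, K) <= N")
  if (k == 0) return(1)
  # log-space sum of dhyper over k..min(n, K)
  support <- k:min(n, K)
  lp <- dhyper(support, K, N - K, n, log = TRUE)
  mx <- max(lp)
  min(1, exp(mx) * sum(exp(lp - mx)))
}

#' Minimum hypergeometric (mHG) statistic of a ranked binary vector
#'
#' Scans every proper prefix of the ranked 0/1 label vector and returns the
#' minimum hypergeometric tail `P[X >= b_n]` over prefixes `n = 1..N-1`,
#' where `b_n` counts the ones in the top `n`. Ties take the smallest
#' prefix.
#'
#' @param labels binary (0/1 or logical) vector, ranked best-first.
#' @return list with `score` (the mHG statistic) and `threshold_rank`
#'   (the minimizing prefix length).
#' @export
#' @examples
#' mhg_statistic(c(1, 1, 0, 0))  # score 1/6 at rank 2
mhg_statistic <- function(labels) {
  labels <- as.integer(as.logical(labels))
  N <- length(labels)
  if (N < 1) stopf("mhg_statistic: empty label vector")
  B <- sum(labels)
  if (N == 1L) return(list(score = 1, threshold_rank = 1L))
  b <- cumsum(labels)[seq_len(N - 1L)]
  n <- seq_len(N - 1L)
  tails <- vapply(seq_along(n), function(i)
    hypergeometric_tail(b[i], n[i], B, N), numeric(1))
  # smallest n on ties; tolerate float noise between mathematically equal
  # tails computed from different prefixes
  best <- min(tails)
  i <- which(tails <= best + max(1e-12, best * 1e-9))[1]
  list(score = tails[i], threshold_rank = n[i])
}

#' Exact p-value of an mHG score
#'
#' Computes `P[mHG <= score]` under a uniform random permutation of `B`
#' ones among `N` labels, by the standard dynamic programme over the
#' `(n, b)` lattice: path probability mass is propagated only through cells
#' whose hypergeometric tail exceeds the score (cells at or below the score
#' form the rejection region), and the p-value is one minus the surviving
#' mass.
#'
#' @param score an mHG score in `(0, 1]` (see [mhg_statistic()]).
#' @param N number of labels.
#' @param B number of ones.
#' @return exact p-value in `[0, 1]`; always `>= score`.
#' @export
mhg_exact_pvalue <- function(score, N, B) {
  stopifnot(score > 0, score <= 1, B >= 0, B <= N, N >= 1)
  if (score >= 1) return(1)
  if (B == 0 || B == N) return(if (score >= 1) 1 else 0)
  tol <- score * (1 + 1e-9)
  # pi[b+1] = probability mass of label paths reaching (n, b) that have
  # avoided the rejection region so far.
  pi <- numeric(B + 1)
  pi[1] <- 1
  for (n in 1:N) {
    new <- numeric(B + 1)
    for (b in 0:min(n, B)) {
      # arrive at (n, b) from (n-1, b-1) via a one, or (n-1, b) via a zero
      mass <- 0
      if (b > 0 && pi[b] > 0)
        mass <- mass + pi[b] * (B - (b - 1)) / (N - (n - 1))
      if (b <= n - 1 && pi[b + 1] > 0)
        mass <- mass + pi[b + 1] * ((N - B) - (n - 1 - b)) / (N - (n - 1))
      if (mass == 0) next
      # rejection region: prefixes n = 1..N-1 whose tail <= score
      if (n < N && hypergeometric_tail(b, n, B, N) <= tol) next
      new[b + 1] <- mass
    }
    pi <- new
  }
  min(1, max(0, 1 - pi[B + 1]))
}

#' Read a GMT gene-set file
#'
#' GMT: one term per line, tab-separated: term id, description, members.
#'
#' @param path path to a `.gmt` file.
#' @return named list of terms; each element has `term_id`, `term_name`,
#'   `members` (unique character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  terms <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3L)
      stopf("GMT parse error: line with fewer than 3 fields in %s", path)
    list(term_id = f[[1]], term_name = f[[2]],
         members = unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  })
  stats::setNames(terms, vapply(terms, `[[`, "", "term_id"))
}

#' Write gene sets as GMT
#'
#' @param terms a named list as returned by [read_gmt()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gmt <- function(terms, path) {
  lines <- vapply(terms, function(t)
    paste(c(t$term_id, t$term_name, t$members), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Term enrichment for a gene set or a ranked gene list
#'
#' Two modes mirror the two common GO-server usages:
#' * `"two_list"` (default): `target` is an unordered gene set tested
#'   against the `universe` background; the p-value per term is the
#'   hypergeometric tail of the observed overlap.
#' * `"ranked_mHG"`: `target` is a *ranked* gene vector (best first,
#'   covering the universe); per term, the membership labels along the
#'   ranking give an mHG score whose exact permutation p-value is reported,
#'   together with the optimizing prefix length (`threshold_rank`).
#'
#' Terms with no overlap with the target (or, in ranked mode, no member in
#' the ranking) are omitted. Results carry the fold enrichment
#' `(k/n)/(K/N)` at the tested cutoff and a Bonferroni-adjusted p alongside
#' the raw (primary) p.
#'
#' @param target character vector: gene set (two-list) or full ranking
#'   (ranked mode).
#' @param universe character vector of background gene ids; the target must
#'   be a subset (two-list) or a permutation-subset (ranked).
#' @param terms named list of term annotations (see [read_gmt()]).
#' @param mode `"two_list"` or `"ranked_mHG"`.
#' @return data.frame sorted by ascending p with columns `term_id`,
#'   `term_name`, `overlap_count`, `expected_count`, `enrichment`,
#'   `p_value`, `p_bonferroni`, `mode`, `threshold_rank` (NA in two-list
#'   mode).
#' @export
enrich_terms <- function(target, universe, terms,
                         mode = c("two_list", "ranked_mHG")) {
  mode <- match.arg(mode)
  universe <- unique(as.character(universe))
  target <- as.character(target)
  if (length(target) == 0L) stopf("enrich_terms: empty target")
  if (!all(target %in% universe))
    stopf("enrich_terms: target contains genes outside the universe")
  N <- length(universe)
  rows <- lapply(terms, function(t) {
    members <- intersect(t$members, universe)
    K <- length(members)
    if (K == 0L) return(NULL)
    if (mode == "two_list") {
      tgt <- unique(target)
      n <- length(tgt)
      k <- length(intersect(tgt, members))
      if (k == 0L) return(NULL)
      p <- hypergeometric_tail(k, n, K, N)
      thr <- NA_integer_
    } else {
      if (anyDuplicated(target))
        stopf("enrich_terms: ranked mode needs a duplicate-free ranking")
      labels <- as.integer(target %in% members)
      if (sum(labels) == 0L) return(NULL)
      st <- mhg_statistic(labels)
      p <- mhg_exact_pvalue(st$score, length(labels), sum(labels))
      thr <- st$threshold_rank
      n <- thr
      k <- sum(labels[seq_len(thr)])
    }
    expected <- n * K / N
    data.frame(term_id = t$term_id, term_name = t$term_name,
               overlap_count = k, expected_count = expected,
               enrichment = (k / n) / (K / N), p_value = p,
               mode = mode, threshold_rank = thr,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L)
    return(data.frame(term_id = character(), term_name = character(),
                      overlap_count = integer(), expected_count = numeric(),
                      enrichment = numeric(), p_value = numeric(),
                      p_bonferroni = numeric(), mode = character(),
                      threshold_rank = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_value * nrow(out))
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("term_id", "term_name", "overlap_count", "expected_count",
          "enrichment", "p_value", "p_bonferroni", "mode", "threshold_rank")]
}
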