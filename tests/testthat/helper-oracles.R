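# Independent brute-force oracles. These deliberately avoid the package's
# code paths (and the stats convenience wrappers they use): contingency
# enumeration goes through choose(), interval overlap through a double
# loop, Mann-Whitney through explicit subset enumeration.

# --- interval / classifier oracles -----------------------------------------

# 1 bp-overlap test between one promoter and every peak, as a double loop.
oracle_mark_present <- function(prom_chrom, prom_start, prom_end, peaks) {
  hit <- FALSE
  if (nrow(peaks)) for (i in seq_len(nrow(peaks))) {
    if (peaks$chrom[i] == prom_chrom &&
        peaks$start[i] < prom_end && peaks$end[i] > prom_start) hit <- TRUE
  }
  hit
}

# Full reference classification: per gene, per mark, per condition, scan
# all peaks; then map states to groups by the published group semantics.
oracle_classify <- function(genes, peaks, cond_a, cond_b,
                            upstream = 2000, downstream = 2000) {
  out <- data.frame(gene_id = genes$gene_id,
                    state_a = NA_character_, state_b = NA_character_,
                    group = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(genes))) {
    if (genes$strand[i] == "+") {
      ws <- max(0, genes$tss[i] - upstream); we <- genes$tss[i] + downstream
    } else {
      ws <- max(0, genes$tss[i] - downstream + 1)
      we <- genes$tss[i] + upstream + 1
    }
    state_of <- function(cond) {
      k4 <- oracle_mark_present(genes$chrom[i], ws, we,
        peaks[peaks$mark == "H3K4me3" & peaks$condition == cond, ])
      k27 <- oracle_mark_present(genes$chrom[i], ws, we,
        peaks[peaks$mark == "H3K27me3" & peaks$condition == cond, ])
      if (k4 && k27) "BIVALENT" else if (k4) "K4_ONLY"
      else if (k27) "K27_ONLY" else "UNMARKED"
    }
    sa <- state_of(cond_a); sb <- state_of(cond_b)
    out$state_a[i] <- sa; out$state_b[i] <- sb
    out$group[i] <- if (sb != "BIVALENT") "NONE"
      else c(K4_ONLY = "I", K27_ONLY = "II",
             UNMARKED = "III", BIVALENT = "IV")[[sa]]
  }
  out
}

# Random classifier instance: <= n_genes genes on 2 chromosomes, <= n_peaks
# peaks scattered near and away from the promoters.
random_instance <- function(n_genes = 50, n_peaks = 200) {
  ng <- sample.int(n_genes, 1)
  genes <- data.frame(
    gene_id = sprintf("g%03d", seq_len(ng)),
    symbol = sprintf("g%03d", seq_len(ng)),
    chrom = sample(c("chr1", "chr2"), ng, replace = TRUE),
    strand = sample(c("+", "-"), ng, replace = TRUE),
    tss = sample.int(200000, ng), stringsAsFactors = FALSE)
  genes$start <- pmax(0L, genes$tss - 500L); genes$end <- genes$tss + 500L
  np <- sample(4:n_peaks, 1)
  start <- sample.int(220000, np)
  # force all four mark x condition collections to be represented so the
  # instance is a legal classifier input
  mark <- c("H3K4me3", "H3K27me3", "H3K4me3", "H3K27me3",
            sample(c("H3K4me3", "H3K27me3"), np - 4, replace = TRUE))
  condition <- c("A", "A", "B", "B",
                 sample(c("A", "B"), np - 4, replace = TRUE))
  peaks <- data.frame(
    chrom = sample(c("chr1", "chr2"), np, replace = TRUE),
    start = start, end = start + sample.int(3000, np),
    mark = mark, condition = condition,
    score = NA_real_, stringsAsFactors = FALSE)
  list(genes = genes, peaks = peaks)
}

# --- exact-test oracles -----------------------------------------------------

# choose()-based hypergeometric point mass (independent of dhyper).
oracle_hyper_pmf <- function(x, N, K, n) {
  choose(K, x) * choose(N - K, n - x) / choose(N, n)
}

oracle_hypergeom_tail <- function(k, n, K, N) {
  if (k == 0) return(1)
  sum(oracle_hyper_pmf(k:min(n, K), N, K, n))
}

# Two-sided Fisher p by explicit enumeration of all tables sharing the
# observed margins, minimum-likelihood rule.
oracle_fisher <- function(a, b, c_, d) {
  r1 <- a + b; c1 <- a + c_; N <- a + b + c_ + d
  if (r1 == 0 || c1 == 0 || r1 == N || c1 == N) return(1)
  support <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- oracle_hyper_pmf(support, N, c1, r1)
  p_obs <- probs[support == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# mHG statistic by exhaustive prefix scan on the oracle tail.
oracle_mhg_stat <- function(labels) {
  N <- length(labels); B <- sum(labels)
  if (N == 1) return(list(score = 1, threshold_rank = 1L))
  best <- Inf; rank <- 1L
  b <- 0
  for (n in 1:(N - 1)) {
    b <- b + labels[n]
    tail <- oracle_hypergeom_tail(b, n, B, N)
    if (tail < best - 1e-15) { best <- tail; rank <- n }
  }
  list(score = best, threshold_rank = rank)
}

# Exhaustive mHG null distribution: P[mHG <= s] over all C(N, B) label
# placements (used for small N alongside the Monte-Carlo oracle).
oracle_mhg_pvalue_exhaustive <- function(s, N, B) {
  combos <- combn(N, B)
  hits <- 0
  for (j in seq_len(ncol(combos))) {
    lab <- integer(N); lab[combos[, j]] <- 1L
    if (oracle_mhg_stat(lab)$score <= s * (1 + 1e-9)) hits <- hits + 1
  }
  hits / ncol(combos)
}

# Exact two-sided Mann-Whitney p by enumeration of all assignments of the
# pooled observations to the x-sample.
oracle_mw_p <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  u_obs <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  combos <- combn(n + m, n)
  us <- apply(combos, 2, function(idx) {
    xs <- pooled[idx]; ys <- pooled[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  })
  p_le <- mean(us <= u_obs + 1e-9)
  p_ge <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# --- small fixture builders -------------------------------------------------

make_peaks <- function(chrom, start, end, mark, condition) {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             mark = mark, condition = condition,
             score = rep(NA_real_, length(chrom)),
             stringsAsFactors = FALSE)
}

make_genes <- function(tss, strand = "+", chrom = "chr1") {
  n <- length(tss)
  data.frame(gene_id = sprintf("g%02d", seq_len(n)),
             symbol = sprintf("g%02d", seq_len(n)),
             chrom = rep_len(chrom, n),
             start = pmax(0L, as.integer(tss) - 100L),
             end = as.integer(tss) + 100L,
             strand = rep_len(strand, n), tss = as.integer(tss),
             stringsAsFactors = FALSE)
}
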