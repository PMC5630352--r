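test_that("the FPKM filter is strictly greater-than", {
  tab <- data.frame(gene_id = c("a", "b", "c", "d"),
                    vector = c(10, 10.1, NA, 50))
  expect_equal(expression_filter(tab, "vector"), c("b", "d"))
  expect_equal(expression_filter(tab, "vector", threshold = 49), "d")
  expect_error(expression_filter(tab, "nope"), "no column")
})

test_that("fraction_lower counts strict decreases only", {
  # the worked 256-of-369 fixture
  n <- 369; k <- 256
  tab <- data.frame(gene_id = sprintf("g%03d", 1:n),
                    a = rep(10, n),
                    b = c(rep(5, k), rep(15, n - k)))
  res <- fraction_lower(tab, "a", "b")
  expect_equal(res$n_lower, k)
  expect_equal(res$n_total, n)
  expect_equal(res$fraction, 256 / 369)
  # ties are not lower
  tied <- data.frame(gene_id = c("x", "y"), a = c(3, 3), b = c(3, 3))
  expect_equal(fraction_lower(tied, "a", "b")$fraction, 0)
  # absent and missing genes are skipped with a count
  res2 <- fraction_lower(tab, "a", "b", c("g001", "g300", "absent"))
  expect_equal(res2$n_total, 2L)
  expect_equal(res2$n_skipped, 1L)
  expect_error(fraction_lower(tab, "a", "b", "absent"), "no usable")
})

test_that("fraction_lower equals a brute-force count and ignores gene order", {
  set.seed(79)
  tab <- data.frame(gene_id = sprintf("g%02d", 1:60),
                    a = rlnorm(60, 2), b = rlnorm(60, 2))
  res <- fraction_lower(tab, "a", "b")
  manual <- 0
  for (i in 1:60) if (tab$b[i] < tab$a[i]) manual <- manual + 1
  expect_equal(res$n_lower, manual)
  shuffled <- fraction_lower(tab, "a", "b", sample(tab$gene_id))
  expect_equal(shuffled$fraction, res$fraction)
  expect_true(res$fraction >= 0 && res$fraction <= 1)
})

test_that("Mann-Whitney U and exact p follow the enumeration oracle", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 2 / choose(6, 3) * 1)  # both tails of the extreme
  expect_equal(mann_whitney_u(1, 1)$U, 0.5)       # tie convention
  set.seed(83)
  for (i in 1:40) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    x <- sample(seq(1, 100), n); y <- sample(seq(101, 200), m) - 100.5
    r <- mann_whitney_u(x, y, mode = "exact")
    expect_equal(r$method, "exact")
    expect_equal(r$p_value, oracle_mw_p(x, y), tolerance = 1e-12)
    # U_x + U_y = n*m
    ryx <- mann_whitney_u(y, x, mode = "exact")
    expect_equal(r$U + ryx$U, n * m)
    expect_equal(r$p_value, ryx$p_value, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney p is invariant under monotone transformation", {
  set.seed(89)
  x <- rnorm(8); y <- rnorm(10, 0.5)
  p1 <- mann_whitney_u(x, y)$p_value
  p2 <- mann_whitney_u(exp(x), exp(y))$p_value
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("Mann-Whitney falls back on ties and large samples", {
  expect_warning(r <- mann_whitney_u(c(1, 2, 2), c(2, 3), mode = "exact"),
                 "ties")
  expect_equal(r$method, "normal_approx")
  big <- mann_whitney_u(rnorm(30), rnorm(30))
  expect_equal(big$method, "normal_approx")
  expect_error(mann_whitney_u(numeric(), 1), "non-empty")
})

test_that("Welch t-test matches the textbook formula and edge conventions", {
  x <- c(1.1, 2.3, 3.7, 2.2); y <- c(4.0, 5.5, 4.8)
  r <- welch_t_test(x, y)
  v1 <- var(x) / 4; v2 <- var(y) / 3
  t_manual <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df_manual <- (v1 + v2)^2 / (v1^2 / 3 + v2^2 / 2)
  expect_equal(r$t, t_manual)
  expect_equal(r$df, df_manual)
  expect_equal(r$p_value, 2 * pt(-abs(t_manual), df_manual))
  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_equal(welch_t_test(c(2, 2), c(2, 2))$p_value, 1)
  expect_equal(welch_t_test(c(2, 2), c(3, 3))$p_value, 0)
})

test_that("Welch p decreases monotonically with the shift", {
  x <- c(1, 2, 3)
  shifts <- c(0.5, 1, 2, 4, 8)
  ps <- vapply(shifts, function(s) welch_t_test(x, x + s)$p_value, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("Welch agrees with pooled t on balanced equal-variance samples", {
  set.seed(97)
  for (i in 1:10) {
    x <- rnorm(12); y <- rnorm(12, 0.3)
    r <- welch_t_test(x, y)
    sp2 <- (var(x) + var(y)) / 2
    t_pooled <- (mean(x) - mean(y)) / sqrt(sp2 * (2 / 12))
    expect_equal(r$t, t_pooled, tolerance = 1e-10)
  }
})

test_that("group summaries carry means, SEMs and Mann-Whitney pairs", {
  spec <- synthetic_spec(n_genes = 800, seed = 41)
  ds <- generate_dataset(spec)
  tt <- classify_transitions(ds$annotation, ds$peaks, "vector", "twist")
  gds <- group_difference_summary(ds$expression, "vector", "twist", tt)
  s <- gds$summary
  # planted repression: Group I mean difference negative and dominant
  expect_true(s$mean_difference[s$group == "I"] < 0)
  expect_true(abs(s$mean_difference[s$group == "I"]) >
                max(s$mean_difference[s$group != "I"]))
  # SEM recomputed from the records
  g1 <- group_members(tt, "I")
  idx <- match(g1, ds$expression$gene_id)
  d <- ds$expression$twist[idx] - ds$expression$vector[idx]
  expect_equal(s$mean_difference[s$group == "I"], mean(d))
  expect_equal(s$sem_difference[s$group == "I"], sd(d) / sqrt(length(d)))
  expect_equal(nrow(gds$pairwise_p), 3L)  # I vs II, III, IV by default
  all_pairs <- group_difference_summary(ds$expression, "vector", "twist",
                                        tt, pairing = "all_pairs")
  expect_equal(nrow(all_pairs$pairwise_p), 6L)
})

test_that("identical condition columns give zero differences and p = 1", {
  spec <- synthetic_spec(n_genes = 300, seed = 43)
  ds <- generate_dataset(spec)
  tt <- classify_transitions(ds$annotation, ds$peaks, "vector", "twist")
  tab <- ds$expression
  tab$twist <- tab$vector
  gds <- group_difference_summary(tab, "vector", "twist", tt)
  expect_true(all(gds$summary$mean_difference[gds$summary$n_genes > 0] == 0))
  expect_true(all(gds$pairwise_p$p_value[!is.na(gds$pairwise_p$p_value)] == 1))
})

test_that("gene-set cumulative scores aggregate per sample", {
  mat <- data.frame(gene_id = c("a", "b", "c"),
                    s1 = c(3, 4, 100), s2 = c(1, 2, 100))
  expect_equal(geneset_cumulative_score(mat, c("a", "b"), "sum"),
               c(s1 = 7, s2 = 3))
  expect_equal(geneset_cumulative_score(mat, c("a", "b"), "mean"),
               c(s1 = 3.5, s2 = 1.5))
  expect_message(geneset_cumulative_score(mat, c("a", "zz")), "missing")
  expect_error(geneset_cumulative_score(mat, "zz"), "no gene")
  # equals a loop aggregation on random data
  set.seed(101)
  big <- cbind(data.frame(gene_id = sprintf("g%02d", 1:30)),
               as.data.frame(matrix(rlnorm(30 * 5), 30, 5,
                                    dimnames = list(NULL, paste0("s", 1:5)))))
  gs <- sprintf("g%02d", sample(30, 12))
  got <- geneset_cumulative_score(big, gs, "sum")
  for (smp in paste0("s", 1:5)) {
    tot <- 0
    for (g in gs) tot <- tot + big[[smp]][big$gene_id == g]
    expect_equal(got[[smp]], tot)
  }
})

test_that("triple-negative labeling follows the receptor rule", {
  expect_equal(tnbc_label("negative", "negative", "negative"), "TN")
  expect_equal(tnbc_label("positive", "negative", "negative"), "NON_TN")
  expect_equal(tnbc_label("negative", "indeterminate", "positive"), "NON_TN")
  expect_equal(tnbc_label("indeterminate", "negative", "negative"),
               "EXCLUDED")
  expect_equal(
    tnbc_label(c("negative", "positive"), "negative", "negative"),
    c("TN", "NON_TN"))
  expect_error(tnbc_label("neg", "negative", "negative"), "unknown status")
})
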