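test_that("comparative Ct arithmetic", {
  expect_equal(delta_delta_ct(20, 20, 20, 20), 1.0)  # ddCt = 0
  expect_equal(delta_delta_ct(25, 20, 24, 20), 0.5)  # ddCt = +1
  expect_equal(delta_delta_ct(22, 20, 25, 20), 8)    # ddCt = -3
  expect_error(delta_delta_ct(NA, 20, 24, 20), "finite")
})

test_that("ddCt of a condition against itself is exactly 1", {
  set.seed(103)
  for (i in 1:20) {
    ct_t <- runif(1, 15, 35); ct_r <- runif(1, 15, 35)
    expect_identical(delta_delta_ct(ct_t, ct_r, ct_t, ct_r), 1)
  }
})

test_that("qpcr_fold_changes chains replicate means through the formula", {
  ct <- rbind(
    data.frame(target = "GAPDH", sample = rep(c("ctrl", "cond"), each = 3),
               replicate = rep(1:3, 2), ct = c(20.1, 20.0, 19.9,
                                               20.2, 20.0, 19.8)),
    data.frame(target = "CDH1", sample = rep(c("ctrl", "cond"), each = 3),
               replicate = rep(1:3, 2), ct = c(24.0, 24.2, 24.1,
                                               26.0, 26.1, 25.9)))
  res <- qpcr_fold_changes(ct, "GAPDH", "cond", "ctrl")
  d_cond <- mean(c(26.0, 26.1, 25.9)) - mean(c(20.2, 20.0, 19.8))
  d_ctrl <- mean(c(24.0, 24.2, 24.1)) - mean(c(20.1, 20.0, 19.9))
  expect_equal(res$fold_change, 2^-(d_cond - d_ctrl))
  expect_error(qpcr_fold_changes(ct, "ACTB", "cond", "ctrl"), "reference")
})

test_that("Holm-Sidak step-down formula with monotonicity and capping", {
  expect_equal(holm_sidak_adjust(0.03), 0.03)
  adj <- holm_sidak_adjust(c(0.01, 0.04))
  expect_equal(adj, c(1 - 0.99^2, max(1 - 0.99^2, 0.04)))
  expect_equal(holm_sidak_adjust(c(0, 0, 0)), c(0, 0, 0))
  expect_equal(holm_sidak_adjust(rep(1, 4)), rep(1, 4))
  # hand-computed step-down for an unsorted vector
  p <- c(0.2, 0.01, 0.05)
  adj <- holm_sidak_adjust(p)
  s <- sort(p)
  expected_sorted <- cummax(pmin(1, 1 - (1 - s)^(3:1)))
  expect_equal(adj[order(p)], expected_sorted)
  expect_error(holm_sidak_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Holm-Sidak adjusted values never fall below the raw ones", {
  set.seed(107)
  for (i in 1:25) {
    p <- runif(sample.int(8, 1))
    adj <- holm_sidak_adjust(p)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    # order of significance is preserved
    expect_equal(order(adj[order(p)]), seq_along(p))
  }
})

test_that("the three-criterion reactivation call covers all 8 combinations", {
  for (down in c(TRUE, FALSE)) for (up in c(TRUE, FALSE))
    for (block in c(TRUE, FALSE)) {
      p <- ifelse(c(down, up, block), 0.001, 0.5)
      fold <- c(if (down) 0.4 else 1.1, if (up) 2.5 else 0.9,
                if (block) 0.5 else 1.2)
      call <- met_reactivation_call(p, fold)
      expect_equal(call$down_in_emt, down)
      expect_equal(call$up_in_met, up)
      expect_equal(call$blocked_by_inhibitor, block)
      expect_equal(call$full_pattern, down && up && block)
    }
  # significant but wrong-direction change is "No"
  call <- met_reactivation_call(c(0.001, 0.001, 0.001), c(2, 2, 2))
  expect_false(call$down_in_emt)
  expect_true(call$up_in_met)
  expect_false(call$full_pattern)
  expect_error(met_reactivation_call(c(0.1, 0.2), c(1, 1)), "length 3")
})

test_that("percent input adjusts the input Ct for the input fraction", {
  expect_equal(percent_input(20, 20, 1), 100)
  expect_equal(percent_input(20 + 3.321928, 20, 1), 10, tolerance = 1e-5)
  # 1% input shifts the adjusted input Ct by log2(100) cycles
  expect_equal(percent_input(20, 20 + log2(100), 0.01), 100)
  # doubling the input fraction shifts the adjusted Ct by exactly 1 cycle
  f <- 0.02
  expect_equal(percent_input(25, 20, 2 * f) / percent_input(25, 20, f), 2)
  expect_error(percent_input(20, 20, 0), "input_fraction")
})

test_that("H3 normalization subtracts IgG and floors negatives", {
  expect_equal(h3_normalized_enrichment(8, 8, 0)$value, 1.0)
  r0 <- h3_normalized_enrichment(0.5, 8, 0.5)
  expect_equal(r0$value, 0)
  expect_false(r0$floored)
  rn <- h3_normalized_enrichment(0.2, 8, 0.5)
  expect_equal(rn$value, 0)
  expect_true(rn$floored)
  r <- h3_normalized_enrichment(3.5, 9, 0.5)
  expect_equal(r$value, (3.5 - 0.5) / (9 - 0.5))
  expect_error(h3_normalized_enrichment(3, 0.4, 0.5), "exceed")
  # subtract-after mode
  r2 <- h3_normalized_enrichment(3.5, 9, 0.5, mode = "subtract_after")
  expect_equal(r2$value, 3.5 / 9 - 0.5 / 9)
})

test_that("fold enrichment is a plain condition ratio", {
  expect_equal(fold_enrichment(2.4, 1.0), 2.4)
  expect_equal(fold_enrichment(7, 7), 1.0)
  expect_warning(expect_true(is.na(fold_enrichment(1, 0))), "undefined")
})

test_that("reactivation table recovers planted patterns exactly at zero noise", {
  # all 8 pattern combinations, planted via independent per-comparison folds
  patterns <- expand.grid(down_in_emt = c(TRUE, FALSE),
                          up_in_met = c(TRUE, FALSE),
                          blocked_by_inhibitor = c(TRUE, FALSE))
  patterns$target <- sprintf("P%d", seq_len(nrow(patterns)))
  patterns$group <- rep(c("I", "II"), length.out = nrow(patterns))
  spec <- synthetic_spec(ct_noise_sd = 0, seed = 11)
  ct <- generate_ct_tables(spec, patterns = patterns)
  res <- met_reactivation_table(ct$rtpcr, ct$comparisons, ct$reference_gene,
                                truth = patterns[, c("target", "group")])
  m <- merge(res$calls, patterns, by = c("target", "group"))
  expect_equal(m$down_in_emt.x, m$down_in_emt.y)
  expect_equal(m$up_in_met.x, m$up_in_met.y)
  expect_equal(m$blocked_by_inhibitor.x, m$blocked_by_inhibitor.y)
  expect_equal(m$full_pattern,
               m$down_in_emt.y & m$up_in_met.y & m$blocked_by_inhibitor.y)
})

test_that("reactivation counts match the planted panel at zero noise", {
  spec <- synthetic_spec(ct_noise_sd = 0, seed = 13)
  ct <- generate_ct_tables(spec)
  res <- met_reactivation_table(ct$rtpcr, ct$comparisons, ct$reference_gene,
                                truth = ct$patterns[, c("target", "group")])
  planted <- ct$patterns
  for (g in c("I", "II", "III", "IV")) {
    pg <- planted[planted$group == g, ]
    expect_equal(unname(res$counts[g, "down_in_emt"]), sum(pg$down_in_emt))
    expect_equal(unname(res$counts[g, "up_in_met"]), sum(pg$up_in_met))
    expect_equal(unname(res$counts[g, "blocked_by_inhibitor"]),
                 sum(pg$blocked_by_inhibitor))
    expect_equal(unname(res$counts[g, "full_pattern"]),
                 sum(pg$down_in_emt & pg$up_in_met &
                       pg$blocked_by_inhibitor))
  }
  # the default panel plants the 9-of-10 Group I pattern
  expect_equal(unname(res$counts["I", c("n", "down_in_emt", "up_in_met",
                                        "full_pattern")]),
               c(22, 15, 10, 9))
})

test_that("genes missing a comparison are excluded with a message", {
  spec <- synthetic_spec(ct_noise_sd = 0, seed = 17)
  ct <- generate_ct_tables(spec)
  broken <- ct$rtpcr[!(ct$rtpcr$target == "I_g01" &
                         ct$rtpcr$sample == "tgfb"), ]
  expect_message(
    res <- met_reactivation_table(broken, ct$comparisons,
                                  ct$reference_gene), "excluded.*I_g01")
  expect_false("I_g01" %in% res$calls$target)
})
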