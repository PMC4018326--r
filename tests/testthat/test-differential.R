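test_that("roll-up sums peptides per protein and conserves intensity", {
  mat <- tibble::tibble(peptide = c("A", "B", "C", "D"),
                        accession = c("P1", "P1", "P1", "P2"),
                        S1 = c(100, 200, 300, 10),
                        S2 = c(NA, 50, 60, NA))
  pq <- rollup(mat)
  expect_equal(pq$intensity[pq$accession == "P1" & pq$sample_id == "S1"], 600)
  expect_equal(pq$n_peptides[pq$accession == "P1" & pq$sample_id == "S2"], 2L)
  # P2 absent in S2: missing row, not a zero
  expect_equal(nrow(pq[pq$accession == "P2", ]), 1)
  expect_equal(sum(pq$intensity), sum(c(mat$S1, mat$S2), na.rm = TRUE))
})

test_that("duplicate runs average to subject level", {
  samples <- tibble::tibble(
    sample_id = c("ACL_M3", "ACL_M3_r2", "ACL_F1"),
    tissue = "ACL", sex = c("M", "M", "F"), donor = c(3L, 3L, 1L),
    replicate = c(1L, 2L, 1L), injected_mass_ug = 3, spike_fmol_per_ug = 25)
  pq <- tibble::tibble(accession = c("P1", "P1", "P1", "P2"),
                       sample_id = c("ACL_M3", "ACL_M3_r2", "ACL_F1",
                                     "ACL_M3"),
                       intensity = c(600, 800, 500, 42), n_peptides = 3L)
  avg <- average_duplicates(pq, samples)
  expect_equal(avg$quant$intensity[avg$quant$accession == "P1" &
                                     avg$quant$sample_id == "ACL_M3"], 700)
  # protein seen in only one of the two runs keeps its present value
  expect_equal(avg$quant$intensity[avg$quant$accession == "P2"], 42)
  expect_equal(nrow(avg$samples), 2)
  expect_equal(avg$samples$n_runs[avg$samples$sample_id == "ACL_M3"], 2L)
  # without duplicates the matrix passes through unchanged
  avg1 <- average_duplicates(pq[pq$sample_id != "ACL_M3_r2", ],
                             samples[samples$replicate == 1, ])
  expect_setequal(avg1$quant$intensity, c(600, 500, 42))
})

test_that("signed fold change uses the -1/r convention below one", {
  expect_equal(signed_fold_change(2, 1), 2)
  expect_equal(signed_fold_change(1, 5), -5)
  expect_equal(signed_fold_change(3, 3), 1)
  expect_true(is.na(signed_fold_change(0, 3)))
  expect_true(is.na(signed_fold_change(3, 0)))
})

test_that("unit-weight ANOVA equals the textbook decomposition", {
  set.seed(77)
  for (i in 1:5) {
    g <- rep(c("a", "b", "c"), times = c(4, 3, 5))
    y <- stats::rnorm(length(g), mean = as.integer(factor(g)) * 0.3)
    # independent oracle: explicit sums of squares and the F distribution
    gm <- tapply(y, g, mean); gn <- tapply(y, g, length)
    ss_b <- sum(gn * (gm - mean(y))^2)
    ss_w <- sum((y - gm[g])^2)
    df_b <- length(gm) - 1; df_w <- length(y) - length(gm)
    f_stat <- (ss_b / df_b) / (ss_w / df_w)
    p_oracle <- stats::pf(f_stat, df_b, df_w, lower.tail = FALSE)
    expect_equal(error_weighted_anova(y, g), p_oracle, tolerance = 1e-10)
  }
})

test_that("degenerate and undersized ANOVA inputs are handled", {
  expect_equal(error_weighted_anova(c(1, 1, 2, 2), c("a", "a", "b", "b")),
               .Machine$double.xmin, ignore_attr = TRUE)
  expect_equal(error_weighted_anova(c(5, 5, 5, 5), c("a", "a", "b", "b")),
               1, ignore_attr = TRUE)
  expect_true(is.na(error_weighted_anova(c(1, 2, 3), c("a", "a", "b"))))
  # equal group means and spreads: F = 0, p = 1
  expect_equal(error_weighted_anova(c(1, 3, 1, 3), c("a", "a", "b", "b")), 1)
})

test_that("weights change the ANOVA and match a weighted-lm oracle", {
  set.seed(5)
  y <- stats::rnorm(12); g <- rep(c("a", "b"), each = 6)
  w <- stats::runif(12, 0.5, 2)
  p_w <- error_weighted_anova(y, g, w)
  p_u <- error_weighted_anova(y, g)
  oracle <- stats::anova(stats::lm(y ~ g, weights = w))[["Pr(>F)"]][1]
  expect_equal(p_w, oracle, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(p_w, p_u)))
})

test_that("BH adjustment matches the hand-applied step-up rule", {
  expect_equal(bh_adjust(0.03), 0.03)
  # step-up: p_(i) * n / i, cumulative minimum from the largest rank
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  p <- c(0.005, 0.011, 0.02, 0.04, 0.1)
  hand <- rev(cummin(rev(p * 5 / seq_len(5))))
  expect_equal(bh_adjust(p), hand)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # Hochberg option: step-up on (n - i + 1) multipliers
  hand_h <- rev(cummin(rev(p * (5 - seq_len(5) + 1))))
  expect_equal(bh_adjust(p, method = "hochberg"), pmin(1, hand_h))
  # monotone in the ranked raw values
  adj <- bh_adjust(p)
  expect_true(all(diff(adj[order(p)]) >= 0))
})

test_that("Cohen's d matches its pooled-SD definition", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cohens_d(c(1, 2, 3), c(3, 4, 5)), -2)
  expect_equal(cohens_d(c(9, 9, 9), c(1, 1, 1)), Inf)
  expect_equal(cohens_d(c(1, 1, 1), c(9, 9, 9)), -Inf)
  expect_true(is.na(cohens_d(1, c(1, 2))))
})

test_that("curation applies all three criteria jointly", {
  res <- tibble::tibble(
    accession = c("A", "B", "C", "D"),
    n_peptides = c(3L, 1L, 3L, 3L),
    p_adj = c(0.01, 0.01, 0.04, 0.2),
    cohen_d = c(2, 2, 0.5, 3))
  kept <- curate(res)
  expect_equal(kept$accession, "A")   # B: 1 peptide; C: small d; D: large p
  expect_equal(nrow(curate(res[0, ])), 0)
})

test_that("differential analysis recovers programmed effects exactly at sigma 0", {
  sim <- simulate_dataset(panel = small_panel(sex_fc_acl = c(2, -3, 1, 1)),
                          tissues = "ACL", sigma = 0, dropout_rate = 0,
                          decoy_rate = 0, seed = 13)
  pq <- rollup(merge_fractions(sim$records))
  diff <- differential_abundance(pq, sim$samples)
  expect_s3_class(diff, "tendon_diff")
  fc <- setNames(diff$fold_change, diff$accession)
  expect_equal(fc[["PROT1_TEST"]], 2, tolerance = 1e-12)
  expect_equal(fc[["PROT2_TEST"]], -3, tolerance = 1e-12)
  expect_equal(fc[["PROT3_TEST"]], 1, tolerance = 1e-12)
  # no-noise groups are degenerate: programmed effects hit the p floor
  expect_true(all(diff$p_adj[diff$accession %in%
                               c("PROT1_TEST", "PROT2_TEST")] < 1e-10))
  expect_true(all(diff$curated == (abs(fc[diff$accession]) > 1)))
  # tidy/glance interface
  td <- tidy(diff)
  expect_true(all(c("estimate", "p.value", "adj.p.value") %in% names(td)))
  gl <- glance(diff)
  expect_equal(gl$n_curated, 2L)
})

test_that("the duplicate-run error curve downweights noisy intensities", {
  sim <- simulate_dataset(panel = small_panel(), tissues = "ACL",
                          sigma = 0.25, dropout_rate = 0, decoy_rate = 0,
                          seed = 17)
  pq <- rollup(merge_fractions(sim$records))
  curve <- fit_error_curve(pq, sim$samples, min_points = 3)
  expect_true(is.function(curve))
  v <- curve(c(10, 15, 20))
  expect_true(all(v > 0))
  # no duplicate runs: no curve, unit-weight fallback
  sim1 <- simulate_dataset(panel = small_panel(), tissues = "ACL",
                           duplicate_subject = NULL, sigma = 0.25,
                           dropout_rate = 0, decoy_rate = 0, seed = 17)
  pq1 <- rollup(merge_fractions(sim1$records))
  expect_null(fit_error_curve(pq1, sim1$samples))
})
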