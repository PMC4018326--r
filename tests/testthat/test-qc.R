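test_that("FDR thresholding returns the most permissive passing threshold", {
  # 2 decoys slip above a block of targets: estimated FDR 2/100 = 2%
  rec <- tibble::tibble(
    score = c(seq(10, 5.05, length.out = 100), 6, 5.5, 4, 3),
    is_decoy = c(rep(FALSE, 100), TRUE, TRUE, TRUE, TRUE))
  thr <- peptide_fdr_threshold(rec, target_fdr_pct = 2)
  expect_equal(thr$fdr_pct, 2)
  expect_equal(thr$n_target, 100L)
  expect_equal(thr$n_decoy, 2L)
  expect_lte(thr$threshold, 5.05)
  # tighter target forces a higher threshold with fewer decoys
  thr1 <- peptide_fdr_threshold(rec, target_fdr_pct = 1)
  expect_gt(thr1$threshold, thr$threshold)
  expect_lte(thr1$fdr_pct, 1)
})

test_that("FDR estimator is monotone non-increasing in the threshold", {
  s <- simulate_scores(400, 200, separation = 2, seed = 21)
  grid <- seq(min(s$score), max(s$score), length.out = 50)
  est <- vapply(grid, function(t) {
    nt <- sum(s$score >= t & !s$is_decoy)
    nd <- sum(s$score >= t & s$is_decoy)
    if (nt == 0) NA_real_ else nd / nt
  }, numeric(1))
  est <- est[!is.na(est)]
  # overall trend: higher threshold, lower estimated FDR (allow flat runs)
  expect_true(all(diff(cummin(est)) <= 0))
  expect_lt(est[length(est)], est[1])
})

test_that("no identifications is a result, not an error", {
  rec <- tibble::tibble(score = c(1, 2, 3), is_decoy = c(TRUE, TRUE, FALSE))
  thr <- peptide_fdr_threshold(rec, target_fdr_pct = 0.5)
  # decoy above the only target at every admissible threshold except the top
  expect_true(is.finite(thr$threshold) || thr$n_target == 0)
  empty <- peptide_fdr_threshold(rec[rec$is_decoy, ], 2)
  expect_equal(empty$n_target, 0L)
  expect_true(is.infinite(empty$threshold))
})

test_that("surrogate RSD matches its hand oracle", {
  pq <- tibble::tibble(accession = "ADH1_YEAST",
                       sample_id = c("a", "b", "c"),
                       intensity = c(90, 100, 110))
  expect_equal(surrogate_rsd(pq), 10)
  pq$intensity <- c(100, 100, 100)
  expect_equal(surrogate_rsd(pq), 0)
  expect_error(surrogate_rsd(pq, standard = "ALBU_HUMAN"), "absent")
})

test_that("fraction uniqueness counts distinct peptides once", {
  rec <- tibble::tibble(
    sample_id = "S", peptide = c("A", "A", "B", "C", "D"),
    accession = "P", fraction = c(1L, 2L, 3L, 3L, 4L),
    intensity = 1)
  expect_equal(fraction_uniqueness(rec), 75)   # 3 of 4 in one fraction
  rec1 <- rec[rec$peptide != "A", ]
  expect_equal(fraction_uniqueness(rec1), 100)
  expect_true(is.na(fraction_uniqueness(rec[0, ])))
})

test_that("per-fraction load tallies conserve the totals", {
  expect_equal(per_fraction_load(tiny_records()[0, ], 3)$n_peptides,
               c(0L, 0L, 0L))
  one <- tibble::tibble(sample_id = "S", peptide = "A", accession = "P",
                        fraction = 5L, intensity = 7)
  tab <- per_fraction_load(one)
  expect_equal(tab$total_intensity[5], 7)
  expect_equal(tab$n_peptides[5], 1L)
  rec <- tiny_records()
  tab <- per_fraction_load(rec)
  expect_equal(sum(tab$total_intensity), sum(rec$intensity))
})

test_that("PCA places duplicate runs at identical coordinates", {
  sim <- quick_sim(seed = 8, sigma = 0.2)
  mat <- merge_fractions(sim$records)
  dup <- mat
  dup$Acopy <- dup[[3]]           # duplicate the first run column verbatim
  p <- pca_scores(dup)
  i <- match(names(dup)[3], p$scores$sample_id)
  j <- match("Acopy", p$scores$sample_id)
  expect_equal(unlist(p$scores[i, -1]), unlist(p$scores[j, -1]),
               tolerance = 1e-8)
})

test_that("PCA is invariant to row and column order up to the sign fix", {
  sim <- quick_sim(seed = 8, sigma = 0.2)
  mat <- merge_fractions(sim$records)
  p1 <- pca_scores(mat)
  set.seed(1)
  mat2 <- mat[sample(nrow(mat)), c(1, 2, sample(3:ncol(mat)))]
  p2 <- pca_scores(mat2)
  s1 <- p1$scores[order(p1$scores$sample_id), ]
  s2 <- p2$scores[order(p2$scores$sample_id), ]
  expect_equal(as.data.frame(s1), as.data.frame(s2), tolerance = 1e-8)
})

test_that("a dominant tissue effect separates tissues on component 1", {
  panel <- small_panel(conc_acl = c(50, 20, 10, 5),
                       conc_pt = c(10, 40, 30, 2))
  sim <- simulate_dataset(panel = panel, tissues = c("ACL", "PT"),
                          sigma = 0.15, dropout_rate = 0, decoy_rate = 0,
                          seed = 31)
  p <- pca_scores(merge_fractions(sim$records))
  sc <- dplyr::inner_join(p$scores, sim$samples, by = "sample_id")
  acl <- sc$PC1[sc$tissue == "ACL"]; pt <- sc$PC1[sc$tissue == "PT"]
  gap <- abs(mean(acl) - mean(pt))
  spread <- max(stats::sd(acl), stats::sd(pt))
  expect_gt(gap, spread)
})

test_that("qc_report assembles all panels", {
  sim <- simulate_dataset(panel = small_panel(), tissues = "ACL",
                          sigma = 0.2, dropout_rate = 0.02,
                          decoy_rate = 0.3, seed = 6)
  qc <- qc_report(sim$records)
  expect_s3_class(qc, "tendon_qc")
  expect_gt(qc$surrogate_rsd_pct, 0)
  expect_true(qc$pct_single_fraction > 50)
  expect_equal(nrow(qc$pca$scores), nrow(sim$samples))
  expect_lte(qc$fdr$fdr_pct, 2)
})
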