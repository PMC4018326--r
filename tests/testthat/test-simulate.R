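test_that("identical config and seed reproduce the dataset exactly", {
  a <- simulate_dataset(panel = small_panel(), tissues = "ACL",
                        sigma = 0.3, dropout_rate = 0.1, decoy_rate = 0.3,
                        seed = 11)
  b <- simulate_dataset(panel = small_panel(), tissues = "ACL",
                        sigma = 0.3, dropout_rate = 0.1, decoy_rate = 0.3,
                        seed = 11)
  expect_identical(a$records, b$records)
  expect_identical(a$samples, b$samples)
  expect_identical(a$truth$proteins, b$truth$proteins)
  c <- simulate_dataset(panel = small_panel(), tissues = "ACL",
                        sigma = 0.3, dropout_rate = 0.1, decoy_rate = 0.3,
                        seed = 12)
  expect_false(identical(a$records$intensity, c$records$intensity))
})

test_that("noise-free totals are proportional to true concentrations", {
  sim <- quick_sim(seed = 5)
  pq <- rollup(merge_fractions(sim$records))
  truth <- sim$truth$proteins |>
    dplyr::filter(.data$tissue == "ACL") |>
    dplyr::inner_join(sim$samples, by = c("tissue", "sex"),
                      relationship = "many-to-many")
  cmp <- dplyr::inner_join(pq, truth, by = c("accession", "sample_id"))
  # constant = sum(efficiency) x mass x scale, fixed per protein across samples
  ratio <- cmp$intensity / cmp$conc_fmol_ug
  by_prot <- split(ratio, cmp$accession)
  for (r in by_prot) expect_lt(diff(range(r)) / mean(r), 1e-12)
})

test_that("a programmed 2-fold sex effect is exact at sigma 0", {
  sim <- quick_sim(seed = 2, sex_fc_acl = c(2, 1, 1, 1))
  pq <- rollup(merge_fractions(sim$records))
  avg <- average_duplicates(pq, sim$samples)
  dat <- dplyr::inner_join(avg$quant, avg$samples, by = "sample_id")
  fc <- dat |>
    dplyr::group_by(.data$accession) |>
    dplyr::summarise(fc = mean(.data$intensity[.data$sex == "M"]) /
                       mean(.data$intensity[.data$sex == "F"]))
  expect_equal(fc$fc[fc$accession == "PROT1_TEST"], 2, tolerance = 1e-12)
  expect_equal(fc$fc[fc$accession == "PROT2_TEST"], 1, tolerance = 1e-12)
})

test_that("fraction assignment is deterministic with a split minority", {
  sim <- simulate_dataset(panel = small_panel(), tissues = "ACL",
                          sigma = 0, dropout_rate = 0, decoy_rate = 0,
                          multi_fraction_rate = 0.3, seed = 1)
  rec <- sim$records
  per_pep <- rec |>
    dplyr::distinct(.data$peptide, .data$accession, .data$fraction) |>
    dplyr::count(.data$peptide, .data$accession)
  expect_true(all(per_pep$n <= 2))
  # split peptides land on adjacent fractions and keep their total intensity
  truth <- sim$truth$peptides
  split_rows <- truth[truth$split, ]
  expect_gt(nrow(split_rows), 0)
  one <- rec |>
    dplyr::filter(.data$peptide == split_rows$peptide[1],
                  .data$accession == split_rows$accession[1],
                  .data$sample_id == rec$sample_id[1])
  expect_equal(nrow(one), 2)
  expect_equal(one$intensity[1] / sum(one$intensity), 0.6, tolerance = 1e-12)
  # rate 0 puts every peptide in exactly one fraction
  sim0 <- simulate_dataset(panel = small_panel(), tissues = "ACL",
                           sigma = 0, dropout_rate = 0, decoy_rate = 0,
                           multi_fraction_rate = 0, seed = 1)
  expect_equal(fraction_uniqueness(sim0$records), 100)
})

test_that("score simulation is seeded and separates targets from decoys", {
  s <- simulate_scores(100, 50, separation = 3, seed = 9)
  expect_equal(sum(!s$is_decoy), 100)
  expect_equal(sum(s$is_decoy), 50)
  expect_identical(s, simulate_scores(100, 50, separation = 3, seed = 9))
  expect_gt(mean(s$score[!s$is_decoy]), mean(s$score[s$is_decoy]))
  expect_error(simulate_scores(-1, 5), "non-negative")
  # no decoys: FDR is zero at any threshold
  s0 <- simulate_scores(10, 0, seed = 1)
  thr <- peptide_fdr_threshold(s0, 2)
  expect_equal(thr$fdr_pct, 0)
  expect_equal(thr$n_target, 10L)
})

test_that("the RNG state of the session is not disturbed", {
  set.seed(123)
  before <- .Random.seed
  invisible(quick_sim(seed = 4))
  invisible(simulate_scores(10, 10, seed = 4))
  expect_identical(.Random.seed, before)
})
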