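#' Decoy-based peptide FDR thresholding
#'
#' Estimates the false discovery rate among peptide identifications from
#' reversed-sequence decoy matches. The estimator is the simple target-decoy
#' ratio `n_decoy_passing / n_target_passing` at a score threshold; the
#' function returns the lowest (most permissive) threshold whose estimated
#' FDR is at or below `target_fdr_pct`.
#'
#' @param records Tibble with `score` and `is_decoy` columns (one row per
#'   scored identification).
#' @param target_fdr_pct Target FDR in percent (default 2).
#' @return One-row tibble: `threshold`, `fdr_pct` (estimated FDR at that
#'   threshold), `n_target`, `n_decoy`. If no threshold admits any target
#'   identification at the requested FDR, `threshold` is `Inf` and the
#'   counts are zero ("no identifications", not an error).
#' @export
peptide_fdr_threshold <- function(records, target_fdr_pct = 2) {
  stopifnot(all(c("score", "is_decoy") %in% names(records)),
            target_fdr_pct >= 0)
  records <- dplyr::filter(records, !is.na(.data$score))
  if (nrow(records) == 0 || !any(!records$is_decoy)) {
    return(tibble::tibble(threshold = Inf, fdr_pct = NA_real_,
                          n_target = 0L, n_decoy = 0L))
  }
  ord <- order(records$score, decreasing = TRUE)
  decoy <- records$is_decoy[ord]
  score <- records$score[ord]
  n_target <- cumsum(!decoy)
  n_decoy <- cumsum(decoy)
  fdr <- ifelse(n_target > 0, n_decoy / n_target, Inf)
  # evaluate at distinct scores only (threshold = accept score >= s)
  last_of_score <- !duplicated(score, fromLast = TRUE)
  ok <- which(last_of_score & fdr * 100 <= target_fdr_pct)
  if (length(ok) == 0) {
    return(tibble::tibble(threshold = Inf, fdr_pct = NA_real_,
                          n_target = 0L, n_decoy = 0L))
  }
  i <- max(ok)   # lowest score threshold still meeting the target
  tibble::tibble(threshold = score[i], fdr_pct = 100 * fdr[i],
                 n_target = n_target[i], n_decoy = n_decoy[i])
}

#' Filter peptide records at a target FDR
#'
#' Applies [peptide_fdr_threshold()] and keeps records (targets and decoys)
#' with scores at or above the chosen threshold. Records without a score
#' column pass unfiltered.
#'
#' @inheritParams peptide_fdr_threshold
#' @return Filtered records with attribute `fdr` (the threshold tibble).
#' @export
apply_fdr_filter <- function(records, target_fdr_pct = 2) {
  if (!"score" %in% names(records)) return(records)
  thr <- peptide_fdr_threshold(records, target_fdr_pct)
  out <- dplyr::filter(records, .data$score >= thr$threshold)
  attr(out, "fdr") <- thr
  out
}

#' Relative standard deviation of the surrogate standard
#'
#' Protein-level precision of the label-free quantitation: 100 x sd / mean of
#' the spiked standard's summed intensity across analytical runs (duplicate
#' runs kept separate; sample standard deviation, n - 1 denominator).
#'
#' @param protein_quant Long protein quantification tibble from [rollup()]
#'   (columns `accession`, `sample_id`, `intensity`).
#' @param standard Accession of the spiked standard (default `ADH1_YEAST`).
#' @return RSD in percent.
#' @export
surrogate_rsd <- function(protein_quant, standard = "ADH1_YEAST") {
  x <- dplyr::filter(protein_quant, .data$accession == standard)
  if (nrow(x) == 0) {
    stop("surrogate standard ", standard, " absent from the quantification",
         call. = FALSE)
  }
  100 * stats::sd(x$intensity) / mean(x$intensity)
}

#' Percentage of peptides confined to a single LC fraction
#'
#' The 2D-LC fractionation quality metric: of the distinct (peptide,
#' accession) pairs observed, the percentage seen in exactly one fraction
#' (in any sample).
#'
#' @param records Peptide records with a `fraction` column.
#' @return Percent of distinct peptides that are fraction-unique, or `NA`
#'   for empty input.
#' @export
fraction_uniqueness <- function(records) {
  if (nrow(records) == 0) return(NA_real_)
  stopifnot("fraction" %in% names(records))
  per_pep <- records |>
    dplyr::distinct(.data$peptide, .data$accession, .data$fraction) |>
    dplyr::count(.data$peptide, .data$accession)
  100 * mean(per_pep$n == 1)
}

#' Per-fraction peptide count and total ion intensity
#'
#' Tally of distinct peptides and summed intensity in each LC/LC fraction,
#' zero-filled for fractions with no observations.
#'
#' @param records Peptide records with `fraction` and `intensity`.
#' @param n_fractions Total number of fractions (default: the maximum seen).
#' @return Tibble with `fraction`, `n_peptides`, `total_intensity`.
#' @export
per_fraction_load <- function(records, n_fractions = NULL) {
  if (is.null(n_fractions)) {
    n_fractions <- if (nrow(records) > 0) max(records$fraction) else 0L
  }
  frame <- tibble::tibble(fraction = seq_len(n_fractions))
  if (nrow(records) == 0) {
    return(dplyr::mutate(frame, n_peptides = 0L, total_intensity = 0))
  }
  tally <- records |>
    dplyr::group_by(.data$fraction) |>
    dplyr::summarise(
      n_peptides = dplyr::n_distinct(.data$peptide, .data$accession),
      total_intensity = sum(.data$intensity), .groups = "drop")
  frame |>
    dplyr::left_join(tally, by = "fraction") |>
    tidyr::replace_na(list(n_peptides = 0L, total_intensity = 0))
}

#' Principal components of the peptide-level quantitative data
#'
#' Each peptide row is z-scored (mean 0, sd 1) across analytical runs and the
#' run-space decomposition of the resulting matrix is returned, the standard
#' visual check that biological variability (tissue, sex) exceeds platform
#' variability (duplicate runs should land on top of each other). Missing
#' cells are imputed with the peptide's row mean before z-scoring (so they
#' carry no signal); zero-variance peptides are dropped and counted.
#' Component signs are fixed so each component's largest-magnitude peptide
#' loading is positive.
#'
#' @param peptide_matrix Wide peptide matrix from [merge_fractions()]
#'   (columns `peptide`, `accession`, then one column per run).
#' @param n_components Number of components to keep (default 3).
#' @return Object of class `tendon_pca`: list with `scores` (tibble,
#'   one row per run: `sample_id`, `PC1..PCk`), `explained_variance`
#'   (proportions), `n_dropped` (zero-variance peptides removed).
#' @export
pca_scores <- function(peptide_matrix, n_components = 3) {
  value_cols <- setdiff(names(peptide_matrix), c("peptide", "accession"))
  if (length(value_cols) < 2) {
    stop("PCA needs at least two analytical runs", call. = FALSE)
  }
  x <- as.matrix(peptide_matrix[, value_cols])
  row_mean <- rowMeans(x, na.rm = TRUE)
  idx <- which(is.na(x), arr.ind = TRUE)
  if (nrow(idx) > 0) x[idx] <- row_mean[idx[, 1]]
  row_sd <- apply(x, 1, stats::sd)
  keep <- !is.na(row_sd) & row_sd > 0
  n_dropped <- sum(!keep)
  x <- x[keep, , drop = FALSE]
  if (nrow(x) == 0) stop("no peptides with non-zero variance", call. = FALSE)
  z <- (x - rowMeans(x)) / apply(x, 1, stats::sd)
  n_components <- min(n_components, ncol(z), nrow(z))
  dec <- stats::prcomp(t(z), center = FALSE, scale. = FALSE)
  load <- dec$rotation[, seq_len(n_components), drop = FALSE]
  scores <- dec$x[, seq_len(n_components), drop = FALSE]
  flip <- vapply(seq_len(n_components), function(j) {
    sign(load[which.max(abs(load[, j])), j])
  }, numeric(1))
  scores <- sweep(scores, 2, flip, `*`)
  ev <- dec$sdev^2 / sum(dec$sdev^2)
  structure(list(
    scores = dplyr::bind_cols(tibble::tibble(sample_id = value_cols),
                              tibble::as_tibble(scores)),
    explained_variance = ev[seq_len(n_components)],
    n_dropped = n_dropped
  ), class = "tendon_pca")
}

#' @export
print.tendon_pca <- function(x, ...) {
  cat(sprintf("PCA of %d analytical runs (%d zero-variance peptides dropped)\n",
              nrow(x$scores), x$n_dropped))
  cat("explained variance:",
      paste0(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", "),
      "\n")
  print(x$scores, ...)
  invisible(x)
}

#' Assemble a dataset-level quality-control report
#'
#' Bundles the dataset-level QC quantities: surrogate-standard RSD, peptide
#' fraction uniqueness, per-fraction load, realized peptide FDR at the
#' requested threshold, and run-level PCA.
#'
#' @param records Peptide records (pre-FDR-filter, with scores and decoys).
#' @param target_fdr_pct FDR target in percent (default 2).
#' @param standard Spiked standard accession.
#' @param n_fractions Number of fractions for the load table.
#' @return List of class `tendon_qc`: `surrogate_rsd_pct`,
#'   `pct_single_fraction`, `fraction_load`, `fdr`, `pca`.
#' @export
qc_report <- function(records, target_fdr_pct = 2, standard = "ADH1_YEAST",
                      n_fractions = NULL) {
  filtered <- apply_fdr_filter(records, target_fdr_pct)
  fdr <- attr(filtered, "fdr") %||%
    tibble::tibble(threshold = -Inf, fdr_pct = 0, n_target = nrow(filtered),
                   n_decoy = 0L)
  targets <- dplyr::filter(filtered, !.data$is_decoy)
  pepmat <- merge_fractions(targets)
  pq <- rollup(pepmat)
  structure(list(
    surrogate_rsd_pct = if (standard %in% pq$accession) {
      surrogate_rsd(pq, standard)
    } else NA_real_,
    pct_single_fraction = if ("fraction" %in% names(targets)) {
      fraction_uniqueness(targets)
    } else NA_real_,
    fraction_load = if ("fraction" %in% names(targets)) {
      per_fraction_load(targets, n_fractions)
    } else NULL,
    fdr = fdr,
    pca = pca_scores(pepmat)
  ), class = "tendon_qc")
}

#' @export
print.tendon_qc <- function(x, ...) {
  cat("QC report\n")
  cat(sprintf("  surrogate RSD: %.1f%%\n", x$surrogate_rsd_pct))
  cat(sprintf("  fraction-unique peptides: %.1f%%\n", x$pct_single_fraction))
  cat(sprintf("  peptide FDR: %.2f%% (%d targets, %d decoys at threshold %.2f)\n",
              x$fdr$fdr_pct, x$fdr$n_target, x$fdr$n_decoy, x$fdr$threshold))
  invisible(x)
}
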