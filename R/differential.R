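#' Roll peptides up to protein-level intensities
#'
#' Sums, per protein and analytical run, the intensities of all observed
#' peptides assigned to that protein. Missing peptide cells contribute
#' nothing; a protein with no observed peptides at all in a run yields no
#' row for that run (missing, not zero). Roll-up conserves total intensity.
#'
#' @param peptide_matrix Wide peptide matrix from [merge_fractions()].
#' @return Long tibble: `accession`, `sample_id`, `intensity`,
#'   `n_peptides` (peptides contributing in that run).
#' @export
rollup <- function(peptide_matrix) {
  value_cols <- setdiff(names(peptide_matrix), c("peptide", "accession"))
  peptide_matrix |>
    tidyr::pivot_longer(dplyr::all_of(value_cols), names_to = "sample_id",
                        values_to = "intensity") |>
    dplyr::filter(!is.na(.data$intensity)) |>
    dplyr::group_by(.data$accession, .data$sample_id) |>
    dplyr::summarise(intensity = sum(.data$intensity),
                     n_peptides = dplyr::n(), .groups = "drop")
}

#' Average duplicate analytical runs to subject level
#'
#' The one sample per tissue analyzed twice is collapsed to its subject by
#' arithmetic mean of the run-level summed intensities; if a protein was
#' observed in only one of the runs, the present value is used. Subject ids
#' are `<tissue>_<sex><donor>`.
#'
#' @param protein_quant Long tibble from [rollup()].
#' @param samples Run-level metadata (see [read_sample_meta()]).
#' @return List with `quant` (long tibble keyed by `sample_id` = subject id)
#'   and `samples` (subject-level metadata, one row per subject).
#' @export
average_duplicates <- function(protein_quant, samples) {
  map <- dplyr::mutate(samples,
                       subject_id = paste0(.data$tissue, "_", .data$sex,
                                           .data$donor))
  n_runs <- dplyr::count(map, .data$subject_id)
  if (any(n_runs$n > 2)) {
    warning("subject(s) with more than 2 runs are averaged over all runs")
  }
  quant <- protein_quant |>
    dplyr::inner_join(dplyr::select(map, "sample_id", "subject_id"),
                      by = "sample_id") |>
    dplyr::group_by(.data$accession, sample_id = .data$subject_id) |>
    dplyr::summarise(intensity = mean(.data$intensity),
                     n_peptides = max(.data$n_peptides), .groups = "drop")
  subj <- map |>
    dplyr::group_by(sample_id = .data$subject_id) |>
    dplyr::summarise(tissue = .data$tissue[1], sex = .data$sex[1],
                     donor = .data$donor[1], n_runs = dplyr::n(),
                     injected_mass_ug = .data$injected_mass_ug[1],
                     spike_fmol_per_ug = .data$spike_fmol_per_ug[1],
                     .groups = "drop")
  list(quant = quant, samples = subj)
}

#' Signed fold change
#'
#' Ratio of linear-scale means reported in the signed convention: `r` when
#' `r >= 1`, `-1/r` otherwise, so a two-fold depletion prints as -2 rather
#' than 0.5. Undefined (zero or missing mean) gives `NA`.
#'
#' @param mean_num,mean_den Linear-scale group means (vectorized).
#' @return Signed fold change(s), `|fc| >= 1`.
#' @export
#' @examples
#' signed_fold_change(2, 1)    # +2
#' signed_fold_change(1, 5)    # -5
signed_fold_change <- function(mean_num, mean_den) {
  r <- mean_num / mean_den
  out <- ifelse(r >= 1, r, -1 / r)
  out[!is.finite(r) | mean_num <= 0 | mean_den <= 0] <- NA_real_
  out
}

#' Error-weighted one-way ANOVA on log2 intensities
#'
#' Fixed-effects one-way ANOVA with per-observation inverse-variance
#' weights, fitted via weighted least squares. With unit weights this is
#' exactly the textbook one-way ANOVA. Degenerate inputs (zero residual
#' variance) return the machine-precision floor when group means differ and
#' 1 when they do not, flagged via the `"degenerate"` attribute.
#'
#' @param values Numeric observations (log2 intensities).
#' @param groups Factor or character group labels (>= 2 groups with >= 2
#'   observations each; otherwise `NA` is returned).
#' @param weights Optional positive per-observation weights (default unit).
#' @return Raw p-value.
#' @export
error_weighted_anova <- function(values, groups, weights = NULL) {
  groups <- as.factor(as.character(groups))
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(groups[keep])
  if (is.null(weights)) weights <- rep(1, length(values)) else weights <- weights[keep]
  stopifnot(all(weights > 0))
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2)) return(NA_real_)
  if (all(tapply(values, groups, function(v) diff(range(v))) == 0)) {
    # zero within-group variance everywhere: the F-test is undefined
    gm <- tapply(values, groups, mean)
    p <- if (max(gm) - min(gm) > 0) .Machine$double.xmin else 1
    attr(p, "degenerate") <- TRUE
    return(p)
  }
  fit <- stats::lm(values ~ groups, weights = weights)
  an <- suppressWarnings(stats::anova(fit))
  p <- an[["Pr(>F)"]][1]
  if (is.na(p)) p <- 1
  p
}

#' Fit an intensity-dependent technical-variance curve from duplicate runs
#'
#' Uses the protein-level intensities of subjects analyzed twice: for every
#' protein present in both runs of a duplicate pair, half the squared log2
#' run difference estimates the technical variance at that protein's mean
#' log2 intensity. The (mean, variance) points are smoothed with
#' [stats::lowess()] to give a variance curve; observations are then
#' weighted by the inverse of the predicted variance. Returns `NULL` (unit
#' weights downstream) when there are no duplicate pairs or too few points.
#'
#' @param protein_quant Long tibble from [rollup()] (run-level, duplicates
#'   not yet averaged).
#' @param samples Run-level metadata.
#' @param min_points Minimum duplicate-pair proteins to attempt a fit.
#' @return A function mapping log2 intensity to predicted variance, or
#'   `NULL`.
#' @export
fit_error_curve <- function(protein_quant, samples, min_points = 10) {
  map <- dplyr::mutate(samples, subject_id = paste0(.data$tissue, "_",
                                                    .data$sex, .data$donor))
  dup_subjects <- map |>
    dplyr::count(.data$subject_id) |>
    dplyr::filter(.data$n >= 2)
  if (nrow(dup_subjects) == 0) return(NULL)
  pts <- protein_quant |>
    dplyr::inner_join(dplyr::select(map, "sample_id", "subject_id"),
                      by = "sample_id") |>
    dplyr::filter(.data$subject_id %in% dup_subjects$subject_id) |>
    dplyr::group_by(.data$accession, .data$subject_id) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::summarise(m = mean(log2(.data$intensity)),
                     v = stats::var(log2(.data$intensity)),
                     .groups = "drop")
  if (nrow(pts) < min_points) return(NULL)
  sm <- stats::lowess(pts$m, pts$v, f = 2 / 3)
  floor_v <- max(1e-6, stats::quantile(pts$v[pts$v > 0], 0.05, names = FALSE,
                                       na.rm = TRUE))
  function(log2_intensity) {
    v <- stats::approx(sm$x, sm$y, xout = log2_intensity, rule = 2)$y
    pmax(v, floor_v)
  }
}

#' Adjust p-values for multiple testing
#'
#' Step-up Benjamini-Hochberg FDR adjustment (default) or Hochberg's
#' step-up FWER procedure, with monotonicity enforced and values capped at
#' one.
#'
#' @param p Numeric p-values in `[0, 1]` (`NA` allowed and preserved).
#' @param method `"BH"` (default) or `"hochberg"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p, method = c("BH", "hochberg")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = method)
}

#' Cohen's d effect size
#'
#' Standardized mean difference `(mean_a - mean_b) / s_pooled` with the
#' pooled standard deviation
#' `sqrt(((n_a-1) s_a^2 + (n_b-1) s_b^2) / (n_a + n_b - 2))`. Identical
#' groups give 0; unequal means with zero pooled SD give a signed-infinity
#' sentinel.
#'
#' @param group_a,group_b Numeric observations (log2 intensities; the sign
#'   follows `a - b`).
#' @return Effect size.
#' @export
cohens_d <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  n_a <- length(group_a); n_b <- length(group_b)
  if (n_a < 2 || n_b < 2) return(NA_real_)
  diff <- mean(group_a) - mean(group_b)
  pooled <- sqrt(((n_a - 1) * stats::var(group_a) +
                    (n_b - 1) * stats::var(group_b)) / (n_a + n_b - 2))
  if (pooled == 0) {
    return(if (diff == 0) 0 else sign(diff) * Inf)
  }
  diff / pooled
}

#' Male-versus-female differential protein abundance within tissue
#'
#' The relative-quantitation arm of the pipeline: subject-level summed
#' protein intensities (duplicate runs averaged) are compared between male
#' and female donors within each tissue. Per protein: signed fold change
#' M/F from linear-scale group means, error-weighted ANOVA p-value on log2
#' intensities (weights from the duplicate-run variance curve when
#' available, unit weights otherwise), Benjamini-Hochberg adjustment within
#' each tissue's protein list, Cohen's d on the log2 scale, and the
#' curation verdict (`> 1` peptide, adjusted p below `alpha`, `|d|` above
#' `min_d`).
#'
#' @param protein_quant Long run-level tibble from [rollup()].
#' @param samples Run-level metadata.
#' @param weights `"auto"` (duplicate-run error curve, falling back to unit
#'   weights) or `"unit"`.
#' @param p_adjust Multiplicity adjustment, `"BH"` (default) or
#'   `"hochberg"`.
#' @param min_peptides,alpha,min_d Curation thresholds (defaults 2, 0.05,
#'   0.8).
#' @return Tibble of class `tendon_diff`: `tissue`, `accession`,
#'   `n_peptides`, group means on log2 scale, `fold_change` (signed M/F),
#'   `p_raw`, `p_adj`, `cohen_d`, `curated`.
#' @export
differential_abundance <- function(protein_quant, samples,
                                   weights = c("auto", "unit"),
                                   p_adjust = c("BH", "hochberg"),
                                   min_peptides = 2, alpha = 0.05,
                                   min_d = 0.8) {
  weights <- match.arg(weights)
  p_adjust <- match.arg(p_adjust)
  var_curve <- if (weights == "auto") {
    fit_error_curve(protein_quant, samples)
  } else NULL
  avg <- average_duplicates(protein_quant, samples)
  dat <- dplyr::inner_join(avg$quant,
                           dplyr::select(avg$samples, "sample_id", "tissue",
                                         "sex"),
                           by = "sample_id")
  res <- dat |>
    dplyr::group_by(.data$tissue, .data$accession) |>
    dplyr::group_modify(function(d, key) {
      l2 <- log2(d$intensity)
      w <- if (!is.null(var_curve)) 1 / var_curve(l2) else NULL
      m <- d$intensity[d$sex == "M"]
      f <- d$intensity[d$sex == "F"]
      tibble::tibble(
        n_peptides = max(d$n_peptides),
        n_male = length(m), n_female = length(f),
        mean_log2_male = if (length(m)) mean(log2(m)) else NA_real_,
        mean_log2_female = if (length(f)) mean(log2(f)) else NA_real_,
        fold_change = if (length(m) && length(f)) {
          signed_fold_change(mean(m), mean(f))
        } else NA_real_,
        p_raw = error_weighted_anova(l2, d$sex, w),
        cohen_d = cohens_d(log2(m), log2(f))
      )
    }) |>
    dplyr::ungroup()
  res <- res |>
    dplyr::group_by(.data$tissue) |>
    dplyr::mutate(p_adj = bh_adjust(.data$p_raw, method = p_adjust)) |>
    dplyr::ungroup() |>
    dplyr::mutate(curated = !is.na(.data$p_adj) &
                    .data$n_peptides >= min_peptides &
                    .data$p_adj < alpha &
                    !is.na(.data$cohen_d) & abs(.data$cohen_d) > min_d) |>
    dplyr::relocate("p_adj", .after = "p_raw") |>
    dplyr::arrange(.data$tissue, .data$p_adj, .data$accession)
  class(res) <- c("tendon_diff", class(res))
  attr(res, "thresholds") <- list(min_peptides = min_peptides, alpha = alpha,
                                  min_d = min_d, p_adjust = p_adjust,
                                  weights = weights,
                                  error_curve = !is.null(var_curve))
  res
}

#' Curate a differential result to the reporting subset
#'
#' Applies the three-part curation rule: more than one peptide observed,
#' adjusted ANOVA p-value below `alpha`, and `|Cohen's d|` above `min_d`.
#'
#' @param results A [differential_abundance()] result (or any tibble with
#'   `n_peptides`, `p_adj`, `cohen_d`).
#' @param min_peptides Minimum peptide count (default 2, i.e. "> 1").
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param min_d Minimum absolute effect size (default 0.8, a "large"
#'   effect).
#' @return The curated subset, same columns.
#' @export
curate <- function(results, min_peptides = 2, alpha = 0.05, min_d = 0.8) {
  dplyr::filter(results,
                .data$n_peptides >= min_peptides,
                !is.na(.data$p_adj) & .data$p_adj < alpha,
                !is.na(.data$cohen_d) & abs(.data$cohen_d) > min_d)
}
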