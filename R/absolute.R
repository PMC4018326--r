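#' Select the top-k "best flier" peptides per protein
#'
#' For each protein the k peptides with the highest mean intensity across
#' the dataset's samples are chosen once per dataset, so every sample of
#' that dataset is quantified on the same peptide set. The ranking mean is
#' taken on within-run-normalized intensities (each run scaled by its total
#' signal), which makes the choice — and hence the whole calibrated
#' quantification — invariant to a global rescaling of any run. Proteins with
#' exactly two peptides are quantified on both (recorded in
#' `n_peptides_used`); proteins with fewer than two peptides are excluded
#' and counted in the `"n_excluded"` attribute. Rank ties are broken by
#' lexicographically smallest peptide sequence.
#'
#' @param peptide_matrix Wide peptide matrix from [merge_fractions()].
#' @param k Number of peptides (default 3).
#' @return Tibble `accession`, `peptide`, `rank`, `mean_intensity`, with
#'   attribute `n_excluded`.
#' @export
select_top_peptides <- function(peptide_matrix, k = 3) {
  value_cols <- setdiff(names(peptide_matrix), c("peptide", "accession"))
  x <- as.matrix(peptide_matrix[, value_cols])
  # normalize each run to its total signal so ranking is scale-invariant
  totals <- colSums(x, na.rm = TRUE)
  xn <- sweep(x, 2, ifelse(totals > 0, totals, 1), `/`)
  means <- peptide_matrix |>
    dplyr::mutate(mean_intensity = rowMeans(xn, na.rm = TRUE)) |>
    dplyr::select("accession", "peptide", "mean_intensity")
  n_pep <- dplyr::count(means, .data$accession)
  excluded <- n_pep$accession[n_pep$n < 2]
  out <- means |>
    dplyr::filter(!.data$accession %in% excluded) |>
    dplyr::arrange(.data$accession, dplyr::desc(.data$mean_intensity),
                   .data$peptide) |>
    dplyr::group_by(.data$accession) |>
    dplyr::slice_head(n = k) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
  attr(out, "n_excluded") <- length(excluded)
  out
}

#' Per-sample response factor from the spiked surrogate standard
#'
#' The standard's known on-column amount is
#' `spike_fmol_per_ug x injected_mass_ug` (75 fmol at the defaults of
#' 25 fmol/ug and 3 ug); the response factor is its top-3 mean intensity
#' divided by that amount, in intensity counts per fmol. Samples in which
#' the standard was not quantified are dropped with a warning and are
#' excluded from absolute quantification.
#'
#' @param standard_top3 Tibble `sample_id`, `top3_intensity` for the
#'   standard.
#' @param samples Sample metadata carrying `spike_fmol_per_ug` and
#'   `injected_mass_ug`.
#' @return Tibble `sample_id`, `known_fmol`, `response` (counts per fmol).
#' @export
calibrate <- function(standard_top3, samples) {
  cal <- samples |>
    dplyr::select("sample_id", "spike_fmol_per_ug", "injected_mass_ug") |>
    dplyr::left_join(standard_top3, by = "sample_id") |>
    dplyr::mutate(known_fmol = .data$spike_fmol_per_ug *
                    .data$injected_mass_ug,
                  response = .data$top3_intensity / .data$known_fmol)
  bad <- cal$sample_id[is.na(cal$response) | cal$response <= 0]
  if (length(bad) > 0) {
    warning("surrogate standard not quantified in sample(s) ",
            paste(bad, collapse = ", "),
            "; excluded from absolute quantification", call. = FALSE)
    cal <- dplyr::filter(cal, !.data$sample_id %in% bad)
  }
  dplyr::select(cal, "sample_id", "known_fmol", "response")
}

#' Top-3 (Hi3) absolute protein quantification
#'
#' Estimates per-sample absolute protein amounts from the mean intensity of
#' each protein's top-3 "best flier" peptides, calibrated against the
#' spiked surrogate standard of known amount:
#' `fmol = top3_intensity / response`, `ng = fmol x MW x 1e-6`, and percent
#' of dry weight as each protein's share of the summed quantified native
#' protein mass in that sample (the standard is excluded from both
#' numerator and denominator). Only proteins with at least two peptides are
#' quantified. Because calibration divides by a same-sample intensity, the
#' estimates are invariant to any global rescaling of a sample's
#' intensities.
#'
#' @param peptide_matrix Wide peptide matrix for one dataset (tissue).
#' @param samples Sample metadata for the matrix's columns.
#' @param proteins Tibble with `accession` and `mol_weight_da` (e.g. from
#'   [read_protein_fasta()] or [default_panel()]).
#' @param standard Spiked standard accession (default `ADH1_YEAST`).
#' @param k Peptides per protein (default 3).
#' @return Tibble of class `tendon_quant`: `accession`, `sample_id`,
#'   `top3_intensity`, `amount_fmol`, `amount_ng`, `pct_dry_weight`,
#'   `n_peptides_used`.
#' @export
hi3_quantify <- function(peptide_matrix, samples, proteins,
                         standard = "ADH1_YEAST", k = 3) {
  value_cols <- setdiff(names(peptide_matrix), c("peptide", "accession"))
  top <- select_top_peptides(peptide_matrix, k = k)
  if (!standard %in% top$accession) {
    stop("calibration impossible: surrogate standard ", standard,
         " not quantified with >= 2 peptides", call. = FALSE)
  }
  top3 <- peptide_matrix |>
    dplyr::inner_join(dplyr::select(top, "accession", "peptide"),
                      by = c("accession", "peptide")) |>
    tidyr::pivot_longer(dplyr::all_of(value_cols), names_to = "sample_id",
                        values_to = "intensity") |>
    dplyr::group_by(.data$accession, .data$sample_id) |>
    dplyr::summarise(
      top3_intensity = if (all(is.na(.data$intensity))) NA_real_ else {
        mean(.data$intensity, na.rm = TRUE)
      },
      n_peptides_used = sum(!is.na(.data$intensity)), .groups = "drop")
  cal <- calibrate(dplyr::filter(top3, .data$accession == standard) |>
                     dplyr::select("sample_id", "top3_intensity"),
                   samples)
  quant <- top3 |>
    dplyr::inner_join(cal, by = "sample_id") |>
    dplyr::left_join(dplyr::select(proteins, "accession", "mol_weight_da"),
                     by = "accession") |>
    dplyr::mutate(amount_fmol = .data$top3_intensity / .data$response,
                  amount_ng = .data$amount_fmol * .data$mol_weight_da *
                    1e-6) |>
    dplyr::select("accession", "sample_id", "top3_intensity", "amount_fmol",
                  "amount_ng", "n_peptides_used")
  out <- to_dry_weight(quant, standard = standard)
  class(out) <- c("tendon_quant", class(out))
  attr(out, "n_excluded") <- attr(top, "n_excluded")
  out
}

#' Express protein amounts as percent of dry weight
#'
#' Normalizes each protein's estimated mass to the total quantified native
#' protein mass in its sample: `pct = 100 x ng / sum(ng)`, with the spiked
#' standard excluded from numerator and denominator. Per-sample percentages
#' sum to 100 over the native proteins.
#'
#' @param quant Long tibble with `accession`, `sample_id`, `amount_ng`.
#' @param standard Spiked standard accession to exclude.
#' @return `quant` with a `pct_dry_weight` column (`NA` for the standard).
#' @export
to_dry_weight <- function(quant, standard = "ADH1_YEAST") {
  quant |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(
      pct_dry_weight = dplyr::if_else(
        .data$accession == standard, NA_real_,
        100 * .data$amount_ng /
          sum(.data$amount_ng[.data$accession != standard], na.rm = TRUE))) |>
    dplyr::ungroup()
}

#' Collapse run-level quantification to subject level
#'
#' Averages the absolute-quantification quantities over duplicate analytical
#' runs of the same subject and attaches subject metadata (tissue, sex,
#' donor).
#'
#' @param quant A [hi3_quantify()] result.
#' @param samples Run-level metadata.
#' @return Subject-level tibble with `tissue`, `sex`, `donor` columns.
#' @export
subject_quant <- function(quant, samples) {
  map <- dplyr::mutate(samples, subject_id = paste0(.data$tissue, "_",
                                                    .data$sex, .data$donor))
  out <- quant |>
    dplyr::inner_join(dplyr::select(map, "sample_id", "subject_id", "tissue",
                                    "sex", "donor"),
                      by = "sample_id") |>
    dplyr::group_by(.data$accession, sample_id = .data$subject_id,
                    .data$tissue, .data$sex, .data$donor) |>
    dplyr::summarise(dplyr::across(c("top3_intensity", "amount_fmol",
                                     "amount_ng", "pct_dry_weight"),
                                   ~ mean(.x, na.rm = FALSE)),
                     n_peptides_used = max(.data$n_peptides_used),
                     .groups = "drop")
  class(out) <- c("tendon_quant", class(out))
  out
}

#' Compare tissues on dry-weight protein fractions
#'
#' For proteins quantified in both tissues: signed fold change ACL/PT of
#' mean percent dry weight, two-sided pooled-variance t-test and Cohen's d
#' on log2 percent dry weight across all subjects (n = 6 per tissue at the
#' default design), plus sex-stratified fold changes and p-values (n = 3
#' per group). Cross-tissue comparison is made on dry-weight fractions, not
#' raw intensity, because the two tissue datasets are acquired and
#' calibrated independently.
#'
#' @param quant Subject-level quantification from [subject_quant()]
#'   covering both tissues (columns `tissue`, `sex`, `pct_dry_weight`).
#' @return Tibble: `accession`, per-tissue peptide counts, `fold_change`
#'   (signed ACL/PT), `p_value`, `cohen_d`, `fold_change_f`, `p_value_f`,
#'   `fold_change_m`, `p_value_m`.
#' @export
compare_tissues <- function(quant) {
  stopifnot(all(c("tissue", "sex", "pct_dry_weight") %in% names(quant)))
  quant <- dplyr::filter(quant, !is.na(.data$pct_dry_weight))
  both <- quant |>
    dplyr::distinct(.data$accession, .data$tissue) |>
    dplyr::count(.data$accession) |>
    dplyr::filter(.data$n == 2)
  strat_fc <- function(acl, pt) {
    if (length(acl) < 2 || length(pt) < 2) {
      return(c(NA_real_, NA_real_))
    }
    p <- if (stats::sd(acl) == 0 && stats::sd(pt) == 0) {
      # degenerate: no within-group spread at all
      if (mean(acl) == mean(pt)) 1 else .Machine$double.xmin
    } else {
      stats::t.test(log2(acl), log2(pt), var.equal = TRUE)$p.value
    }
    c(signed_fold_change(mean(acl), mean(pt)), p)
  }
  quant |>
    dplyr::filter(.data$accession %in% both$accession) |>
    dplyr::group_by(.data$accession) |>
    dplyr::group_modify(function(d, key) {
      acl <- d$pct_dry_weight[d$tissue == "ACL"]
      pt <- d$pct_dry_weight[d$tissue == "PT"]
      all_s <- strat_fc(acl, pt)
      f_s <- strat_fc(d$pct_dry_weight[d$tissue == "ACL" & d$sex == "F"],
                      d$pct_dry_weight[d$tissue == "PT" & d$sex == "F"])
      m_s <- strat_fc(d$pct_dry_weight[d$tissue == "ACL" & d$sex == "M"],
                      d$pct_dry_weight[d$tissue == "PT" & d$sex == "M"])
      tibble::tibble(
        n_peptides_acl = max(c(d$n_peptides_used[d$tissue == "ACL"], 0L)),
        n_peptides_pt = max(c(d$n_peptides_used[d$tissue == "PT"], 0L)),
        fold_change = all_s[1], p_value = all_s[2],
        cohen_d = cohens_d(log2(acl), log2(pt)),
        fold_change_f = f_s[1], p_value_f = f_s[2],
        fold_change_m = m_s[1], p_value_m = m_s[2])
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$p_value, .data$accession)
}

#' Molar chain ratios within a protein family
#'
#' Ratios of per-subject molar amounts (fmol) for a set of chains relative
#' to a reference chain (type VI collagen alpha-2 by default), averaged per
#' tissue: the ratio is computed per donor, then summarized as mean +/- SD.
#' Donors missing any chain are excluded and counted.
#'
#' @param quant Subject-level quantification (needs `tissue`,
#'   `amount_fmol`).
#' @param chains Accessions of the chains.
#' @param reference Reference chain accession (ratio fixed at 1).
#' @return Tibble `tissue`, `accession`, `ratio_mean`, `ratio_sd`,
#'   `n_donors`, with attribute `n_excluded_donors`.
#' @export
chain_ratio <- function(quant,
                        chains = c("CO6A1_HUMAN", "CO6A2_HUMAN",
                                   "CO6A3_HUMAN"),
                        reference = "CO6A2_HUMAN") {
  stopifnot(reference %in% chains)
  d <- quant |>
    dplyr::filter(.data$accession %in% chains,
                  !is.na(.data$amount_fmol)) |>
    dplyr::select("accession", "sample_id", "tissue", "amount_fmol")
  complete <- d |>
    dplyr::count(.data$sample_id) |>
    dplyr::filter(.data$n == length(chains))
  n_excluded <- dplyr::n_distinct(d$sample_id) - nrow(complete)
  out <- d |>
    dplyr::filter(.data$sample_id %in% complete$sample_id) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(ratio = .data$amount_fmol /
                    .data$amount_fmol[.data$accession == reference]) |>
    dplyr::group_by(.data$tissue, .data$accession) |>
    dplyr::summarise(ratio_mean = mean(.data$ratio),
                     ratio_sd = stats::sd(.data$ratio),
                     n_donors = dplyr::n(), .groups = "drop")
  attr(out, "n_excluded_donors") <- n_excluded
  out
}

#' Type I : type III collagen ratio
#'
#' Per donor, the ratio of total type I collagen (alpha-1 plus alpha-2
#' chains) to type III collagen percent dry weight, reported per tissue as
#' mean +/- SD of the per-donor ratios (in the conventional "1 : x" form,
#' x = type I / type III). Donors with no quantified type III are excluded.
#'
#' @param quant Subject-level quantification.
#' @param type1 Type I chain accessions.
#' @param type3 Type III chain accession.
#' @return Tibble `tissue`, `ratio_mean`, `ratio_sd`, `n_donors`, plus
#'   per-tissue mean percent columns `pct_type1_mean`, `pct_type3_mean`,
#'   `pct_type1_sd`, `pct_type3_sd`.
#' @export
type_ratio <- function(quant,
                       type1 = c("CO1A1_HUMAN", "CO1A2_HUMAN"),
                       type3 = "CO3A1_HUMAN") {
  per_donor <- quant |>
    dplyr::filter(.data$accession %in% c(type1, type3),
                  !is.na(.data$pct_dry_weight)) |>
    dplyr::group_by(.data$tissue, .data$sample_id) |>
    dplyr::summarise(
      pct_type1 = sum(.data$pct_dry_weight[.data$accession %in% type1]),
      pct_type3 = sum(.data$pct_dry_weight[.data$accession %in% type3]),
      .groups = "drop") |>
    dplyr::filter(.data$pct_type3 > 0)
  per_donor |>
    dplyr::group_by(.data$tissue) |>
    dplyr::summarise(ratio_mean = mean(.data$pct_type1 / .data$pct_type3),
                     ratio_sd = stats::sd(.data$pct_type1 /
                                            .data$pct_type3),
                     pct_type1_mean = mean(.data$pct_type1),
                     pct_type1_sd = stats::sd(.data$pct_type1),
                     pct_type3_mean = mean(.data$pct_type3),
                     pct_type3_sd = stats::sd(.data$pct_type3),
                     n_donors = dplyr::n(), .groups = "drop")
}

#' Protein enrichment relative to albumin
#'
#' Blood, serum and amyloid proteins found in a vascular tissue at levels
#' similar to or above serum albumin are likely enriched in the tissue
#' rather than carried passively in residual blood. For every quantified
#' protein the per-subject ratio of percent dry weight to albumin's is
#' computed; group summaries (per tissue and sex) flag proteins whose mean
#' ratio is at least one, and male-vs-female differences in the ratio are
#' t-tested per tissue.
#'
#' @param quant Subject-level quantification.
#' @param reference Albumin accession (default `ALBU_HUMAN`).
#' @return Tibble `accession`, `tissue`, `sex`, `mean_ratio`, `sd_ratio`,
#'   `n`, `enriched`; attribute `sex_comparison` holds per
#'   (accession, tissue) t-test p-values for the M/F ratio difference.
#' @export
albumin_ratio <- function(quant, reference = "ALBU_HUMAN") {
  alb <- quant |>
    dplyr::filter(.data$accession == reference) |>
    dplyr::select("sample_id", alb_pct = "pct_dry_weight")
  missing_alb <- setdiff(unique(quant$sample_id),
                         alb$sample_id[!is.na(alb$alb_pct)])
  if (length(missing_alb) > 0) {
    warning("albumin not quantified in sample(s) ",
            paste(missing_alb, collapse = ", "),
            "; albumin-relative enrichment unavailable there",
            call. = FALSE)
  }
  ratios <- quant |>
    dplyr::inner_join(alb, by = "sample_id") |>
    dplyr::filter(!is.na(.data$pct_dry_weight), !is.na(.data$alb_pct),
                  .data$alb_pct > 0) |>
    dplyr::mutate(ratio = .data$pct_dry_weight / .data$alb_pct)
  out <- ratios |>
    dplyr::group_by(.data$accession, .data$tissue, .data$sex) |>
    dplyr::summarise(mean_ratio = mean(.data$ratio),
                     sd_ratio = stats::sd(.data$ratio), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(enriched = .data$mean_ratio >= 1)
  sex_tests <- ratios |>
    dplyr::group_by(.data$accession, .data$tissue) |>
    dplyr::summarise(p_sex = {
      m <- .data$ratio[.data$sex == "M"]
      f <- .data$ratio[.data$sex == "F"]
      if (length(m) >= 2 && length(f) >= 2 &&
          (stats::sd(m) > 0 || stats::sd(f) > 0)) {
        stats::t.test(m, f, var.equal = TRUE)$p.value
      } else NA_real_
    }, .groups = "drop")
  attr(out, "sex_comparison") <- sex_tests
  out
}
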