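#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a differential-abundance result
#'
#' One row per (tissue, protein) with the estimate and its statistics, in
#' broom column conventions (`estimate` = log2 fold change M/F,
#' `p.value` / `adj.p.value`, `effect.size` = Cohen's d).
#'
#' @param x A [differential_abundance()] result.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy tendon_diff
#' @export
tidy.tendon_diff <- function(x, ...) {
  dplyr::transmute(tibble::as_tibble(x),
                   .data$tissue, .data$accession,
                   estimate = .data$mean_log2_male -
                     .data$mean_log2_female,
                   fold.change = .data$fold_change,
                   p.value = .data$p_raw, adj.p.value = .data$p_adj,
                   effect.size = .data$cohen_d,
                   n.peptides = .data$n_peptides, curated = .data$curated)
}

#' Summarize a differential-abundance result
#'
#' One row per tissue: proteins tested, proteins passing each curation
#' criterion, and the curated count.
#'
#' @inheritParams tidy.tendon_diff
#' @return A tibble with one row per tissue.
#' @method glance tendon_diff
#' @export
glance.tendon_diff <- function(x, ...) {
  thr <- attr(x, "thresholds")
  tibble::as_tibble(x) |>
    dplyr::group_by(.data$tissue) |>
    dplyr::summarise(
      n_proteins = dplyr::n(),
      n_significant = sum(.data$p_adj < (thr$alpha %||% 0.05),
                          na.rm = TRUE),
      n_large_effect = sum(abs(.data$cohen_d) > (thr$min_d %||% 0.8),
                           na.rm = TRUE),
      n_curated = sum(.data$curated), .groups = "drop")
}

#' Volcano plot of a differential-abundance result
#'
#' Log2 fold change (M/F) against -log10 adjusted p, curated proteins
#' highlighted, faceted by tissue.
#'
#' @param object A [differential_abundance()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tendon_diff
#' @export
autoplot.tendon_diff <- function(object, ...) {
  d <- tidy.tendon_diff(object)
  d <- dplyr::filter(d, !is.na(.data$adj.p.value))
  ggplot2::ggplot(d, ggplot2::aes(.data$estimate,
                                  -log10(.data$adj.p.value),
                                  colour = .data$curated)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::facet_wrap(~tissue) +
    ggplot2::labs(x = "log2 fold change (male / female)",
                  y = "-log10 adjusted p", colour = "curated") +
    ggplot2::theme_minimal()
}

#' Composition plot of an absolute-quantification result
#'
#' Per-sample protein composition as percent of dry weight, the most
#' abundant proteins named and the remainder pooled.
#'
#' @param object A [hi3_quantify()] or [subject_quant()] result.
#' @param n_top Number of proteins shown individually (default 8).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tendon_quant
#' @export
autoplot.tendon_quant <- function(object, n_top = 8, ...) {
  d <- dplyr::filter(tibble::as_tibble(object),
                     !is.na(.data$pct_dry_weight))
  top <- d |>
    dplyr::group_by(.data$accession) |>
    dplyr::summarise(m = mean(.data$pct_dry_weight), .groups = "drop") |>
    dplyr::slice_max(.data$m, n = n_top)
  d <- d |>
    dplyr::mutate(protein = ifelse(.data$accession %in% top$accession,
                                   .data$accession, "other")) |>
    dplyr::group_by(.data$sample_id, .data$protein) |>
    dplyr::summarise(pct = sum(.data$pct_dry_weight), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(.data$sample_id, .data$pct,
                                  fill = .data$protein)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of dry weight", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Score plot of a peptide-level PCA
#'
#' Runs plotted on the first two principal components.
#'
#' @param object A [pca_scores()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tendon_pca
#' @export
autoplot.tendon_pca <- function(object, ...) {
  s <- object$scores
  ggplot2::ggplot(s, ggplot2::aes(.data$PC1, .data$PC2,
                                  label = .data$sample_id)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::labs(
      x = sprintf("PC1 (%.0f%%)", 100 * object$explained_variance[1]),
      y = sprintf("PC2 (%.0f%%)", 100 * object$explained_variance[2])) +
    ggplot2::theme_minimal()
}
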