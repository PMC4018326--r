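#' The bundled matrisome annotation table
#'
#' Accession-to-category mapping for extracellular-matrix (matrisome)
#' classification: collagens, proteoglycans, glycoproteins, ECM regulators,
#' ECM-affiliated proteins and secreted factors, plus a curated flag for
#' blood/plasma/amyloid-associated proteins. The table ships with the
#' package (a static, versioned approximation of Matrisome-Project and gene
#' ontology blood-term annotation; no live database queries).
#'
#' @return Tibble: `accession`, `gene`, `matrisome_category`,
#'   `blood_related`.
#' @export
matrisome_table <- function() {
  readr::read_tsv(
    system.file("extdata", "matrisome_annotation.tsv", package = "tendomics"),
    show_col_types = FALSE, progress = FALSE)
}

#' Annotate proteins with matrisome categories and blood flags
#'
#' Left-joins the annotation onto any tibble with an `accession` column.
#' Accessions absent from the table are classified `non_matrisome` with
#' `blood_related = FALSE` (a default, not an error), so annotation is
#' total and idempotent.
#'
#' @param x Tibble with an `accession` column (or a character vector of
#'   accessions).
#' @param table Annotation table (default [matrisome_table()]).
#' @return `x` with `matrisome_category` and `blood_related` columns.
#' @export
annotate_proteins <- function(x, table = matrisome_table()) {
  if (is.character(x)) x <- tibble::tibble(accession = x)
  x <- dplyr::select(x, -dplyr::any_of(c("matrisome_category",
                                         "blood_related")))
  x |>
    dplyr::left_join(dplyr::select(table, "accession", "matrisome_category",
                                   "blood_related"),
                     by = "accession") |>
    tidyr::replace_na(list(matrisome_category = "non_matrisome",
                           blood_related = FALSE))
}

MATRISOME_CATEGORIES <- c("collagen", "proteoglycan", "glycoprotein",
                          "ECM_regulator", "ECM_affiliated",
                          "secreted_factor", "non_matrisome")

#' Tally proteins per matrisome category
#'
#' Exhaustive counts per category (zero-filled), optionally restricted to
#' proteins identified with at least `min_peptides` peptides. When the
#' input carries a `tissue` column the tally is per tissue and a
#' `shared` count of accessions seen in every tissue is attached.
#'
#' @param annotated Tibble from [annotate_proteins()]; one row per protein
#'   (per tissue if `tissue` present). May carry `n_peptides`.
#' @param min_peptides Optional minimum peptide count filter.
#' @return Tibble of `matrisome_category` counts (by `tissue` if present),
#'   with attribute `n_shared` when multiple tissues are tallied.
#' @export
category_tally <- function(annotated, min_peptides = NULL) {
  if (!is.null(min_peptides) && "n_peptides" %in% names(annotated)) {
    annotated <- dplyr::filter(annotated,
                               .data$n_peptides >= min_peptides)
  }
  frame <- tibble::tibble(matrisome_category = MATRISOME_CATEGORIES)
  by_tissue <- "tissue" %in% names(annotated)
  if (by_tissue) {
    frame <- tidyr::expand_grid(tissue = unique(annotated$tissue),
                                matrisome_category = MATRISOME_CATEGORIES)
    counts <- dplyr::count(annotated, .data$tissue,
                           .data$matrisome_category)
    out <- frame |>
      dplyr::left_join(counts, by = c("tissue", "matrisome_category")) |>
      tidyr::replace_na(list(n = 0L))
    shared <- annotated |>
      dplyr::distinct(.data$accession, .data$tissue) |>
      dplyr::count(.data$accession) |>
      dplyr::filter(.data$n == dplyr::n_distinct(annotated$tissue))
    attr(out, "n_shared") <- nrow(shared)
    return(out)
  }
  counts <- dplyr::count(annotated, .data$matrisome_category)
  frame |>
    dplyr::left_join(counts, by = "matrisome_category") |>
    tidyr::replace_na(list(n = 0L))
}
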