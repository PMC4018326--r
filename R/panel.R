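#' The bundled synthetic protein panel
#'
#' A panel of ~50 proteins emulating the composition of human anterior
#' cruciate ligament (ACL) and patellar tendon (PT): collagen-dominated
#' (type I collagen roughly 52% of ACL and 82% of PT dry weight), with
#' programmed tissue and sex fold changes on the proteins the tissues are
#' known to differ in, tissue-exclusive proteins, type VI collagen chains at
#' unequal molar ratios, the blood proteins albumin carries along, and the
#' ADH1_YEAST surrogate standard. Sequences are synthetic stand-ins
#' (random tryptic-friendly sequences of roughly the right mass), so
#' molecular weights, digests and the ground-truth ledger are all computed
#' from the same bundled FASTA and stay internally consistent.
#'
#' Concentrations are in fmol per microgram of digest for each tissue;
#' sex fold changes use the signed convention (negative = higher in female),
#' applied symmetrically around the tissue concentration.
#'
#' @return Tibble with columns `accession`, `gene`, `description`,
#'   `matrisome_category`, `blood_related`, `conc_acl_fmol_ug`,
#'   `conc_pt_fmol_ug`, `sex_fc_acl`, `sex_fc_pt`, `sequence`,
#'   `mol_weight_da`.
#' @export
default_panel <- function() {
  panel <- readr::read_tsv(
    system.file("extdata", "synthetic_panel.tsv", package = "tendomics"),
    show_col_types = FALSE, progress = FALSE)
  fasta <- read_protein_fasta(
    system.file("extdata", "synthetic_proteins.fasta", package = "tendomics"))
  dplyr::left_join(panel, dplyr::select(fasta, "accession", "sequence",
                                        "mol_weight_da"),
                   by = "accession")
}
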