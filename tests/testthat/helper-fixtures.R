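# small in-code fixtures shared across test files

# hand-built records: 2 samples, 2 proteins, one peptide split over fractions
tiny_records <- function() {
  tibble::tibble(
    sample_id = c("A", "A", "A", "A", "B", "B", "B"),
    fraction  = c(3L, 4L, 1L, 2L, 3L, 1L, 2L),
    peptide   = c("PEPTIDEK", "PEPTIDEK", "AGGTK", "LLSVK",
                  "PEPTIDEK", "AGGTK", "LLSVK"),
    accession = c("P1", "P1", "P1", "P2", "P1", "P1", "P2"),
    intensity = c(100, 50, 200, 300, 140, 210, 290),
    score     = rep(5, 7),
    is_decoy  = FALSE
  )
}

tiny_meta <- function() {
  tibble::tibble(
    sample_id = c("A", "B"),
    tissue = "ACL", sex = c("M", "F"), donor = c(1L, 1L),
    replicate = 1L, injected_mass_ug = 3, spike_fmol_per_ug = 25
  )
}

# compact panel for fast simulations: short synthetic tryptic-friendly
# sequences, deterministic; standard + a handful of proteins
small_panel <- function(sex_fc_acl = c(1, 1, 1, 1),
                        conc_acl = c(50, 20, 10, 5),
                        conc_pt = conc_acl,
                        with_standard = TRUE) {
  # deterministic distinct tryptic peptides: 7 residues + K, no internal K/R
  aa <- strsplit("GAVLSTDEMFWYNQHCI", "")[[1]]
  mk_seq <- function(offset, n_pep) {
    peps <- vapply(seq_len(n_pep), function(j) {
      # first residue tags the protein, second the peptide: no collisions
      idx <- c(offset %% 17, (offset * 3 + j) %% 17,
               (j * 5 + seq_len(5) * 3) %% 17) + 1
      paste0(paste(aa[idx], collapse = ""), "K")
    }, character(1))
    paste(peps, collapse = "")
  }
  acc <- paste0("PROT", seq_along(conc_acl), "_TEST")
  seqs <- vapply(seq_along(acc), function(i) mk_seq(i, 10 + i), character(1))
  panel <- tibble::tibble(
    accession = acc, gene = acc, description = acc,
    matrisome_category = "non_matrisome", blood_related = FALSE,
    conc_acl_fmol_ug = conc_acl, conc_pt_fmol_ug = conc_pt,
    sex_fc_acl = sex_fc_acl, sex_fc_pt = 1,
    sequence = seqs
  )
  if (with_standard) {
    panel <- dplyr::bind_rows(panel, tibble::tibble(
      accession = "ADH1_YEAST", gene = "ADH1", description = "standard",
      matrisome_category = "non_matrisome", blood_related = FALSE,
      conc_acl_fmol_ug = 25, conc_pt_fmol_ug = 25,
      sex_fc_acl = 1, sex_fc_pt = 1,
      sequence = mk_seq(99, 15)
    ))
  }
  panel$mol_weight_da <- protein_mw(panel$sequence)
  panel
}

# fast one-tissue simulation used in several files
quick_sim <- function(seed = 1, sigma = 0, dropout = 0, decoy = 0, ...) {
  simulate_dataset(panel = small_panel(...), tissues = "ACL",
                   sigma = sigma, dropout_rate = dropout,
                   decoy_rate = decoy, seed = seed)
}
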