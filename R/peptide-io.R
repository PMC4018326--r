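#' Read a peptide-level quantitative table
#'
#' Reads a delimited text file with one quantified peptide observation per row.
#' Required columns: `sample_id`, `peptide`, `accession`, `intensity`.
#' Optional columns: `fraction` (LC/LC fraction index; absent means the table
#' is already fraction-merged), `score` (identification score) and `is_decoy`
#' (reversed-sequence decoy flag, defaults to `FALSE`). Any further columns are
#' kept untouched.
#'
#' Missing intensities are encoded as empty fields, never as zero: a zero in
#' the file means "observed at zero area", an empty cell means "not observed".
#'
#' @param path Path to the delimited file.
#' @param delim Field delimiter (default tab).
#' @return A tibble of peptide records, one row per observation.
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("sample_id\tfraction\tpeptide\taccession\tintensity",
#'              "ACL_M1\t1\tAGGTK\tCO1A1_HUMAN\t100"), f)
#' read_peptide_table(f)
read_peptide_table <- function(path, delim = "\t") {
  if (!file.exists(path)) {
    stop("peptide table not found: ", path, call. = FALSE)
  }
  rec <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  required <- c("sample_id", "peptide", "accession", "intensity")
  missing_cols <- setdiff(required, names(rec))
  if (length(missing_cols) > 0) {
    stop("peptide table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  rec <- dplyr::mutate(rec,
    sample_id = as.character(.data$sample_id),
    peptide   = as.character(.data$peptide),
    accession = as.character(.data$accession),
    intensity = as.numeric(.data$intensity)
  )
  if (!"is_decoy" %in% names(rec)) rec$is_decoy <- FALSE
  rec$is_decoy <- as.logical(rec$is_decoy)
  if ("fraction" %in% names(rec)) rec$fraction <- as.integer(rec$fraction)
  validate_peptide_records(rec)
  tibble::as_tibble(rec)
}

#' Write a peptide-level quantitative table
#'
#' Writes records as tab-delimited text with a deterministic row order
#' (sample, fraction, peptide, accession) and column order, so that a
#' write/read round trip is the identity and outputs are diff-able.
#'
#' @param records Tibble of peptide records (see [read_peptide_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(records, path) {
  validate_peptide_records(records)
  lead <- intersect(c("sample_id", "fraction", "peptide", "accession",
                      "intensity", "score", "is_decoy"), names(records))
  records <- dplyr::select(records, dplyr::all_of(lead), dplyr::everything())
  ord <- intersect(c("sample_id", "fraction", "peptide", "accession"),
                   names(records))
  records <- dplyr::arrange(records, dplyr::across(dplyr::all_of(ord)))
  readr::write_tsv(records, path, progress = FALSE)
  invisible(path)
}

validate_peptide_records <- function(records) {
  if (nrow(records) == 0) return(invisible(records))
  bad <- which(!is.na(records$intensity) & records$intensity < 0)
  if (length(bad) > 0) {
    stop("negative intensity at row ", bad[1], call. = FALSE)
  }
  if (any(!nzchar(records$peptide))) {
    stop("empty peptide sequence at row ", which(!nzchar(records$peptide))[1],
         call. = FALSE)
  }
  if ("fraction" %in% names(records)) {
    if (any(records$fraction < 1, na.rm = TRUE)) {
      stop("fraction index below 1", call. = FALSE)
    }
  }
  invisible(records)
}

#' Read or write sample metadata
#'
#' Sample metadata holds one row per analytical run: `sample_id`, `tissue`
#' (ACL or PT), `sex` (M or F), `donor` (1-3), `replicate` (run index within
#' subject), `injected_mass_ug` (protein digest on column, default 3) and
#' `spike_fmol_per_ug` (surrogate-standard spike level, default 25).
#'
#' @param path Path to a tab-delimited metadata file.
#' @return A tibble with one row per analytical run.
#' @export
read_sample_meta <- function(path) {
  meta <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("sample_id", "tissue", "sex", "donor", "replicate")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0) {
    stop("sample metadata is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"injected_mass_ug" %in% names(meta)) meta$injected_mass_ug <- 3
  if (!"spike_fmol_per_ug" %in% names(meta)) meta$spike_fmol_per_ug <- 25
  validate_sample_meta(meta)
}

#' @rdname read_sample_meta
#' @param meta Sample metadata tibble.
#' @export
write_sample_meta <- function(meta, path) {
  validate_sample_meta(meta)
  readr::write_tsv(dplyr::arrange(meta, .data$sample_id), path, progress = FALSE)
  invisible(path)
}

validate_sample_meta <- function(meta) {
  stopifnot(all(meta$injected_mass_ug > 0), all(meta$spike_fmol_per_ug >= 0))
  key <- paste(meta$tissue, meta$sex, meta$donor, meta$replicate)
  if (anyDuplicated(key)) {
    stop("duplicated (tissue, sex, donor, replicate) in sample metadata",
         call. = FALSE)
  }
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicated sample_id in sample metadata", call. = FALSE)
  }
  tibble::as_tibble(meta)
}

#' Merge LC/LC fractions into a peptide-by-sample matrix
#'
#' Sums each peptide's intensity across fractions within a sample (the small
#' minority of peptides eluting in more than one fraction get their areas
#' added), then spreads samples to columns. Peptide identity is the pair
#' (sequence including modification annotations, accession); homologous
#' peptides are taken as assigned by the input and not re-grouped.
#'
#' Decoy records are excluded from the matrix but tallied in the
#' `"decoy_summary"` attribute (count and total intensity), so intensity
#' conservation can be checked: matrix total + decoy total = record total.
#'
#' A table without a `fraction` column is treated as already merged.
#'
#' @param records Tibble of peptide records.
#' @return A tibble with `peptide`, `accession` and one intensity column per
#'   sample (`NA` = not observed), with attribute `decoy_summary`.
#' @export
merge_fractions <- function(records) {
  if (nrow(records) == 0) {
    out <- tibble::tibble(peptide = character(), accession = character())
    attr(out, "decoy_summary") <- tibble::tibble(n = 0L, total_intensity = 0)
    return(out)
  }
  validate_peptide_records(records)
  if (!"is_decoy" %in% names(records)) records$is_decoy <- FALSE
  decoys <- dplyr::filter(records, .data$is_decoy)
  targets <- dplyr::filter(records, !.data$is_decoy)
  merged <- targets |>
    dplyr::group_by(.data$peptide, .data$accession, .data$sample_id) |>
    dplyr::summarise(intensity = sum(.data$intensity), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "intensity") |>
    dplyr::arrange(.data$accession, .data$peptide)
  attr(merged, "decoy_summary") <- tibble::tibble(
    n = nrow(decoys),
    total_intensity = sum(decoys$intensity)
  )
  merged
}

# average residue masses (Da) for molecular weight from sequence
AA_AVG_MASS <- c(G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
                 T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594,
                 N = 114.1038, D = 115.0886, Q = 128.1307, K = 128.1741,
                 E = 129.1155, M = 131.1926, H = 137.1411, F = 147.1766,
                 R = 156.1875, Y = 163.1760, W = 186.2132)
WATER_MASS <- 18.0153

#' Average molecular weight of a protein or peptide sequence
#'
#' Sum of average residue masses plus one water. Modified residues are not
#' handled; modification annotations, if any, must be stripped first.
#'
#' @param sequence Character vector of amino-acid sequences.
#' @return Numeric vector of average masses in Da.
#' @export
#' @examples
#' protein_mw("G")   # glycine + water = 75.07
protein_mw <- function(sequence) {
  vapply(sequence, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_real_)
    aa <- strsplit(s, "")[[1]]
    unknown <- setdiff(aa, names(AA_AVG_MASS))
    if (length(unknown) > 0) {
      stop("non-amino-acid character(s) in sequence: ",
           paste(unique(unknown), collapse = ", "), call. = FALSE)
    }
    sum(AA_AVG_MASS[aa]) + WATER_MASS
  }, numeric(1), USE.NAMES = FALSE)
}

#' Read protein sequences from FASTA
#'
#' Parses a FASTA file into a tibble of accession, description, sequence and
#' computed average molecular weight. The accession is the first white-space
#' delimited token of the header.
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return Tibble with columns `accession`, `description`, `sequence`,
#'   `mol_weight_da`.
#' @export
read_protein_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("the Biostrings package is required to read FASTA files",
         call. = FALSE)
  }
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0) {
    return(tibble::tibble(accession = character(), description = character(),
                          sequence = character(), mol_weight_da = numeric()))
  }
  header <- names(seqs)
  accession <- sub("\\s.*$", "", header)
  description <- ifelse(grepl("\\s", header), sub("^\\S+\\s+", "", header), "")
  tibble::tibble(
    accession = accession,
    description = description,
    sequence = as.character(seqs),
    mol_weight_da = protein_mw(as.character(seqs))
  )
}
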