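#' In-silico tryptic digestion
#'
#' Cleaves a protein sequence after every K or R that is not followed by P,
#' and returns all peptides carrying `0..max_missed` missed cleavages whose
#' length lies in `[min_len, max_len]`.
#'
#' @param sequence Single amino-acid sequence (standard 20 letters).
#' @param max_missed Maximum number of missed cleavages (default 2, the usual
#'   database-search setting).
#' @param min_len,max_len Peptide length window (defaults keep everything).
#' @return Character vector of unique peptide sequences, in N- to C-terminal
#'   order of their start position.
#' @export
#' @examples
#' digest_protein("AKRPGK", max_missed = 0)   # no cleavage at R|P
digest_protein <- function(sequence, max_missed = 2, min_len = 1,
                           max_len = Inf) {
  stopifnot(length(sequence) == 1, max_missed >= 0, min_len >= 1)
  if (is.na(sequence) || !nzchar(sequence)) {
    stop("sequence must be non-empty", call. = FALSE)
  }
  aa <- strsplit(sequence, "")[[1]]
  unknown <- setdiff(aa, names(AA_AVG_MASS))
  if (length(unknown) > 0) {
    stop("non-amino-acid character(s) in sequence: ",
         paste(unique(unknown), collapse = ", "), call. = FALSE)
  }
  n <- length(aa)
  # cleavage sites: after position i when aa[i] in (K, R) and aa[i+1] != P
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after == n | aa[pmin(cut_after + 1, n)] != "P"]
  bounds <- c(0L, cut_after, if (n %in% cut_after) NULL else n)
  bounds <- unique(bounds)
  n_frag <- length(bounds) - 1L
  out <- character(0)
  for (i in seq_len(n_frag)) {
    for (m in 0:max_missed) {
      j <- i + m
      if (j > n_frag) break
      len <- bounds[j + 1L] - bounds[i]
      if (len >= min_len && len <= max_len) {
        out <- c(out, substr(sequence, bounds[i] + 1L, bounds[j + 1L]))
      }
    }
  }
  unique(out)
}
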