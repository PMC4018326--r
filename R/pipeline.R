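#' Build a validated pipeline configuration
#'
#' Collects every knob of the end-to-end analysis in one list: the input
#' source (a simulation configuration, or paths to a peptide table, sample
#' metadata and protein FASTA), the peptide FDR target, curation
#' thresholds, top-k and spike settings, the seed and the output directory.
#'
#' @param simulate `TRUE` to generate the input with [simulate_dataset()]
#'   (using `sim_args`), `FALSE` to read from `peptide_table` /
#'   `sample_meta` / `fasta` paths.
#' @param sim_args List of arguments passed to [simulate_dataset()].
#' @param peptide_table,sample_meta,fasta Input paths when
#'   `simulate = FALSE`.
#' @param target_fdr_pct Peptide FDR target in percent (default 2).
#' @param alpha,min_d,min_peptides Curation thresholds (0.05, 0.8, 2).
#' @param top_k Peptides for Hi3 quantification (default 3).
#' @param standard Spiked standard accession.
#' @param p_adjust `"BH"` or `"hochberg"`.
#' @param weights ANOVA weighting, `"auto"` or `"unit"`.
#' @param seed Integer seed for every stochastic step.
#' @param out_dir Output directory (created if needed).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = TRUE, sim_args = list(),
                            peptide_table = NULL, sample_meta = NULL,
                            fasta = NULL,
                            target_fdr_pct = 2, alpha = 0.05, min_d = 0.8,
                            min_peptides = 2, top_k = 3,
                            standard = "ADH1_YEAST",
                            p_adjust = c("BH", "hochberg"),
                            weights = c("auto", "unit"),
                            seed = 1L, out_dir = tempfile("tendomics_")) {
  stopifnot(target_fdr_pct > 0, alpha > 0, min_d > 0, min_peptides > 0,
            top_k >= 2)
  if (!simulate && (is.null(peptide_table) || is.null(sample_meta))) {
    stop("peptide_table and sample_meta paths are required when not ",
         "simulating", call. = FALSE)
  }
  structure(list(simulate = simulate, sim_args = sim_args,
                 peptide_table = peptide_table, sample_meta = sample_meta,
                 fasta = fasta, target_fdr_pct = target_fdr_pct,
                 alpha = alpha, min_d = min_d, min_peptides = min_peptides,
                 top_k = top_k, standard = standard,
                 p_adjust = match.arg(p_adjust),
                 weights = match.arg(weights),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — read or simulate, decoy FDR filter,
#' fraction merging, QC, protein roll-up, duplicate averaging,
#' male-vs-female differential analysis, Hi3 absolute quantification,
#' cross-tissue comparisons, ratio analyses and matrisome annotation — and
#' writes every result as a tab-delimited table whose first line records
#' the seed and a hash of the configuration. Identical configuration and
#' seed reproduce byte-identical outputs. A stage failure aborts with the
#' stage name and removes partial outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all in-memory results (`qc`,
#'   `differential`, `quant`, `comparison`, `ratios`, `tally`, `tables`,
#'   plus `sim` when simulated).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  log_lines <- character(0)
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))
  cfg_for_hash <- unclass(config)
  cfg_for_hash$out_dir <- NULL   # the hash identifies the analysis, not where it lands
  stamp <- sprintf("# tendomics seed=%d config_hash=%s", config$seed,
                   rlang::hash(cfg_for_hash))
  emit <- function(x, name) {
    path <- file.path(config$out_dir, name)
    writeLines(stamp, path)
    readr::write_tsv(x, path, append = TRUE, col_names = TRUE,
                     progress = FALSE)
    written <<- c(written, path)
  }
  stage <- "setup"
  result <- tryCatch({
    # --- acquire ---------------------------------------------------------
    stage <- "input"
    if (config$simulate) {
      sim_args <- utils::modifyList(list(seed = config$seed),
                                    config$sim_args)
      sim <- do.call(simulate_dataset, sim_args)
      records <- sim$records
      samples <- sim$samples
      proteins <- sim$truth$panel
    } else {
      sim <- NULL
      records <- read_peptide_table(config$peptide_table)
      samples <- read_sample_meta(config$sample_meta)
      proteins <- if (!is.null(config$fasta)) {
        read_protein_fasta(config$fasta)
      } else default_panel()
    }
    say("input: %d peptide records, %d analytical runs", nrow(records),
        nrow(samples))

    tissues <- unique(samples$tissue)
    qc <- list(); pq_all <- list(); quant_all <- list()
    for (tt in tissues) {
      runs <- samples$sample_id[samples$tissue == tt]
      rec_t <- dplyr::filter(records, .data$sample_id %in% runs)

      stage <- paste0("fdr_filter[", tt, "]")
      filt <- apply_fdr_filter(rec_t, config$target_fdr_pct)
      fdr <- attr(filt, "fdr")
      if (!is.null(fdr)) {
        say("%s: FDR filter kept %d targets, %d decoys (%.2f%%)", tt,
            fdr$n_target, fdr$n_decoy, fdr$fdr_pct)
      }
      targets <- dplyr::filter(filt, !.data$is_decoy)

      stage <- paste0("merge_fractions[", tt, "]")
      pepmat <- merge_fractions(targets)
      say("%s: %d merged peptides", tt, nrow(pepmat))

      stage <- paste0("qc[", tt, "]")
      qc[[tt]] <- qc_report(rec_t, config$target_fdr_pct, config$standard)

      stage <- paste0("rollup[", tt, "]")
      pq_all[[tt]] <- rollup(pepmat)
      say("%s: %d proteins rolled up", tt,
          dplyr::n_distinct(pq_all[[tt]]$accession))

      stage <- paste0("absolute_quant[", tt, "]")
      if (!config$standard %in% pq_all[[tt]]$accession) {
        stop("calibration: surrogate standard ", config$standard,
             " missing from the ", tt, " dataset", call. = FALSE)
      }
      sam_t <- dplyr::filter(samples, .data$tissue == tt)
      q <- hi3_quantify(pepmat, sam_t, proteins,
                        standard = config$standard, k = config$top_k)
      quant_all[[tt]] <- subject_quant(q, sam_t)
      say("%s: %d proteins absolutely quantified", tt,
          dplyr::n_distinct(quant_all[[tt]]$accession))
    }
    pq <- dplyr::bind_rows(pq_all)
    quant <- dplyr::bind_rows(quant_all)

    stage <- "differential"
    diff <- differential_abundance(pq, samples, weights = config$weights,
                                   p_adjust = config$p_adjust,
                                   min_peptides = config$min_peptides,
                                   alpha = config$alpha,
                                   min_d = config$min_d)
    for (tt in tissues) {
      say("%s: %d proteins tested, %d curated", tt,
          sum(diff$tissue == tt), sum(diff$curated[diff$tissue == tt]))
    }

    stage <- "tissue_comparison"
    comparison <- if (length(tissues) == 2) compare_tissues(quant) else NULL

    stage <- "ratios"
    ratios <- list(
      chain = tryCatch(chain_ratio(quant), error = function(e) NULL),
      type = tryCatch(type_ratio(quant), error = function(e) NULL),
      albumin = tryCatch(suppressWarnings(albumin_ratio(quant)),
                         error = function(e) NULL))

    stage <- "annotation"
    annotated <- diff |>
      dplyr::distinct(.data$tissue, .data$accession, .data$n_peptides) |>
      annotate_proteins()
    tally <- category_tally(annotated)

    stage <- "report"
    tables <- report_tables(list(differential = diff,
                                 comparison = comparison,
                                 config = config))
    say("report: %d curated sex-difference rows, %d tissue-difference rows",
        nrow(tables$sex_differences), nrow(tables$tissue_differences))

    stage <- "write"
    qc_flat <- purrr::imap(qc, function(q, tt) {
      tibble::tibble(tissue = tt, surrogate_rsd_pct = q$surrogate_rsd_pct,
                     pct_single_fraction = q$pct_single_fraction,
                     fdr_pct = q$fdr$fdr_pct, fdr_threshold = q$fdr$threshold,
                     n_target = q$fdr$n_target, n_decoy = q$fdr$n_decoy)
    }) |> dplyr::bind_rows()
    emit(qc_flat, "qc_summary.tsv")
    emit(purrr::imap(qc, ~ dplyr::mutate(.x$fraction_load, tissue = .y)) |>
           dplyr::bind_rows(), "fraction_load.tsv")
    emit(purrr::imap(qc, ~ dplyr::mutate(.x$pca$scores, tissue = .y)) |>
           dplyr::bind_rows(), "pca_scores.tsv")
    emit(diff, "differential.tsv")
    emit(quant, "absolute_quant.tsv")
    if (!is.null(comparison)) emit(comparison, "tissue_comparison.tsv")
    if (!is.null(ratios$chain)) emit(ratios$chain, "col6_chain_ratio.tsv")
    if (!is.null(ratios$type)) emit(ratios$type, "collagen_type_ratio.tsv")
    if (!is.null(ratios$albumin)) emit(ratios$albumin, "albumin_ratio.tsv")
    emit(tally, "category_tally.tsv")
    emit(tables$sex_differences, "table_sex_differences.tsv")
    emit(tables$tissue_differences, "table_tissue_differences.tsv")
    writeLines(c(stamp, log_lines), file.path(config$out_dir, "log.txt"))

    list(qc = qc, protein_quant = pq, differential = diff, quant = quant,
         comparison = comparison, ratios = ratios, tally = tally,
         tables = tables, sim = sim, config = config)
  }, error = function(e) {
    unlink(written)
    stop("pipeline failed at stage ", stage, ": ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

#' Format publication-style result tables
#'
#' Produces the two reporting tables: per-tissue curated male-vs-female
#' differences (peptide count, signed fold change M/F, adjusted ANOVA
#' p-value, Cohen's d) and curated ACL-vs-PT differences (per-tissue
#' peptide counts, signed fold change ACL/PT, t-test p, Cohen's d, and the
#' sex-stratified fold changes and p-values). Rows are ordered by adjusted
#' p (then accession) so output is deterministic.
#'
#' @param results List with `differential` (a [differential_abundance()]
#'   result), optional `comparison` (a [compare_tissues()] result) and
#'   optional `config` (for curation thresholds).
#' @return List with tibbles `sex_differences` and `tissue_differences`.
#' @export
report_tables <- function(results) {
  cfg <- results$config
  alpha <- cfg$alpha %||% 0.05
  min_d <- cfg$min_d %||% 0.8
  min_pep <- cfg$min_peptides %||% 2
  diff <- results$differential
  sex_tab <- if (!is.null(diff) && nrow(diff) > 0) {
    curate(diff, min_peptides = min_pep, alpha = alpha, min_d = min_d) |>
      annotate_proteins() |>
      dplyr::transmute(.data$tissue, .data$accession,
                       .data$matrisome_category,
                       peptide_count = .data$n_peptides,
                       fold_change_m_f = round(.data$fold_change, 2),
                       anova_p = signif(.data$p_adj, 3),
                       cohen_d = round(.data$cohen_d, 2)) |>
      dplyr::arrange(.data$tissue, .data$anova_p, .data$accession)
  } else {
    tibble::tibble(tissue = character(), accession = character(),
                   matrisome_category = character(),
                   peptide_count = integer(), fold_change_m_f = numeric(),
                   anova_p = numeric(), cohen_d = numeric())
  }
  comp <- results$comparison
  tissue_tab <- if (!is.null(comp) && nrow(comp) > 0) {
    comp |>
      dplyr::filter(pmax(.data$n_peptides_acl, .data$n_peptides_pt) >=
                      min_pep,
                    !is.na(.data$p_value) & .data$p_value < alpha,
                    !is.na(.data$cohen_d) & abs(.data$cohen_d) > min_d) |>
      annotate_proteins() |>
      dplyr::transmute(.data$accession, .data$matrisome_category,
                       acl_peptides = .data$n_peptides_acl,
                       pt_peptides = .data$n_peptides_pt,
                       fold_change_acl_pt = round(.data$fold_change, 2),
                       p_value = signif(.data$p_value, 3),
                       cohen_d = round(.data$cohen_d, 2),
                       female_fc = round(.data$fold_change_f, 2),
                       female_p = signif(.data$p_value_f, 3),
                       male_fc = round(.data$fold_change_m, 2),
                       male_p = signif(.data$p_value_m, 3)) |>
      dplyr::arrange(.data$p_value, .data$accession)
  } else {
    tibble::tibble(accession = character(),
                   matrisome_category = character(),
                   acl_peptides = integer(), pt_peptides = integer(),
                   fold_change_acl_pt = numeric(), p_value = numeric(),
                   cohen_d = numeric(), female_fc = numeric(),
                   female_p = numeric(), male_fc = numeric(),
                   male_p = numeric())
  }
  list(sex_differences = sex_tab, tissue_differences = tissue_tab)
}
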