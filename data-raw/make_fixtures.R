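# Builds the bundled synthetic fixtures:
#   inst/extdata/synthetic_proteins.fasta  - synthetic stand-in sequences, one per panel protein
#   inst/extdata/synthetic_panel.tsv       - per-protein group concentrations + programmed effects
#   inst/extdata/matrisome_annotation.tsv  - accession -> matrisome category / blood flag
# Run from the package root: Rscript data-raw/make_fixtures.R
# Sequences are random with tryptic-friendly composition; identities are nominal only.

set.seed(20140512)

# average residue masses (Da); water added per chain
AA_MASS <- c(G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
             T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
             D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
             H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)
WATER <- 18.0153

# amino-acid sampling weights: roughly vertebrate proteome composition,
# K+R ~ 11% so tryptic peptides of usable length are plentiful
AA_FREQ <- c(G = 0.071, A = 0.074, S = 0.081, P = 0.050, V = 0.060,
             T = 0.062, C = 0.015, L = 0.090, I = 0.045, N = 0.044,
             D = 0.059, Q = 0.037, K = 0.058, E = 0.058, M = 0.018,
             H = 0.022, F = 0.040, R = 0.052, Y = 0.033, W = 0.013)

rand_seq <- function(n) paste(sample(names(AA_FREQ), n, replace = TRUE, prob = AA_FREQ),
                              collapse = "")
seq_mass <- function(s) sum(AA_MASS[strsplit(s, "")[[1]]]) + WATER

# ---- panel definition -------------------------------------------------------
# mw_kda: target synthetic mass (real values capped ~150-200 kDa to bound FASTA size)
# pct_*: design %-dry-weight per tissue; NA = solved below
# fc_tissue: design ACL/PT fold change used to derive pct_acl for minor proteins
p <- function(acc, gene, desc, cat, blood, mw, pct_pt, fc_tissue, sex_acl = 1, sex_pt = 1)
  data.frame(accession = acc, gene = gene, description = desc, matrisome_category = cat,
             blood_related = blood, mw_kda = mw, pct_pt = pct_pt, fc_tissue = fc_tissue,
             sex_fc_acl = sex_acl, sex_fc_pt = sex_pt, stringsAsFactors = FALSE)

panel <- rbind(
  # anchors: dry-weight percentages fixed directly in both tissues
  p("CO1A1_HUMAN", "COL1A1", "Collagen alpha-1(I) chain", "collagen", FALSE, 139, 54.77, NA, -1.20, -1.20),
  p("CO1A2_HUMAN", "COL1A2", "Collagen alpha-2(I) chain", "collagen", FALSE, 129, 27.39, NA, -1.23, -1.12),
  p("CO3A1_HUMAN", "COL3A1", "Collagen alpha-1(III) chain", "collagen", FALSE, 139, 6.61, NA, 1, 1),
  # type VI chains: percentages fixed to give molar ratios ~2:1:6 (ACL) and ~2:1:4 (PT)
  p("CO6A1_HUMAN", "COL6A1", "Collagen alpha-1(VI) chain", "collagen", FALSE, 108, NA, NA, 1, 1.41),
  p("CO6A2_HUMAN", "COL6A2", "Collagen alpha-2(VI) chain", "collagen", FALSE, 108, NA, NA, 1, 1),
  p("CO6A3_HUMAN", "COL6A3", "Collagen alpha-3(VI) chain", "collagen", FALSE, 180, NA, NA, 1, 1),
  # minor proteins with programmed tissue fold changes (Table-2-style, ACL/PT)
  p("FINC_HUMAN", "FN1", "Fibronectin", "glycoprotein", TRUE, 170, 0.15, 6.00),
  p("CO9_HUMAN", "C9", "Complement component C9", "non_matrisome", TRUE, 63, 0.03, 5.64, -4.56, 1),
  p("HRG_HUMAN", "HRG", "Histidine-rich glycoprotein", "ECM_regulator", TRUE, 60, 0.03, 4.74),
  p("MIME_HUMAN", "OGN", "Mimecan", "proteoglycan", FALSE, 34, 0.10, 4.44, 1, 1.31),
  p("VIME_HUMAN", "VIM", "Vimentin", "non_matrisome", FALSE, 54, 0.04, 3.53, 1, 2.01),
  p("CLUS_HUMAN", "CLU", "Clusterin", "ECM_affiliated", TRUE, 52, 0.05, 3.53),
  p("TENX_HUMAN", "TNXB", "Tenascin-X", "glycoprotein", FALSE, 150, 0.08, 3.43),
  p("ASPN_HUMAN", "ASPN", "Asporin", "proteoglycan", FALSE, 43, 0.12, 3.27),
  p("BGH3_HUMAN", "TGFBI", "TGF-beta-induced protein ig-h3", "glycoprotein", TRUE, 75, 0.06, 3.11),
  p("PGS1_HUMAN", "BGN", "Biglycan", "proteoglycan", FALSE, 42, 0.30, 3.06),
  p("ANXA1_HUMAN", "ANXA1", "Annexin A1", "ECM_affiliated", FALSE, 39, 0.02, 3.05),
  p("ANXA5_HUMAN", "ANXA5", "Annexin A5", "ECM_affiliated", FALSE, 36, 0.02, 3.02),
  p("TENA_HUMAN", "TNC", "Tenascin C", "glycoprotein", FALSE, 150, 0.03, 2.99),
  p("ELN_HUMAN", "ELN", "Elastin", "glycoprotein", FALSE, 68, 0.06, 2.53),
  p("TSP4_HUMAN", "THBS4", "Thrombospondin-4", "glycoprotein", FALSE, 106, 0.10, 2.46),
  p("PRELP_HUMAN", "PRELP", "Prolargin", "proteoglycan", FALSE, 44, 0.55, 2.46),
  p("CILP1_HUMAN", "CILP", "Cartilage intermediate layer protein 1", "glycoprotein", FALSE, 133, 0.30, 2.42),
  p("PGBM_HUMAN", "HSPG2", "Basement membrane heparan sulfate proteoglycan", "proteoglycan", FALSE, 150, 0.05, 2.32),
  p("H4_HUMAN", "HIST1H4A", "Histone H4", "non_matrisome", FALSE, 11, 0.04, 2.25),
  p("LUM_HUMAN", "LUM", "Lumican", "proteoglycan", FALSE, 38, 0.18, 2.07, 1, 1.81),
  p("A1AT_HUMAN", "SERPINA1", "Alpha-1-antitrypsin", "ECM_regulator", TRUE, 47, 0.05, 1.72),
  p("COMP_HUMAN", "COMP", "Cartilage oligomeric matrix protein", "glycoprotein", FALSE, 83, 0.30, 1.63),
  p("FBN1_HUMAN", "FBN1", "Fibrillin-1", "glycoprotein", FALSE, 150, 0.25, -1.62),
  p("FMOD_HUMAN", "FMOD", "Fibromodulin", "proteoglycan", FALSE, 43, 0.35, -2.92),
  # AMBP sits at albumin-like levels in PT (ratio to albumin ~1)
  p("AMBP_HUMAN", "AMBP", "Protein AMBP", "ECM_regulator", TRUE, 39, 1.10, -3.92),
  p("COCA1_HUMAN", "COL12A1", "Collagen alpha-1(XII) chain", "collagen", FALSE, 150, 0.45, -6.22),
  # no programmed tissue effect
  p("PGS2_HUMAN", "DCN", "Decorin", "proteoglycan", FALSE, 40, 0.70, 1, -1.22, 1),
  p("PRG4_HUMAN", "PRG4", "Proteoglycan 4 (lubricin)", "proteoglycan", FALSE, 120, 0.20, 1),
  p("CO2A1_HUMAN", "COL2A1", "Collagen alpha-1(II) chain", "collagen", FALSE, 140, 0.20, 1),
  p("TTHY_HUMAN", "TTR", "Transthyretin", "non_matrisome", TRUE, 16, 0.08, 1, 1, 1.83),
  p("MYOC_HUMAN", "MYOC", "Myocilin", "non_matrisome", FALSE, 57, 0.05, 1, 3.88, 1),
  p("ADH1B_HUMAN", "ADH1B", "Alcohol dehydrogenase 1B", "non_matrisome", FALSE, 40, 0.03, 1, -4.98, 1),
  p("TIMP3_HUMAN", "TIMP3", "Metalloproteinase inhibitor 3", "ECM_regulator", FALSE, 24, 0.05, 1),
  p("POSTN_HUMAN", "POSTN", "Periostin", "glycoprotein", FALSE, 93, 0.10, 1),
  p("ACTH_HUMAN", "ACTG2", "Actin, gamma-enteric smooth muscle", "non_matrisome", FALSE, 42, 0.06, 1, 1, 1.76),
  p("ANXA2_HUMAN", "ANXA2", "Annexin A2", "ECM_affiliated", FALSE, 39, 0.04, 1, 1, 1.56),
  p("TSP1_HUMAN", "THBS1", "Thrombospondin-1", "glycoprotein", FALSE, 129, 0.08, 1, 1, -2.04),
  p("ALBU_HUMAN", "ALB", "Serum albumin", "non_matrisome", TRUE, 69, NA, 1, 2.24, 2.48),
  # tissue-exclusive proteins (pct solved below to balance tissue sums)
  p("CO5A2_HUMAN", "COL5A2", "Collagen alpha-2(V) chain", "collagen", FALSE, 145, 0, Inf),
  p("COEA1_HUMAN", "COL14A1", "Collagen alpha-1(XIV) chain", "collagen", FALSE, 150, 0, Inf),
  p("PGCA_HUMAN", "ACAN", "Aggrecan core protein", "proteoglycan", FALSE, 150, 0, Inf),
  p("CSPG2_HUMAN", "VCAN", "Versican core protein", "proteoglycan", FALSE, 150, 0, Inf),
  p("MMP10_HUMAN", "MMP10", "Stromelysin-2", "ECM_regulator", FALSE, 54, 0, Inf),
  p("CO8A1_HUMAN", "COL8A1", "Collagen alpha-1(VIII) chain", "collagen", FALSE, 73, NA, 0),
  p("MMP3_HUMAN", "MMP3", "Stromelysin-1", "ECM_regulator", FALSE, 54, NA, 0, 1, -2.14),
  p("S10AA_HUMAN", "S100A10", "Protein S100-A10", "non_matrisome", FALSE, 11, NA, 0),
  # spiked surrogate standard (concentration handled by the generator, not the panel)
  p("ADH1_YEAST", "ADH1", "Alcohol dehydrogenase 1 (yeast), spiked standard", "non_matrisome", FALSE, 37, 0, 1)
)

# ---- synthetic sequences ----------------------------------------------------
panel$length <- pmax(60L, round(panel$mw_kda * 1000 / 110))
panel$sequence <- vapply(panel$length, rand_seq, character(1))
panel$mol_weight_da <- vapply(panel$sequence, seq_mass, numeric(1))

# ---- solve percentages ------------------------------------------------------
# COL6 chain molar ratios (fmol/ug units): ACL 2:1:6, PT 2:1:4 around a CO6A2 base
mw <- setNames(panel$mol_weight_da, panel$accession)
col6 <- c("CO6A1_HUMAN", "CO6A2_HUMAN", "CO6A3_HUMAN")
acl_mol <- c(2, 1, 6) * 0.040   # fmol/ug
pt_mol  <- c(2, 1, 4) * 0.030
pct_from_fmol <- function(fmol, acc) fmol * mw[acc] / 1e4   # 1 ug digest = 1e6 ng... pct = fmol*MW(Da)*1e-6 ng / 1000ng *100
col6_pct_acl <- pct_from_fmol(acl_mol, col6)
col6_pct_pt  <- pct_from_fmol(pt_mol, col6)

panel$pct_acl <- NA_real_
rownames(panel) <- panel$accession
panel[col6, "pct_pt"]  <- col6_pct_pt
panel[col6, "pct_acl"] <- col6_pct_acl

anchors <- c("CO1A1_HUMAN", "CO1A2_HUMAN", "CO3A1_HUMAN")
panel["CO1A1_HUMAN", "pct_acl"] <- 54.77 / 1.60
panel["CO1A2_HUMAN", "pct_acl"] <- 27.39 / 1.51
panel["CO3A1_HUMAN", "pct_acl"] <- 27.11

minor <- is.na(panel$pct_acl) & is.finite(panel$fc_tissue) & panel$fc_tissue != 0 &
  panel$accession != "ADH1_YEAST" & !is.na(panel$pct_pt)
fc_lin <- ifelse(panel$fc_tissue >= 1, panel$fc_tissue, -1 / panel$fc_tissue)
panel$pct_acl[minor] <- panel$pct_pt[minor] * fc_lin[minor]

acl_only <- c("CO5A2_HUMAN", "COEA1_HUMAN", "PGCA_HUMAN", "CSPG2_HUMAN", "MMP10_HUMAN")
pt_only  <- c("CO8A1_HUMAN", "MMP3_HUMAN", "S10AA_HUMAN")
acl_only_w <- c(0.30, 0.20, 0.45, 0.25, 0.02)   # relative weights, scaled to close the sum
pt_only_w  <- c(0.15, 0.05, 0.02)

fixed_pt  <- sum(panel$pct_pt[!(panel$accession %in% c(pt_only, "ALBU_HUMAN", "ADH1_YEAST"))])
fixed_acl <- sum(panel$pct_acl[!(panel$accession %in% c(acl_only, "ALBU_HUMAN", "ADH1_YEAST"))],
                 na.rm = TRUE)
alb <- 1.05                                     # serum albumin %, same in both tissues
pt_only_scale  <- (100 - alb - fixed_pt)  / sum(pt_only_w)
acl_only_scale <- (100 - alb - fixed_acl) / sum(acl_only_w)
stopifnot(pt_only_scale > 0, acl_only_scale > 0)
panel[pt_only, "pct_pt"]   <- pt_only_w * pt_only_scale
panel[pt_only, "pct_acl"]  <- 0
panel[acl_only, "pct_acl"] <- acl_only_w * acl_only_scale
panel[acl_only, "pct_pt"]  <- 0
panel["ALBU_HUMAN", c("pct_acl", "pct_pt")] <- alb
panel["ADH1_YEAST", c("pct_acl", "pct_pt")] <- 0

cat(sprintf("pct sums: ACL %.3f  PT %.3f\n", sum(panel$pct_acl), sum(panel$pct_pt)))
cat(sprintf("type I pct: ACL %.2f PT %.2f; type III: ACL %.2f PT %.2f\n",
            sum(panel[c("CO1A1_HUMAN","CO1A2_HUMAN"), "pct_acl"]),
            sum(panel[c("CO1A1_HUMAN","CO1A2_HUMAN"), "pct_pt"]),
            panel["CO3A1_HUMAN","pct_acl"], panel["CO3A1_HUMAN","pct_pt"]))

# concentrations in fmol per ug digest (1 ug = 1000 ng): fmol = pct/100*1000 / (MW*1e-6)
panel$conc_acl_fmol_ug <- panel$pct_acl * 1e4 / panel$mol_weight_da
panel$conc_pt_fmol_ug  <- panel$pct_pt  * 1e4 / panel$mol_weight_da

# ---- write fixtures ---------------------------------------------------------
fa <- file("inst/extdata/synthetic_proteins.fasta", "w")
for (i in seq_len(nrow(panel))) {
  cat(sprintf(">%s synthetic stand-in sequence (%s)\n", panel$accession[i], panel$gene[i]),
      file = fa)
  s <- panel$sequence[i]
  cat(gsub("(.{60})", "\\1\n", s), "\n", file = fa, sep = "")
}
close(fa)

out <- panel[, c("accession", "gene", "description", "matrisome_category", "blood_related",
                 "conc_acl_fmol_ug", "conc_pt_fmol_ug", "sex_fc_acl", "sex_fc_pt")]
num <- vapply(out, is.numeric, logical(1))
out[num] <- lapply(out[num], function(x) signif(x, 7))
write.table(out, "inst/extdata/synthetic_panel.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# annotation table: panel accessions plus a few extra study-context accessions
extra <- data.frame(
  accession = c("MMP11_HUMAN", "ATS7_HUMAN", "ADA15_HUMAN", "COGA1_HUMAN", "COLA1_HUMAN",
                "CO8A2_HUMAN", "CHAD_HUMAN", "TRFE_HUMAN", "APOA1_HUMAN", "SAMP_HUMAN"),
  gene = c("MMP11", "ADAMTS7", "ADAM15", "COL16A1", "COL21A1",
           "COL8A2", "CHAD", "TF", "APOA1", "APCS"),
  matrisome_category = c("ECM_regulator", "ECM_regulator", "ECM_regulator", "collagen",
                         "collagen", "collagen", "proteoglycan", "non_matrisome",
                         "non_matrisome", "non_matrisome"),
  blood_related = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
ann <- rbind(panel[, c("accession", "gene", "matrisome_category", "blood_related")], extra)
write.table(ann[order(ann$accession), ], "inst/extdata/matrisome_annotation.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("files written; fasta bytes:",
    file.size("inst/extdata/synthetic_proteins.fasta"), "\n")
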