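---
title: "Methods: label-free quantitation of ligament and tendon proteomes"
author: "tendomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: label-free quantitation of ligament and tendon proteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

tendomics implements the quantitative analysis used in label-free,
data-independent-acquisition (MSE) proteomics of dense connective tissue:
anterior cruciate ligament (ACL) and patellar tendon (PT) from male and
female donors. This vignette documents the statistical model, the tunable
parameters, the synthetic data generator that stands in for raw
mass-spectrometry data, and the numerical and design choices a maintainer
should know about.

## The data model

The unit of observation is one quantified peptide ion: a sample (analytical
run), an LC/LC fraction (1–8 in the default two-dimensional separation), a
peptide sequence (modified forms counted as distinct peptides), a protein
accession, an area-under-curve intensity, an identification score, and a
decoy flag. The study design behind the defaults is 2 tissues × 2 sexes ×
3 donors, with one subject per tissue analyzed twice, so each tissue
contributes 7 analytical runs over 6 subjects. Tissues are acquired and
processed independently; nothing in the analysis compares raw intensities
across tissues.

Missing cells are encoded as missing, never zero: a zero means "observed at
zero area" and enters sums, a missing cell means "not observed" and does
not.

## Identification filtering and QC

Peptide identifications are filtered by the target–decoy method. The FDR
estimator is the simple ratio `n_decoy / n_target` above a score threshold
(the alternative `2d/(t+d)` estimator is deliberately not used: the simple
ratio is more conservative and easier to reason about), and
`peptide_fdr_threshold()` returns the lowest threshold whose estimate is at
or below the target (default 2%). Both directions are available: a target
FDR gives a threshold, and any threshold's estimated FDR can be read off
the same curve.

Dataset-level QC mirrors standard practice for 2D-LC platforms:

* **Surrogate RSD** — the spiked standard (ADH1_YEAST, 25 fmol/µg in every
  sample) is rolled up to protein level and its relative standard deviation
  (100·sd/mean, sample SD with n−1) across runs summarizes platform
  precision. Duplicate runs are kept separate here on purpose: they are
  part of the precision being measured.
* **Fraction uniqueness** — the percentage of distinct peptides seen in
  exactly one LC fraction.
* **Per-fraction load** — peptide counts and total ion intensity per
  fraction, zero-filled.
* **PCA** — each peptide row is z-scored across runs (missing cells imputed
  with the row mean first, so they carry no signal; zero-variance rows are
  dropped and counted) and the run-space scores of the top 3 components are
  reported. Component signs are fixed by making the largest-magnitude
  loading positive, so results do not depend on row or column order.

## Relative quantitation: male vs female within tissue

Peptide intensities are summed across fractions (`merge_fractions()`), then
across peptides per protein (`rollup()`); the duplicate-run subject is
averaged to one column (`average_duplicates()`; a protein seen in only one
of the two runs keeps its observed value). Per protein and tissue:

* **Fold change** is the ratio of linear-scale male and female group means,
  printed in the signed convention (a ratio of 0.5 prints as −2), computed
  on the duplicate-averaged subject intensities.
* **Significance** comes from a one-way fixed-effects ANOVA on log2
  intensities with per-observation inverse-variance weights
  (`error_weighted_anova()`). The weights model intensity-dependent
  technical variance: for every protein present in both runs of a
  duplicate pair, half the squared log2 run difference estimates the
  technical variance at that mean log2 intensity; those points are smoothed
  with `lowess` and the curve (floored at its own 5th percentile to avoid
  exploding weights) supplies each observation's variance. When a dataset
  has no duplicate runs the weights fall back to units, in which case the
  test is exactly the textbook one-way ANOVA — this fallback is also the
  behaviour verified against an independent sums-of-squares oracle in the
  tests.
* **Multiplicity** is handled by Benjamini–Hochberg step-up FDR adjustment
  within each tissue's protein list (the tissues are independent
  analyses). Hochberg's FWER step-up is available as an option
  (`p_adjust = "hochberg"`); the default follows the named
  Benjamini–Hochberg procedure.
* **Effect size** is Cohen's d with pooled SD, computed on the same log2
  scale as the ANOVA so the two statistics describe the same comparison.
* **Curation** requires all three of: more than one peptide, adjusted
  p < 0.05, and |d| > 0.8 (a "large" effect).

Degenerate inputs are handled explicitly: when every group has zero
within-group spread the F statistic is undefined, and the p-value is
reported as the machine floor (distinct group means) or 1 (identical), with
a `degenerate` attribute. Zero pooled SD in Cohen's d yields a
signed-infinity sentinel; identical groups yield 0.

## Absolute quantitation: top-3 against the spiked standard

Because the two tissue datasets cannot be aligned at the intensity level,
cross-tissue comparison goes through "Hi3" absolute quantification:

1. For each protein with at least two peptides, the 3 most intense
   ("best flier") peptides are selected once per tissue dataset, so every
   sample is quantified on the same peptides. The ranking statistic is the
   peptide's mean across runs of *within-run-normalized* intensity (each
   run divided by its total signal). Raw means would make the selection —
   and therefore the whole quantification — sensitive to a global
   rescaling of a single run; normalized ranking is scale-invariant and
   identical to raw ranking in the noise-free limit. Ties at rank k are
   broken by lexicographically smallest peptide sequence, so selection is
   deterministic. Proteins with exactly two peptides are quantified on
   both (`n_peptides_used = 2`); proteins with one peptide are excluded.
2. The standard's known on-column amount is
   `spike_fmol_per_ug × injected_mass_ug` (25 × 3 = 75 fmol at the
   defaults), giving a per-sample response factor in counts/fmol; protein
   amounts follow as `fmol = top3 / response` and
   `ng = fmol × MW × 10⁻⁶`, with molecular weights computed from FASTA
   sequences as sums of average residue masses plus water (modifications
   ignored — their mass contribution is far inside the method's two-fold
   accuracy envelope).
3. Per sample, each protein's mass is expressed as percent of the summed
   quantified native protein mass ("percent of dry weight"); the spiked
   standard is excluded from numerator and denominator, and percentages
   sum to 100 by construction. The alternative denominator — the weighed
   tissue aliquot — would require assuming complete extraction and
   quantification; the summed-protein denominator is self-contained and is
   the package's default.

Tissue comparisons (`compare_tissues()`) are made on percent dry weight for
proteins quantified in both tissues: signed fold change of means, two-sided
pooled-variance t-test and Cohen's d on log2 percent (the same scale
convention as the relative arm), across all six subjects and sex-stratified
at n = 3. Ratio analyses divide per-donor amounts first and then average:
the type I : III collagen ratio is the mean ± SD of per-donor
`(CO1A1+CO1A2)/CO3A1` percent ratios (means of per-donor ratios and ratios
of means differ noticeably at these spreads, and the per-donor form is the
one whose dispersion is reportable), and type VI chain ratios are per-donor
molar (fmol) ratios normalized to the α2(VI) chain. Albumin-relative
enrichment divides each protein's percent dry weight by albumin's in the
same subject; a group-mean ratio at or above 1 flags a blood-associated
protein as enriched in the tissue rather than carried in residual blood.

## The synthetic data generator

`simulate_dataset()` generates peptide-level datasets with the statistical
structure the analysis assumes, plus a ground-truth ledger, so every stage
is testable without any raw data download. What it emulates:

* the full study design (2 × 2 × 3 with per-tissue duplicate runs, 8
  fractions, ADH1_YEAST at 25 fmol/µg, 3 µg on column);
* a collagen-dominated composition: the bundled panel of ~50 proteins
  (synthetic stand-in sequences of roughly the right mass; concentrations
  in fmol/µg) puts type I collagen near 52% of ACL and 82% of PT dry
  weight, type III near 27% and 7%, programs the known tissue fold
  changes, per-tissue sex effects, tissue-exclusive proteins, type VI
  chain molar ratios of about 2:1:6 (ACL) and 2:1:4 (PT), and AMBP at
  albumin-like levels in PT;
* per-peptide ionization efficiencies drawn once (log-normal, sdlog 0.9)
  and shared across samples, which produces stable "flier" peptides; each
  protein's top-min(3, n) efficiencies are rescaled to average exactly 1,
  so Hi3 quantification is exact in the noise-free limit and any noise in
  the estimates is attributable to the noise model;
* multiplicative log-normal intensity noise (default σ = 0.25 on the
  natural-log scale). At this setting the protein-level surrogate RSD
  lands around 10% per tissue, between the two values a well-behaved
  2D-LC platform produces on these tissues;
* deterministic fraction assignment by hashing the peptide sequence, with
  a 17% minority split 60/40 across two adjacent fractions (~83% of
  peptides fraction-unique);
* intensity-dependent dropout (logistic in log intensity, mean rate 5%);
* decoy identifications at 0.3 per target peptide, scored from a standard
  normal null, with target scores shifted up by 3.5.

What it does **not** emulate, and what passing tests therefore do not show
about real data: donor-level biological variance (all within-group spread
is technical, so the generator's power at n = 3 is optimistic — programmed
fold changes below ~1.3 are recovered less often than the larger ones, and
real biological scatter would lower power further); chromatographic
retention structure (fractions are hashes, not elution profiles);
peptide-modification mass shifts; interference/co-elution; and
search-engine score distributions beyond a two-normal location family.

Determinism: every stochastic step runs under the single seed in the
configuration, fraction assignment is hash-based rather than RNG-based, and
the generator restores the session RNG state on exit. Identical
configuration and seed reproduce datasets — and entire pipeline output
directories — byte for byte.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `target_fdr_pct` | 2 | % | decoy-estimated peptide FDR target |
| `alpha` | 0.05 | — | adjusted-p curation threshold |
| `min_d` | 0.8 | — | minimum absolute Cohen's d ("large") |
| `min_peptides` | 2 | count | minimum peptides per curated protein |
| `top_k` | 3 | count | peptides for Hi3 quantification |
| `spike_fmol_per_ug` | 25 | fmol/µg | surrogate spike level |
| `injected_mass_ug` | 3 | µg | digest mass on column |
| `sigma` | 0.25 | ln-scale SD | generator intensity noise |
| `multi_fraction_rate` | 0.17 | fraction | peptides split across 2 fractions |
| `dropout_rate` | 0.05 | fraction | mean intensity-weighted missingness |
| `decoy_rate` | 0.3 | per target | decoy records per target peptide |
| `score_separation` | 3.5 | score SD | target vs decoy score shift |

## Problem sizes used in the test suite

The packaged tests run the statistical calibration checks at desk scale,
chosen to give tight Monte-Carlo error while keeping the default suite
under a minute: conservation and envelope checks on full default-panel
simulations (~2,300 target peptides, 14 runs); a 1,000-protein null for
p-value uniformity and type-I error at n = 3 per group, σ = 0.2; 40
repetitions of 1,000 + 1,000 target/decoy score draws for FDR calibration;
and 200 repeated small-panel simulations for fold-change recovery at
σ = 0.2. The two-fold Hi3 accuracy envelope is checked at σ = 0.3, a noise
level above the default.

## Known limitations

* The error-weighting scheme reconstructs a proprietary algorithm's intent
  (inverse-variance weights from an intensity-dependent technical error
  curve) rather than its exact form; with a single duplicate pair per
  tissue the curve is coarse, and the unit-weight fallback is the
  better-characterized path.
* Protein inference is out of scope: peptides shared between homologous
  proteins stay with the accession the input assigns.
* Absolute amounts inherit the Hi3 method's ~two-fold accuracy envelope;
  dry-weight percentages are relative to quantified protein, not to tissue
  wet or dry mass.
* With n = 3 per group the curated list controls type I error but is
  underpowered for fold changes below roughly 1.3; curated counts should
  be read with that in mind.
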