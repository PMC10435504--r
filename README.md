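# spaceclone

Spatial subclonal architecture of multiple myeloma from paired-site bulk
and single-cell sequencing.

Multiple myeloma spreads through the bone marrow both diffusely and as
focal lesions. A single iliac-crest aspirate (RBM) can miss tumor subclones
that dominate a focal lesion (FL). `spaceclone` quantifies that spatial
heterogeneity from paired-site data:

* **Cancer clonal fractions (CCF)** per SNV from bulk whole-genome allele
  counts, via the mutation copy number
  `n_mut = f_s · (1/p) · [p·n_locus + 2(1−p)]` with binomial
  maximum-likelihood multiplicity `n_chr` and a Wilson 95% interval;
  `CCF = n_mut / n_chr`.
* **Paired-site classification** of SNVs and copy-number events into
  shared / unshared / enriched (and major/minor by whether the CCF CI
  reaches 1), with the study's thresholds: CCF retention filter 0.15,
  CNA length filter 200 kb, segment-CCF cut 0.6, threefold enrichment.
* **WGS-supervised CNA-subclone detection** in single-cell RNA
  (expression averages over subclonal regions, reference-centered) and
  ATAC (10 Mb bin z-scores vs normal plasma cells), Ward clustering with a
  genotype-saturation dendrogram cut, and cross-modality/WGS confirmation.
* **Single-cell peak co-accessibility** at single-cell resolution with a
  shuffled-background threshold (99th percentile of per-shuffle maxima)
  and percent-accessible evaluation.
* **TCR repertoire rules**: clonotype assembly with single-chain merging,
  expansion (≥1%, ≥5 cells) and hyperexpansion (≥5%), the ≥10-cell pairing
  filter and threefold spatial cut-off, and gene-set module scores.
* **Paired microenvironment composition** with exact signed-rank tests and
  the ≥2.5-fold / p < 0.05 depletion flag.

Patient-level data of this kind are controlled-access, so the package
ships a synthetic paired-site cohort generator with full ground truth
(clone tree, multiplicities, subclone labels, clonotype frequencies); all
tests and analyses run against it.

## Worked example

Estimate the CCF of a variant with 25 alt reads out of 100 at purity 0.5
on a diploid locus:

```r
library(spaceclone)
estimate_ccf(alt = 25, total = 100, purity = 0.5, n_locus = 2)
#>   alt total  f_s purity n_locus n_mut n_chr ccf    ci_low  ci_high detected cn_conflict
#> 1  25   100 0.25    0.5       2     1     1   1 0.7018085 1.372179     TRUE       FALSE
```

The VAF 0.25 maps to mutation copy number 1 at multiplicity 1: a clonal
heterozygous variant (CCF = 1, clonal-compatible since the CI upper bound
exceeds 1).

The `analysis/` directory holds the numbered workflow over the synthetic
cohort (outputs under `results/`):

```sh
Rscript analysis/01_simulate_cohort.R     # 8 patients, paired RBM/FL bulk
Rscript analysis/02_ccf_heterogeneity.R   # CCFs + shared/unshared/enriched
Rscript analysis/03_sc_subclones.R        # scRNA + scATAC subclone calling
Rscript analysis/04_coaccessibility.R     # permutation-thresholded links
Rscript analysis/05_tcr_repertoire.R      # clonotypes, expansion, spatial
Rscript analysis/06_tme_report.R          # composition tests + reports
```

`02` prints, per patient, the retained SNV count, the heterogeneous
fraction (unshared + enriched over retained) and the recovery of the
generator's ground-truth classes, e.g.:

```
P03: 152 retained SNVs, 60.5% heterogeneous, accuracy 100.0%
...
cohort mean heterogeneous fraction: 50.7%
```

`03` recovers all four planted subclones in both modalities
(`RNA: k = 4, labels S1 S2 S3 S4, per-cell agreement 99.3%`), confirms
them across modalities, and flags the two RBM-unique subclones in the
composition table. `04` shows a calibrated null (0% significant links on
independent data at the 99th-percentile threshold) and recovers a planted
co-accessible pair (r = 0.81) only in the group it was planted in.

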