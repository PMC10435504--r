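---
title: "Quantifying spatial subclonal architecture in myeloma from paired-site sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spatial subclonal architecture in myeloma from paired-site sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spaceclone)
```

## The problem

Multiple myeloma grows both as diffusely infiltrating plasma cells in the
bone marrow and as focal lesions — nodular accumulations scattered through
the skeleton. A biopsy of the iliac crest (a "random" bone marrow aspirate,
RBM) may therefore miss tumor subclones that dominate a focal lesion (FL),
and vice versa. `spaceclone` implements the quantitative machinery to
measure this spatial heterogeneity from paired-site data: bulk whole-genome
allele counts, single-cell RNA and ATAC matrices, TCR contigs, and
microenvironment cell-type annotations. Because real patient-level data of
this kind are controlled-access, the package also ships a synthetic cohort
generator with complete ground truth; all tests and the acceptance script
run against it.

## Cancer clonal fraction from bulk allele counts

For an SNV observed at variant allele frequency $f_s$ in a sample of purity
$p$ with tumor total copy number $n_{locus}$ at the locus, the mutation copy
number is

$$n_{mut} = f_s \frac{1}{p}\left[p\,n_{locus} + 2(1-p)\right].$$

The multiplicity $n_{chr}$ (how many chromosome copies carry the mutation)
is assigned by maximum likelihood: each candidate $C \in \{1..n_{locus}\}$
predicts an expected VAF $Cp/(p\,n_{locus}+2(1-p))$ (capped at 1), which is
scored by the binomial likelihood of the observed read counts; ties go to
the smaller $C$. The cancer clonal fraction is $CCF = n_{mut}/n_{chr}$.
Expected VAFs above 1 are capped before scoring, and the likelihood is
evaluated analytically (in log space) so exact non-integral expectations
can be scored; for integer counts it is identical to `dbinom`.

The paper-style procedure does not fix a CI construction; we use a Wilson
score interval on $f_s$ at 95% and push it through the (monotone)
$n_{mut}$ map with $n_{chr}$ held fixed. Wilson is closed-form and behaves
at $f_s$ near 0 and 1, which matters because the major/minor grading below
depends on the upper bound reaching 1. CCF point estimates can exceed 1 and
are reported uncapped.

## Paired-site classification

SNVs are retained when the estimated CCF exceeds 0.15 in at least one of
the paired samples; classification is then applied to retained variants:

* **major / minor** — the upper 95% bound of the dominant (higher-CCF)
  site reaches 1, i.e. the call is compatible with clonality there.
* **unshared** — undetectable at the partner site. "Undetectable" is made
  explicit as: partner CCF below 0.05 *and* no more variant reads than the
  sequencing error rate explains (`alt <= 1 + total * err_rate`, default
  error 1e-3). This mirrors re-counting reads in both samples before
  declaring absence.
* **enriched** — detected at both sites, major at the dominant site, and a
  CCF point-estimate ratio of at least 3 (ties at exactly 3 count).
* **shared** — retained, neither unshared nor enriched.

Copy-number events shorter than 200 kb are dropped; segment CCF 0.6
separates major from minor events; an event with CCF > 0.6 in one sample
that is a minor subclone (0 < CCF <= 0.6) in the partner is the
"dominant-in-one-sample" class; cross-sample matching uses 50% reciprocal
interval overlap restricted to the same direction of change. The
heterogeneous fraction of a pair is (unshared + enriched) / retained.

## The synthetic cohort

The generator encodes the study conditions rather than exposing free dials:

* two sites per patient, bulk depth Poisson around **85x**, purity drawn
  per patient in **0.5–0.9**;
* a clone tree with one truncal root; derived subclones own private SNVs
  (25 each; 60 truncal) and one large CNA each (0.7–0.9 of a chromosome,
  gains and losses alternating); two short (150 kb) decoy events exercise
  the length filter;
* expected VAFs from the inverted mutation-copy-number relation, mixed
  with a symmetric substitution error (default 1e-3) so absence calls are
  non-trivial;
* site prevalences drawn from gamma weights, with flagged site-unique
  subclones dominant at their home site (prevalence 0.75–0.9, as dominant
  lesion-unique clones are in practice). Draws below **0.25** are rounded
  to absence: at 85x a subclone below CCF ~0.25 is at the edge of
  detectability, and the floor keeps planted CCFs clearly separated from
  the 0.15 retention filter so every SNV has a well-defined ground-truth
  class. Multiplicity above 1 arises only on clonally gained loci.
* single-cell counts: negative binomial for RNA (size 10), Poisson for
  ATAC tiles, with the mean scaled by $1 + (CN-2)(d-1)$ per feature —
  at the default per-copy dosage effect $d = 1.5$ a single-copy gain
  multiplies means by 1.5 and a single-copy loss by 0.5. The synthetic
  transcriptome has 22 chromosomes with 500 genes each (~5,500 UMIs per
  cell at the default depth, matching droplet scRNA-seq of plasma cells);
  a block of neutral normal-plasma-cell reference cells is always present.
* QC metadata are simulated with a small (~4%) failing fraction per rule so
  the published thresholds (mito > 5%, genes outside [200, 5000], doublet
  score > 0.3; ATAC TSS < 8, fragments < 3000, doublet enrichment > 6,
  predicted doublet score > 200) remove someone.

What the generator does **not** emulate: linked read structure, phasing,
germline variation, transcriptional covariance between genes (counts are
independent given copy number and depth), doublet transcriptomes (doublets
exist only as a score column), chromatin peak structure within tiles, and
real reference genomes. Passing tests therefore demonstrate that the
statistical machinery recovers planted signal under the stated noise
models — not performance on real data.

## Single-cell subclone detection

Only regions subclonal by bulk WGS (0 < segment CCF < 0.95 at one or more
sites) are interrogated — the analysis is deliberately supervised.

**RNA signal.** Counts per 10k + `log1p`, per-gene centering on the
reference-cell mean, a running mean over 51 genes along genomic order
(edge-truncated), then per-cell median centering: the log1p/depth
interaction leaves a per-cell offset that would leak correlated noise into
every region, and subtracting each cell's genome-wide median removes it
(most of the genome is neutral). The region signal is the mean over member
genes (assigned by midpoint); regions with fewer than 20 expressed genes
are dropped.

**ATAC signal.** Overlapping 10 Mb bins at a 5 Mb step; per-cell fragment
fractions per bin; z-scores against the reference-cell mean and SD (bins
with zero reference variance are excluded); the region signal is the mean
z over overlapping bins.

**Clustering.** Ward (`ward.D2`) linkage on Euclidean distances over the
cell-by-region matrix, with each region divided by its reference-cell SD so
regions contribute in comparable noise units. The dendrogram cut is chosen
by *genotype saturation*: over cuts $k$ in [2, candidates + 1], the cut
revealing the most distinct called genotypes among clusters of at least 10
cells wins, ties broken by the higher mean silhouette width and then the
smaller $k$. We initially selected $k$ by maximal silhouette alone, but a
small genotype-distinct cluster — exactly the "one modality suggests an
extra subclone" situation the confirmation rule exists for — is
systematically absorbed by the silhouette optimum (gaps of 0.05–0.08 in
mean width), so maximal silhouette proved the wrong surrogate for the
WGS-guided visual dendrogram inspection it replaces; silhouette remains as
the tie-breaker and is reported per cut.

**Genotype calls.** A cluster's genotype is the sign of its mean region
signal thresholded at ±tau: tau = 0.1 in centered log-expression units
(RNA). For z-score signals the same rule is applied at tau = 1, since the
signal is already in reference-noise units and compositional coupling of
bin fractions produces systematic |z| up to ~0.3 on non-carried regions.
Clusters matching a candidate genotype (from WGS) exactly take its label;
others are provisional.

**Confirmation.** A genotype is confirmed when it matches a WGS-consistent
candidate, or when the identical genotype is independently recovered in the
second modality. Provisional genotypes with neither support are excluded —
the package reproduces this on planted one-modality artifact populations
(a cell population carrying only part of another subclone's event set),
which are detected as provisional clusters and excluded in 100% of seeded
runs.

Per-site composition marks a subclone site-unique when the other site has
fewer than 5 cells and under 1% of that site's cells (the uniqueness floor
is our choice; uniqueness is otherwise qualitative), and
plasticity-eligible at more than 50 cells per site.

## Co-accessibility

Peak–peak Pearson correlation across single cells without aggregation,
binarized (`count > 0`) by default because sparse single-cell ATAC signal
is close to binary; a raw-count mode exists. Pairs are scored within a 250 kb
center-to-center window. Significance uses a shuffled background: the
accessibility values are permuted jointly over the cells-by-peaks matrix,
all within-window correlations are recomputed, and the maximum per shuffle
is recorded; the threshold is the 99th percentile of the per-shuffle maxima
(100 shuffles by default). The alternative reading — the 99th percentile of
the pooled shuffled correlations — is implemented as `mode = "pooled"`; the
max-based reading is the default because it controls the family-wise error
of the strongest link, which is how a single threshold over all pairs is
used. Links must additionally be accessible in at least 5% of cells at
both peaks.

## TCR repertoire rules

Productive contigs with non-empty CDR3 define clonotypes by the (TRA, TRB)
pair; a single-chain cell merges into a clonotype only when its chain
matches exactly one clonotype's corresponding chain (ambiguous matches stay
singletons — the original analysis does not describe its resolution, and
refusing to guess inflates no clone). Expansion: at least 1% of the site's
T cells at one or more sites *and* at least 5 cells in one of the paired
samples; hyperexpansion at 5% with the same count floor. The proportion
denominator is per-site totals (the pooled reading is available as an
option). Pairing comparisons consider clonotypes with at least 10 cells at
one site; a threefold proportion difference flags spatial variation, with a
0.5-cell pseudocount when one side is zero but the clone is not
site-unique. Module scores (exhaustion, cytotoxicity) are the conventional
target-minus-matched-controls score with 24 average-expression bins and 100
control genes per target, seeded.

## Microenvironment composition

Per patient and site, cell-type proportions; per cell type, an exact
two-sided Wilcoxon signed-rank test on the paired per-patient proportions.
The exact null is computed by generating-function convolution over the
(mid)ranks — mathematically the full $2^n$ sign enumeration — because the
cohorts are 6–8 pairs where the normal approximation is visibly wrong
(6 uniformly-directed pairs give exactly $p = 2/64 = 0.03125$). Zero
differences are dropped; ties use midranks; beyond 25 pairs the
tie-corrected normal approximation takes over. Flags combine a fold change
of mean proportions of at least 2.5 with raw $p < 0.05$; Benjamini-Hochberg
adjusted values are reported alongside because whether the original
analysis adjusted across cell types is not stated.

## Problem sizes

The test-suite sizes are the package's own choices to keep runs fast while
preserving the study conditions: unit tests use a 10-chromosome genome with
100–150 genes per chromosome and 200–500 cells; the acceptance checks use
the 8-patient cohort at full depth/purity conditions, an 800-cells-per-site
patient on the 22-chromosome genome for subclone recovery, 20 seeded
artifact runs on an 8-chromosome genome with 400 genes per chromosome, and
a 1000-cell × 50-peak matrix with 100 shuffles for the co-accessibility
null.

## Known limitations

* CCF estimation takes purity as an input; it is not re-estimated from VAF
  histograms.
* The locus copy number entering the CCF equation is the sample-level ACE-style
  total; the generator avoids placing SNVs inside subclonal CNAs so the
  diploid/clonal value is well defined. Real data with SNVs inside
  subclonal CNAs inherit the usual ambiguity of the equation.
* Subclone detection is supervised by WGS regions; it cannot discover CNAs
  absent from the bulk segmentation (by design).
* The exact signed-rank test assumes exchangeable signs under the null, as
  the standard test does.
* The genotype-saturation cut assumes candidate genotypes are roughly
  balanced in at least ~10 cells; rarer subclones are not resolvable.
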