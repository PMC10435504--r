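#!/usr/bin/env Rscript
# Simulate the paired-site cohort (8 patients, RBM + focal lesion, 85x bulk
# depth, purity 0.5-0.9, a site-unique subclone in 3 patients) and write the
# bulk layer plus ground truth under results/cohort/.
#
# Every downstream script regenerates the same cohort from COHORT_SEED, so
# the written tables are for inspection, not hand-off.

suppressPackageStartupMessages(library(spaceclone))

COHORT_SEED <- 11L
out <- "results/cohort"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

coh <- simulate_cohort(8, seed = COHORT_SEED, n_unique_patients = 3,
                       purity_range = c(0.5, 0.9))

truth <- list()
for (pt in coh) {
  pdir <- file.path(out, pt$patient)
  for (s in pt$config$sites)
    write_bulk_site(pt$bulk[[s]], pdir, s)
  truth[[pt$patient]] <- list(
    purity = unname(pt$config$purity[[1]]),
    n_subclones = nrow(pt$tree$subclones),
    site_unique_subclone = if (pt$has_unique)
      which(pt$tree$subclones$site_unique) else NULL,
    prevalence = as.data.frame(pt$tree$prevalence)
  )
  cat(sprintf("%s: %d subclones, purity %.2f%s\n", pt$patient,
              nrow(pt$tree$subclones), pt$config$purity[[1]],
              if (pt$has_unique) ", one site-unique subclone" else ""))
}
jsonlite::write_json(truth, file.path(out, "truth.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("wrote", out, "\n")
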