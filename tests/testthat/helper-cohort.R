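# shared fixtures: a small genome keeps unit tests fast; acceptance tests
# build their own study-scale objects

tiny_genome <- function(n_chrom = 10, chrom_length = 5e7,
                        genes_per_chrom = 100) {
  sim_genome(n_chrom = n_chrom, chrom_length = chrom_length,
             genes_per_chrom = genes_per_chrom)
}

tiny_config <- function(seed = 1L, genome = tiny_genome(),
                        n_cells = c(rna = 200L, atac = 200L),
                        n_ref_cells = 60L, n_truncal_snvs = 20L,
                        n_snvs_per_subclone = 10L, ...) {
  sim_config(seed = seed, genome = genome, n_cells = n_cells,
             n_ref_cells = n_ref_cells, n_truncal_snvs = n_truncal_snvs,
             n_snvs_per_subclone = n_snvs_per_subclone, ...)
}

# one-row ccf_estimate stub with chosen fields, for classifier unit tests
fake_estimate <- function(ccf, ci_high = ccf + 0.2, alt = round(ccf * 40),
                          total = 85, detection_floor = 0.05) {
  out <- data.frame(alt = alt, total = total, f_s = alt / total,
                    purity = 1, n_locus = 2, n_mut = ccf, n_chr = 1,
                    ccf = ccf, ci_low = max(0, ccf - 0.2), ci_high = ci_high,
                    detected = ccf > detection_floor, cn_conflict = FALSE)
  class(out) <- c("ccf_estimate", class(out))
  out
}

# simulate one patient's bulk + regions + candidates on a given config
sim_patient_bulk <- function(seed, config, n_subclones = 4,
                             site_unique = NULL, n_cna_per_subclone = 1L,
                             n_small_events = 2L) {
  tree <- simulate_clone_tree(n_subclones, 2, site_unique = site_unique,
                              seed = seed, config = config,
                              n_cna_per_subclone = n_cna_per_subclone)
  cna <- place_cna_events(tree, config, seed = seed,
                          n_small_events = n_small_events)
  snvs <- place_snvs(tree, config, cna, seed = seed + 1L)
  bulk <- lapply(stats::setNames(config$sites, config$sites), function(s)
    simulate_bulk_reads(tree, config, s, snvs = snvs, cna_events = cna))
  regions <- wgs_subclonal_regions(lapply(bulk, `[[`, "segments"))
  list(tree = tree, cna = cna, snvs = snvs, bulk = bulk, regions = regions,
       candidates = candidate_genotypes(tree, cna, regions$event_id))
}
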