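test_that("QC filters apply the published thresholds", {
  cells <- data.frame(
    cell = paste0("c", 1:5), site = "RBM", modality = "rna",
    reference = FALSE, subclone = 1L,
    mito_frac = c(0.06, 0.03, 0.03, 0.03, 0.03),
    n_features = c(1000, 250, 150, 6000, 1000),
    doublet_score = c(0.1, 0.1, 0.1, 0.1, 0.5))
  mat <- structure(list(counts = Matrix::Matrix(0, 2, 5, sparse = TRUE,
                                                dimnames = list(NULL, cells$cell)),
                        features = data.frame(gene = c("a", "b")),
                        cells = cells, modality = "rna"),
                   class = "cell_feature_matrix")
  out <- qc_filter_cells(mat)
  expect_equal(out$cells$cell, "c2")     # inside all bounds
  expect_setequal(out$qc_log$reason[out$qc_log$cell == "c1"], "high_mito")

  acells <- data.frame(
    cell = paste0("a", 1:4), site = "FL", modality = "atac",
    reference = FALSE, subclone = 1L,
    tss_score = c(7.5, 10, 10, 10),
    n_fragments = c(5000, 2000, 5000, 5000),
    doublet_enrichment = c(1, 1, 7, 1),
    doublet_score_pred = c(10, 10, 10, 300))
  amat <- structure(list(counts = Matrix::Matrix(0, 2, 4, sparse = TRUE,
                                                 dimnames = list(NULL, acells$cell)),
                         features = data.frame(gene = c("a", "b")),
                         cells = acells, modality = "atac"),
                    class = "cell_feature_matrix")
  aout <- qc_filter_cells(amat)
  expect_equal(nrow(aout$cells), 0)      # every cell violates one rule

  bad <- mat; bad$cells$mito_frac <- NULL
  expect_error(qc_filter_cells(bad), "mito_frac")
})

test_that("RNA region signal separates carriers and centers references", {
  cfg <- tiny_config(11, genome = tiny_genome(genes_per_chrom = 150))
  pb <- sim_patient_bulk(11, cfg, n_subclones = 3)
  ms <- lapply(cfg$sites, function(s)
    simulate_sc_counts(pb$tree, cfg, s, "rna", cna_events = pb$cna,
                       n_cells = 250))
  mat <- do.call(merge_cell_matrices, lapply(ms, qc_filter_cells))
  sig <- region_signal_rna(mat, pb$regions)

  # reference cells center at 0 in every region
  expect_true(all(abs(colMeans(sig[mat$cells$reference, , drop = FALSE]))
                  < 0.02))

  # carriers of each event separate from non-carriers in the right direction;
  # the direct group-mean oracle on the same matrix reproduces the sign
  for (k in seq_len(nrow(pb$regions))) {
    ev <- pb$regions$event_id[k]
    owner <- pb$cna$owner[pb$cna$event_id == ev]
    tum <- !mat$cells$reference
    carrier <- tum & mat$cells$subclone == owner
    noncar <- tum & mat$cells$subclone != owner
    if (!any(carrier) || !any(noncar)) next
    diff <- mean(sig[carrier, ev]) - mean(sig[noncar, ev])
    expect_equal(sign(diff), pb$regions$direction[k], info = ev)

    # oracle: unsmoothed centered normalized means over region genes
    counts <- as.matrix(mat$counts)
    depth <- colSums(counts); norm <- log1p(t(t(counts) / depth * 1e4))
    cen <- norm - rowMeans(norm[, mat$cells$reference, drop = FALSE])
    inside <- mat$features$chrom == pb$regions$chrom[k] &
      mat$features$mid >= pb$regions$start[k] &
      mat$features$mid < pb$regions$end[k]
    odiff <- mean(cen[inside, carrier]) - mean(cen[inside, noncar])
    expect_equal(sign(odiff), sign(diff), info = ev)
  }
})

test_that("regions with too few genes are dropped with a warning", {
  cfg <- tiny_config(12)
  pb <- sim_patient_bulk(12, cfg, n_subclones = 2)
  m <- simulate_sc_counts(pb$tree, cfg, "RBM", "rna", cna_events = pb$cna,
                          n_cells = 100)
  tiny_region <- data.frame(chrom = pb$regions$chrom[1], start = 0,
                            end = 1e6, event_id = "tiny", direction = 1)
  expect_warning(sig <- region_signal_rna(m, tiny_region), "dropped")
  expect_equal(ncol(sig), 0)
})

test_that("ATAC bin z-scores standardise on the reference population", {
  cfg <- tiny_config(13)
  pb <- sim_patient_bulk(13, cfg, n_subclones = 3)
  m <- simulate_sc_counts(pb$tree, cfg, "RBM", "atac", cna_events = pb$cna,
                          n_cells = 250)
  fr <- fragments_from_tiles(m)
  ref <- m$cells$cell[m$cells$reference]
  sig <- region_signal_atac(fr, pb$regions, cfg$genome$chrom_lengths, ref)
  z <- attr(sig, "bin_z")
  zr <- z[rownames(z) %in% ref, , drop = FALSE]
  expect_true(all(abs(colMeans(zr)) < 0.05))
  expect_true(all(abs(apply(zr, 2, sd) - 1) < 0.1))

  # a loss carried by a subclone present at this site gives negative z
  losses <- pb$regions[pb$regions$direction == -1 &
                         pb$regions$ccf_RBM > 0, , drop = FALSE]
  if (nrow(losses)) {
    ev <- losses$event_id[1]
    owner <- pb$cna$owner[pb$cna$event_id == ev]
    carrier <- m$cells$cell[!m$cells$reference & m$cells$subclone == owner]
    expect_lt(mean(sig[rownames(sig) %in% carrier, ev]), 0)
  }

  bad <- fr; bad$end[1] <- cfg$genome$chrom_lengths[[bad$chrom[1]]] + 10
  expect_error(region_signal_atac(bad, pb$regions,
                                  cfg$genome$chrom_lengths, ref),
               "outside chromosome bounds")
  expect_error(region_signal_atac(fr, pb$regions,
                                  cfg$genome$chrom_lengths, character(0)),
               "reference")
})

test_that("planted genotypes are recovered by supervised clustering", {
  # two well-separated genotypes, strong dosage -> perfect recovery
  cfg <- tiny_config(14, dosage_effect = 3,
                     genome = tiny_genome(genes_per_chrom = 150))
  pb <- sim_patient_bulk(14, cfg, n_subclones = 2)
  ms <- lapply(cfg$sites, function(s)
    simulate_sc_counts(pb$tree, cfg, s, "rna", cna_events = pb$cna,
                       n_cells = 250))
  mat <- do.call(merge_cell_matrices, lapply(ms, qc_filter_cells))
  asn <- detect_subclones(mat, pb$regions, pb$candidates)
  truth <- paste0("S", asn$cells$subclone)
  expect_equal(mclust::adjustedRandIndex(asn$subclone, truth), 1)
  expect_setequal(asn$labels, c("S1", "S2"))
})

test_that("four subclones are recovered as distinct clusters", {
  cfg <- tiny_config(15, genome = tiny_genome(n_chrom = 8,
                                              chrom_length = 8e7,
                                              genes_per_chrom = 250),
                     n_cells = c(rna = 400L, atac = 400L),
                     n_ref_cells = 100L)
  pb <- sim_patient_bulk(15, cfg, n_subclones = 4)
  ms <- lapply(cfg$sites, function(s)
    simulate_sc_counts(pb$tree, cfg, s, "rna", cna_events = pb$cna))
  mat <- do.call(merge_cell_matrices, lapply(ms, qc_filter_cells))
  asn <- detect_subclones(mat, pb$regions, pb$candidates)
  expect_setequal(asn$labels, paste0("S", 1:4))
})

test_that("degenerate input collapses to a single cluster", {
  sig <- matrix(0, 60, 2, dimnames = list(paste0("c", 1:60), c("r1", "r2")))
  asn <- cluster_subclones(sig, candidates = list(S1 = c(r1 = 0L, r2 = 0L)))
  expect_equal(asn$k, 1L)
  expect_true(asn$degenerate)
  expect_true(all(is.na(asn$silhouette)))

  expect_error(cluster_subclones(matrix(0, 60, 0), list()), "empty region")
})

test_that("confirmation requires WGS-consistent genotypes or both modalities", {
  geno <- rbind(c(1L, 0L), c(0L, 0L), c(1L, 1L))
  colnames(geno) <- c("evA", "evB")
  rna <- structure(list(genotypes = geno,
                        labels = c("provisional_1", "S1", "S2")),
                   class = "subclone_assignment")
  wgs <- data.frame(event_id = c("evA", "evB"))

  # RNA-only provisional genotype: excluded
  conf <- confirm_subclones(rna, NULL, wgs)
  expect_false(conf$confirmed[conf$label == "provisional_1"])
  expect_true(all(conf$confirmed[conf$label %in% c("S1", "S2")]))

  # the same genotype found in ATAC confirms it even without a WGS match
  atac <- structure(list(genotypes = geno[c(1, 3), , drop = FALSE],
                         labels = c("provisional_1", "S2")),
                    class = "subclone_assignment")
  conf2 <- confirm_subclones(rna, atac, wgs)
  expect_true(conf2$confirmed[conf2$label == "provisional_1"])
})

test_that("site composition flags unique and plasticity-eligible subclones", {
  labels <- c(rep("S1", 300), rep("S2", 360), rep("S3", 302))
  sites <- c(rep("FL", 300),                      # S1 only at FL
             rep(c("FL", "RBM"), 180),            # S2 at both
             rep("RBM", 300), "FL", "FL")         # S3 nearly RBM-only
  asn <- structure(list(subclone = labels), class = "subclone_assignment")
  comp <- site_composition(asn, sites, confirmed = c("S1", "S2", "S3"))
  expect_equal(sum(comp$prop_FL), 1)
  expect_equal(sum(comp$prop_RBM), 1)
  expect_equal(comp$unique_to[comp$subclone == "S1"], "FL")
  expect_equal(comp$unique_to[comp$subclone == "S3"], "RBM")
  expect_true(is.na(comp$unique_to[comp$subclone == "S2"]))
  expect_true(comp$plasticity_eligible[comp$subclone == "S2"])
  expect_false(comp$plasticity_eligible[comp$subclone == "S1"])
})

test_that("single-cell variant site test matches the exact hypergeometric oracle", {
  # the headline example: 651/1442 mutant cells at the lesion vs 3/814
  calls <- rbind(
    data.frame(cell = sprintf("fl%d", 1:1442), variant = "KRAS_G13D",
               ref_reads = 1L,
               alt_reads = c(rep(1L, 651), rep(0L, 791)), site = "FL"),
    data.frame(cell = sprintf("rbm%d", 1:814), variant = "KRAS_G13D",
               ref_reads = 1L,
               alt_reads = c(rep(1L, 3), rep(0L, 811)), site = "RBM"))
  res <- sc_snv_site_test(calls)
  expect_equal(res$enriched_site, "FL")
  expect_lt(res$p_adj, 1e-10)

  # oracle: two-sided Fisher p by hypergeometric enumeration
  m <- 651 + 3; n <- 1442 + 814 - m; k <- 1442
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_oracle <- sum(probs[probs <= dhyper(651, m, n, k) * (1 + 1e-7)])
  expect_equal(res$p, p_oracle, tolerance = 1e-8)

  # no mutant cells anywhere: p 1, no flag
  none <- calls; none$alt_reads <- 0L
  r0 <- sc_snv_site_test(none)
  expect_equal(r0$p, 1)
  expect_true(is.na(r0$enriched_site))
  expect_equal(r0$odds_ratio, 1)

  # equal proportions: odds ratio 1
  eq <- rbind(
    data.frame(cell = sprintf("a%d", 1:100), variant = "v", ref_reads = 1L,
               alt_reads = rep(c(1L, 0L), 50), site = "FL"),
    data.frame(cell = sprintf("b%d", 1:100), variant = "v", ref_reads = 1L,
               alt_reads = rep(c(1L, 0L), 50), site = "RBM"))
  expect_equal(sc_snv_site_test(eq)$odds_ratio, 1)

  # cells without coverage are excluded; variant untestable when one site
  # has no covered cells
  onecov <- data.frame(cell = c("x", "y"), variant = "v",
                       ref_reads = c(1L, 0L), alt_reads = c(0L, 0L),
                       site = c("FL", "RBM"))
  r1 <- sc_snv_site_test(onecov)
  expect_false(r1$testable)
})
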