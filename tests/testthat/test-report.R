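test_that("exact signed-rank p-values match full sign enumeration", {
  # six uniformly-directed pairs: two-sided p = 2/64
  x <- c(10, 11, 12, 13, 14, 15); y <- x - 1
  res <- exact_signed_rank_test(x, y)
  expect_true(res$exact)
  expect_equal(res$p_value, 0.03125)

  # oracle: enumerate all 2^n sign assignments directly
  enum_p <- function(d) {
    d <- d[d != 0]; n <- length(d); r <- rank(abs(d))
    w_obs <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_all <- signs %*% r
    p_le <- mean(w_all <= w_obs + 1e-12)
    p_ge <- mean(w_all >= w_obs - 1e-12)
    min(1, 2 * min(p_le, p_ge))
  }
  expect_equal(res$p_value, enum_p(x - y))

  set.seed(12)
  for (n in c(3, 5, 8, 10)) {
    for (rep in 1:5) {
      a <- round(runif(n, 0, 1), 2)
      b <- round(runif(n, 0, 1), 2)
      got <- exact_signed_rank_test(a, b)
      expect_equal(got$p_value, enum_p(a - b),
                   info = sprintf("n=%d rep=%d", n, rep))
    }
  }

  # agreement with the reference implementation when there are no ties
  a <- c(0.11, 0.25, 0.4, 0.52, 0.61, 0.77, 0.9)
  b <- c(0.15, 0.2, 0.33, 0.6, 0.5, 0.81, 0.7)
  ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)
  expect_equal(exact_signed_rank_test(a, b)$p_value, ref$p.value)

  # all-zero differences
  expect_equal(exact_signed_rank_test(1:4, 1:4)$p_value, 1)
})

test_that("paired composition comparison flags strong consistent shifts", {
  set.seed(8)
  pats <- paste0("P", 1:6)
  rows <- list()
  for (p in pats) {
    for (s in c("RBM", "FL")) {
      # macrophages at ~9% in RBM, ~3% in FL; filler type for the rest
      n <- 800
      n_mac <- round(n * ifelse(s == "RBM", 0.09, 0.03) * runif(1, 0.9, 1.1))
      rows[[paste(p, s)]] <- data.frame(
        patient = p, site = s, cell = sprintf("%s_%s_%d", p, s, 1:n),
        cell_type = c(rep("Macrophage", n_mac), rep("T", n - n_mac)))
    }
  }
  ann <- do.call(rbind, rows)
  res <- compare_tme_composition(ann, sites = c("RBM", "FL"))
  mac <- res[res$cell_type == "Macrophage", ]
  expect_equal(mac$p, 0.03125)          # 6/6 consistent direction
  expect_gte(mac$fold_change, 2.5)
  expect_equal(mac$direction, "FL")     # depleted at the lesion
  expect_true(mac$flagged)
  expect_true(all(res$p_adj >= res$p))

  # fold change of means arithmetic
  expect_equal(mac$fold_change,
               mac$mean_RBM / mac$mean_FL)

  # identical proportions: p 1, fold 1, no flag
  same <- ann[ann$site == "RBM", ]
  both <- rbind(same, transform(same, site = "FL"))
  r2 <- compare_tme_composition(both, sites = c("RBM", "FL"))
  expect_true(all(r2$p == 1))
  expect_true(all(abs(r2$fold_change - 1) < 1e-12))
  expect_false(any(r2$flagged))

  # patients missing a site are excluded with a warning
  dropped <- ann[!(ann$patient == "P6" & ann$site == "FL"), ]
  expect_warning(compare_tme_composition(dropped, sites = c("RBM", "FL")),
                 "P6")
})

test_that("patient reports aggregate counts and round-trip via JSON", {
  cl <- data.frame(class = c(rep("shared_major", 7), rep("unshared_major", 2),
                             "enriched"))
  summ <- summarize_heterogeneity(cl)
  comp <- data.frame(subclone = paste0("S", 1:4),
                     n_RBM = c(100L, 50L, 0L, 60L),
                     prop_RBM = c(0.5, 0.24, 0, 0.26),
                     n_FL = c(80L, 40L, 70L, 55L),
                     prop_FL = c(0.33, 0.16, 0.29, 0.22),
                     unique_to = c(NA, NA, "FL", NA),
                     plasticity_eligible = c(TRUE, FALSE, FALSE, TRUE))
  rep <- build_patient_report("P01", summ, subclone_composition = comp)
  expect_equal(rep$confirmed_subclones, 4)
  expect_equal(rep$heterogeneous_snv_fraction, 30)
  expect_equal(rep$site_unique_subclones$S3, "FL")

  path <- tempfile(fileext = ".json")
  write_patient_report(rep, path)
  back <- read_patient_report(path)
  expect_equal(back$confirmed_subclones, rep$confirmed_subclones)
  expect_equal(back$heterogeneous_snv_fraction, rep$heterogeneous_snv_fraction)
  expect_equal(unlist(back$snv_class_counts), unlist(rep$snv_class_counts))
})

test_that("the pipeline is deterministic end to end", {
  cfg_fn <- function(seed, purity)
    tiny_config(seed, purity = c(RBM = purity, FL = purity))
  d1 <- file.path(tempdir(), "run1"); d2 <- file.path(tempdir(), "run2")
  coh1 <- simulate_cohort(2, seed = 7, n_unique_patients = 1,
                          config_fn = cfg_fn)
  coh2 <- simulate_cohort(2, seed = 7, n_unique_patients = 1,
                          config_fn = cfg_fn)
  r1 <- run_pipeline(d1, seed = 7, cohort = coh1)
  r2 <- run_pipeline(d2, seed = 7, cohort = coh2)
  for (f in basename(r1$reports)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  expect_equal(r1$heterogeneous_fractions, r2$heterogeneous_fractions)
})

test_that("tabular and matrix round trips preserve content", {
  cfg <- tiny_config(41)
  tr <- simulate_clone_tree(2, 2, seed = 41, config = cfg)
  b <- simulate_bulk_reads(tr, cfg, "RBM")
  d <- tempfile(); dir.create(d)
  write_bulk_site(b, d, "RBM")
  v <- read_tsv(file.path(d, "variants_RBM.tsv"))
  expect_equal(nrow(v), nrow(b$variants))
  expect_equal(v$ALT_READS_RBM, b$variants$alt_reads)

  m <- simulate_sc_counts(tr, cfg, "RBM", "rna", n_cells = 50)
  prefix <- file.path(d, "rna")
  write_cell_matrix(m, prefix)
  m2 <- read_cell_matrix(prefix)
  expect_equal(as.matrix(m2$counts), as.matrix(m$counts))
  expect_equal(m2$cells$subclone, m$cells$subclone)
})
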