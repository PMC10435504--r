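contig <- function(cell, chain, cdr3, site = "RBM", productive = TRUE) {
  data.frame(cell_id = cell, chain = chain, cdr3 = cdr3,
             productive = productive, site = site, stringsAsFactors = FALSE)
}

test_that("clonotypes are defined by the TRA/TRB pair and merge single chains", {
  contigs <- rbind(
    contig("c1", "TRA", "CAAAF"), contig("c1", "TRB", "CASSF"),
    contig("c2", "TRA", "CAAAF"), contig("c2", "TRB", "CASSF"),
    contig("c3", "TRB", "CASSF"),                  # unique TRB match
    contig("c4", "TRA", "CAXXF"), contig("c4", "TRB", "CASYF"),
    contig("c5", "TRB", "CASZF"))                  # no match: singleton
  res <- assign_clonotypes(contigs)
  cl <- res$clonotypes
  expect_equal(nrow(cl), 3)
  expect_equal(cl$n_RBM[cl$cdr3_trb == "CASSF"], 3)   # c1, c2, c3 merged
  expect_true(res$cell_map$merged[res$cell_map$cell_id == "c3"])
  expect_equal(res$assignment_rate, 1)

  # ambiguous single chain stays unmerged
  amb <- rbind(
    contig("c1", "TRA", "A1"), contig("c1", "TRB", "B1"),
    contig("c2", "TRA", "A2"), contig("c2", "TRB", "B1"),
    contig("c3", "TRB", "B1"))
  r2 <- assign_clonotypes(amb)
  expect_equal(nrow(r2$clonotypes), 3)   # two pairs + unmerged singleton
  expect_false(r2$cell_map$merged[r2$cell_map$cell_id == "c3"])

  # conflicting CDR3 for one chain in one cell is an error
  bad <- rbind(contig("c1", "TRA", "A1"), contig("c1", "TRA", "A2"))
  expect_error(assign_clonotypes(bad), "c1")

  # non-productive contigs never enter
  np <- rbind(contig("c1", "TRA", "A1"), contig("c1", "TRB", "B1"),
              contig("c9", "TRA", "XX", productive = FALSE))
  r3 <- assign_clonotypes(np)
  expect_false("XX" %in% c(r3$clonotypes$cdr3_tra, r3$clonotypes$cdr3_trb))
})

test_that("conservation: clonotype counts per site sum to assigned cells", {
  cfg <- tiny_config(31)
  sims <- lapply(c("RBM", "FL"), function(s)
    simulate_tcr(cfg, s, 400, seed = 31 + match(s, c("RBM", "FL"))))
  contigs <- do.call(rbind, lapply(sims, `[[`, "contigs"))
  res <- assign_clonotypes(contigs)
  for (s in c("RBM", "FL")) {
    assigned <- sum(!is.na(res$cell_map$clonotype[res$cell_map$site == s]))
    expect_equal(sum(res$clonotypes[[paste0("n_", s)]]), assigned)
  }
})

test_that("expansion classes follow the proportion and count rules exactly", {
  tab <- data.frame(
    clonotype_id = 1:4,
    n_RBM = c(60L, 12L, 4L, 9L),
    n_FL  = c(55L, 0L,  4L, 0L))
  totals <- c(RBM = 1000, FL = 1000)
  out <- classify_expansion(tab, totals)
  expect_equal(out$expansion,
               c("hyperexpanded",   # 6% and >= 5 cells
                 "expanded",        # 1.2%, >= 5 cells at RBM
                 "none",            # under both floors
                 "none"))           # 0.9% < 1%
  # exact edges: 1% and 5 cells qualify; 5% qualifies as hyperexpanded
  edge <- data.frame(clonotype_id = 1:3,
                     n_RBM = c(5L, 50L, 4L), n_FL = c(0L, 0L, 4L))
  oe <- classify_expansion(edge, c(RBM = 500, FL = 500))
  expect_equal(oe$expansion, c("expanded", "hyperexpanded", "none"))

  expect_error(classify_expansion(data.frame(n_RBM = 10L, n_FL = 0L),
                                  c(RBM = 5, FL = 5)), "exceeds")
})

test_that("expansion and spatial rules reproduce a brute-force oracle", {
  set.seed(99)
  for (rep in 1:30) {
    n <- sample(5:50, 1)
    tab <- data.frame(clonotype_id = seq_len(n),
                      n_RBM = rpois(n, 4), n_FL = rpois(n, 4))
    # sprinkle exact edge cases
    tab$n_RBM[1] <- 5L; tab$n_FL[1] <- 0L
    tab$n_FL[2] <- 10L; tab$n_RBM[2] <- 0L
    totals <- c(RBM = max(500, sum(tab$n_RBM)), FL = max(500, sum(tab$n_FL)))
    totals["RBM"] <- 500; totals["FL"] <- 500
    if (sum(tab$n_RBM) > 500 || sum(tab$n_FL) > 500) next
    out <- compare_sites(classify_expansion(tab, totals), totals)
    for (i in seq_len(n)) {
      pr <- c(tab$n_RBM[i] / 500, tab$n_FL[i] / 500)
      cnt <- c(tab$n_RBM[i], tab$n_FL[i])
      exp_cls <- if (max(pr) >= 0.05 && max(cnt) >= 5) "hyperexpanded"
        else if (max(pr) >= 0.01 && max(cnt) >= 5) "expanded" else "none"
      expect_equal(out$expansion[i], exp_cls)
      eligible <- max(cnt) >= 10
      expect_equal(out$pairing_eligible[i], eligible)
      pseudo <- ifelse(cnt == 0, 0.5, cnt) / 500
      ratio <- max(pseudo) / min(pseudo)
      expect_equal(out$spatial_variation[i], eligible && ratio >= 3)
    }
  }
})

test_that("threefold spatial cut-off triggers at exactly ratio 3", {
  tab <- data.frame(clonotype_id = 1:3,
                    n_RBM = c(9L, 9L, 10L), n_FL = c(30L, 9L, 10L))
  out <- compare_sites(classify_expansion(tab, c(RBM = 900, FL = 1000)),
                       c(RBM = 900, FL = 1000))
  # 30/1000 vs 9/900 = 0.03 vs 0.01 -> ratio 3, eligible via 30 cells
  expect_true(out$spatial_variation[1])
  # 9 cells at both sites: not eligible
  expect_false(out$pairing_eligible[2])
  # identical proportions: not flagged
  expect_false(out$spatial_variation[3])
})

test_that("module scores equal the mean difference to matched controls", {
  n_genes <- 300; n_cells <- 40
  # set genes equal the controls plus a constant in log space
  target <- paste0("g", sprintf("%03d", 1:5))
  cshift <- 0.7
  xl <- matrix(1, n_genes, n_cells,
               dimnames = list(sprintf("g%03d", 1:n_genes),
                               sprintf("c%02d", 1:n_cells)))
  xl[target, ] <- 1 + cshift
  sc <- module_score(xl, target, n_bins = 4, n_ctrl = 50, seed = 1,
                     normalize = FALSE)
  expect_true(all(abs(sc - cshift) < 1e-9))

  # all-zero target and controls give score 0
  z <- matrix(0, 50, 10, dimnames = list(paste0("g", 1:50), paste0("c", 1:10)))
  sc0 <- module_score(z, c("g1", "g2"), n_bins = 3, n_ctrl = 10, seed = 1,
                      normalize = FALSE)
  expect_true(all(sc0 == 0))

  # determinism and missing-gene error
  s1 <- module_score(xl, target, seed = 7, normalize = FALSE)
  s2 <- module_score(xl, target, seed = 7, normalize = FALSE)
  expect_identical(s1, s2)
  expect_error(module_score(xl, c("NOPE1", "NOPE2"), seed = 1), "NOPE1")
})
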