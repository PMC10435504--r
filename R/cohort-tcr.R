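#' Simulate T-cell receptor contigs for one site
#'
#' Cells are assigned clonotypes multinomially from the configured frequency
#' vector; each clonotype has a unique TRA and TRB CDR3 amino-acid string. A
#' configurable fraction of cells emits only one of its two chains, and a
#' small fraction of extra non-productive contigs is added.
#'
#' @param config a `sim_config`; @param site site label.
#' @param n_cells number of T cells.
#' @param freqs clonotype frequencies (default `config$clonotype_freqs`);
#'   must sum to 1 within 1e-9.
#' @param seed integer seed (default derived from `config$seed` and site).
#' @return list with `contigs` (data.frame: `cell_id`, `chain`,
#'   `cdr3`, `productive`, `site`) and `truth` (data.frame:
#'   `clonotype`, `cdr3_tra`, `cdr3_trb`, `frequency`, `n_cells`).
#' @export
simulate_tcr <- function(config, site, n_cells, freqs = NULL, seed = NULL) {
  if (is.null(freqs)) freqs <- config$clonotype_freqs
  if (abs(sum(freqs) - 1) > 1e-9)
    stop("clonotype frequencies must sum to 1", call. = FALSE)
  if (is.null(seed))
    seed <- config$seed + 15485863L %% 2147483L +
      1000L * match(site, config$sites)

  # clonotype CDR3 strings are a fixed catalogue (index-determined), so the
  # same clonotype carries the same sequences at both sites
  k <- length(freqs)
  cdr3_tra <- make_cdr3(k, prefix = "CA", seed_offset = 0L)
  cdr3_trb <- make_cdr3(k, prefix = "CASS", seed_offset = 1L)
  n_junk <- max(0L, round(0.03 * n_cells))
  junk_cdr3 <- make_cdr3(n_junk, prefix = "CX", seed_offset = 2L)

  set.seed(seed)
  assign <- sample.int(k, n_cells, replace = TRUE, prob = freqs)
  single <- stats::runif(n_cells) < config$single_chain_fraction
  drop_tra <- single & stats::runif(n_cells) < 0.5

  cell_ids <- sprintf("%s_t%05d", site, seq_len(n_cells))
  tra <- data.frame(cell_id = cell_ids, chain = "TRA",
                    cdr3 = cdr3_tra[assign], productive = TRUE,
                    site = site, stringsAsFactors = FALSE)[!drop_tra, ]
  trb <- data.frame(cell_id = cell_ids, chain = "TRB",
                    cdr3 = cdr3_trb[assign], productive = TRUE,
                    site = site, stringsAsFactors = FALSE)[!(single & !drop_tra), ]
  contigs <- rbind(tra, trb)

  if (n_junk > 0) {
    junk <- data.frame(
      cell_id = sample(cell_ids, n_junk),
      chain = sample(c("TRA", "TRB"), n_junk, replace = TRUE),
      cdr3 = junk_cdr3,
      productive = FALSE, site = site, stringsAsFactors = FALSE)
    contigs <- rbind(contigs, junk)
  }
  contigs <- contigs[order(contigs$cell_id, contigs$chain), ]
  rownames(contigs) <- NULL

  truth <- data.frame(
    clonotype = seq_len(k), cdr3_tra = cdr3_tra, cdr3_trb = cdr3_trb,
    frequency = as.numeric(freqs),
    n_cells = tabulate(assign, nbins = k), stringsAsFactors = FALSE)
  list(contigs = contigs, truth = truth)
}

# deterministic-per-index unique CDR3 strings
make_cdr3 <- function(n, prefix = "CASS", seed_offset = 0L) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  vapply(seq_len(n), function(i) {
    set.seed(1e6L + seed_offset * 1e5L + i)
    paste0(prefix, paste(sample(aa, 8, replace = TRUE), collapse = ""), "F")
  }, character(1))
}

#' Simulate paired-site microenvironment cell-type annotations
#'
#' Per patient and site, draws cell-type labels multinomially from the
#' configured per-site proportion vectors, with per-patient Dirichlet-like
#' jitter so patients differ while the planted site shift (e.g. the
#' monocyte/macrophage depletion in focal lesions) is consistent.
#'
#' @param config a `sim_config`.
#' @param patients character vector of patient ids.
#' @param n_cells_per_site cells per patient per site.
#' @param jitter concentration of per-patient proportion jitter (larger =
#'   less variation).
#' @param seed integer seed.
#' @return data.frame: `patient`, `site`, `cell`, `cell_type`.
#' @export
simulate_tme_annotations <- function(config, patients, n_cells_per_site = 2000,
                                     jitter = 400, seed = 1L) {
  set.seed(seed)
  rows <- list()
  for (pt in patients) {
    for (site in config$sites) {
      base <- config$cell_type_props[[site]]
      w <- stats::rgamma(length(base), shape = base * jitter)
      p <- w / sum(w)
      lab <- sample(names(base), n_cells_per_site, replace = TRUE, prob = p)
      rows[[paste(pt, site)]] <- data.frame(
        patient = pt, site = site,
        cell = sprintf("%s_%s_%05d", pt, site, seq_len(n_cells_per_site)),
        cell_type = lab, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a full paired-site synthetic cohort
#'
#' Study-condition defaults: 8 patients, two sites, 85x depth, per-patient
#' purity drawn uniformly in 0.5–0.9, 4–6 subclones per patient, and one
#' site-unique subclone in 3 of the patients. Only the bulk layer is
#' generated here; single-cell layers are simulated per patient on demand
#' ([simulate_sc_counts()], [simulate_tcr()]) to keep problem sizes
#' controllable.
#'
#' @param n_patients number of patients.
#' @param seed integer master seed; per-patient seeds are derived from it.
#' @param n_unique_patients patients receiving a site-unique subclone.
#' @param purity_range per-patient purity is drawn uniformly in this range
#'   (shared by both sites).
#' @param n_subclone_range inclusive range of subclone counts per patient.
#' @param config_fn function(seed, purity) returning a `sim_config`; the
#'   default uses study-condition defaults.
#' @return list of patients, each with `patient`, `config`, `tree`,
#'   `cna_events`, `snvs`, and per-site `bulk` results.
#' @export
simulate_cohort <- function(n_patients = 8, seed = 1L,
                            n_unique_patients = 3,
                            purity_range = c(0.5, 0.9),
                            n_subclone_range = c(4L, 6L),
                            config_fn = NULL) {
  set.seed(seed)
  purities <- stats::runif(n_patients, purity_range[1L], purity_range[2L])
  n_sub <- sample(seq(n_subclone_range[1L], n_subclone_range[2L]),
                  n_patients, replace = TRUE)
  unique_pt <- sort(sample.int(n_patients, n_unique_patients))
  if (is.null(config_fn))
    config_fn <- function(seed, purity)
      sim_config(seed = seed, purity = c(RBM = purity, FL = purity))

  lapply(seq_len(n_patients), function(i) {
    pseed <- (seed * 131L + i * 7907L) %% 2000000000L
    cfg <- config_fn(pseed, purities[i])
    su <- rep(FALSE, n_sub[i])
    if (i %in% unique_pt) su[n_sub[i]] <- TRUE
    tree <- simulate_clone_tree(n_sub[i], n_sites = 2, site_unique = su,
                                seed = pseed, config = cfg)
    cna <- place_cna_events(tree, cfg, seed = pseed)
    snvs <- place_snvs(tree, cfg, cna, seed = pseed + 1L)
    bulk <- lapply(stats::setNames(cfg$sites, cfg$sites), function(site)
      simulate_bulk_reads(tree, cfg, site, snvs = snvs, cna_events = cna))
    list(patient = sprintf("P%02d", i), config = cfg, tree = tree,
         cna_events = cna, snvs = snvs, bulk = bulk,
         has_unique = i %in% unique_pt)
  })
}

#' Ground-truth paired-site class of a simulated SNV
#'
#' Maps the simulator's true per-site CCFs to the coarse heterogeneity
#' class used for recovery checks: `filtered` when the CCF exceeds 0.15 at
#' neither site, `unshared` when the variant is absent (CCF 0) at one site,
#' `enriched` when present at both with the dominant site clonal and a
#' >= 3-fold CCF ratio, `shared` otherwise.
#'
#' @param ccf_a,ccf_b true CCFs at the two sites (vectorised).
#' @param ccf_floor,enrich_ratio thresholds matching the classifier.
#' @return character vector of coarse classes.
#' @export
true_snv_class <- function(ccf_a, ccf_b, ccf_floor = 0.15, enrich_ratio = 3) {
  hi <- pmax(ccf_a, ccf_b); lo <- pmin(ccf_a, ccf_b)
  out <- rep("shared", length(hi))
  out[lo > 0 & hi >= 1 - 1e-9 & hi / pmax(lo, 1e-12) >= enrich_ratio] <- "enriched"
  out[lo == 0] <- "unshared"
  out[hi <= ccf_floor] <- "filtered"
  out
}

#' Collapse a six-way paired classification to its coarse class
#' @param class character vector of classifier labels.
#' @return character vector over shared/unshared/enriched/filtered.
#' @export
coarse_class <- function(class) {
  sub("_(major|minor)$", "", class)
}
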