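#' Synthetic genome model
#'
#' A simplified genome used by the cohort simulator: a set of autosomes with
#' fixed lengths and an ordered gene catalogue (genes evenly spaced with
#' jitter, strictly increasing within each chromosome). No real reference
#' sequence is involved.
#'
#' @param n_chrom number of chromosomes (default 22).
#' @param chrom_length length of each chromosome in bp (scalar or vector).
#' @param genes_per_chrom number of genes per chromosome.
#' @param gene_width gene footprint in bp.
#' @return list with `chrom_lengths` (named vector) and `genes`
#'   (data.frame: `gene`, `chrom`, `start`, `end`, `mid`; 0-based half-open).
#' @export
sim_genome <- function(n_chrom = 22, chrom_length = 1.2e8,
                       genes_per_chrom = 500, gene_width = 2e4) {
  chroms <- paste0("chr", seq_len(n_chrom))
  lens <- rep_len(chrom_length, n_chrom)
  names(lens) <- chroms
  genes <- do.call(rbind, lapply(seq_len(n_chrom), function(ci) {
    spacing <- lens[ci] / (genes_per_chrom + 1)
    start <- round(seq_len(genes_per_chrom) * spacing)
    data.frame(
      gene = sprintf("G%s_%04d", ci, seq_len(genes_per_chrom)),
      chrom = chroms[ci],
      start = start,
      end = pmin(start + gene_width, lens[ci]),
      stringsAsFactors = FALSE
    )
  }))
  genes$mid <- (genes$start + genes$end) / 2
  list(chrom_lengths = lens, genes = genes)
}

#' Simulation configuration for the paired-site cohort generator
#'
#' Collects every tunable of the synthetic cohort. Defaults encode the study
#' conditions: two bone-marrow sites (random aspirate RBM and focal lesion
#' FL), mean tumor sequencing depth 85x, per-copy dosage effect 1.5 on
#' single-cell counts, substitution error rate 1e-3 on bulk reads.
#'
#' @param seed integer seed.
#' @param sites site labels (first is taken as the random aspirate).
#' @param purity named per-site tumor purity in (0, 1].
#' @param depth mean bulk read depth.
#' @param error_rate symmetric per-base substitution error rate.
#' @param genome genome model from [sim_genome()].
#' @param n_cells named per-modality cells per site.
#' @param n_ref_cells neutral normal-plasma-cell reference cells per matrix.
#' @param dosage_effect relative count multiplier per copy gained; a
#'   single-copy gain scales means by this factor, a single-copy loss by
#'   `2 - dosage_effect`.
#' @param nb_size negative-binomial size (inverse dispersion) for RNA counts.
#' @param atac_mean_fragments target mean fragments per ATAC cell.
#' @param n_truncal_snvs,n_snvs_per_subclone SNVs owned by the root clone and
#'   by each derived subclone.
#' @param n_truncal_cna truncal copy-number events.
#' @param min_prevalence smallest non-zero subclone prevalence admitted at a
#'   site; draws below it are rounded to absence.
#' @param clonotype_freqs clonotype frequency vector (must sum to 1); the
#'   tail clone absorbs the remainder.
#' @param single_chain_fraction fraction of T cells emitting only one chain.
#' @param cell_type_props named list of per-site cell-type proportion
#'   vectors for the microenvironment (each sums to 1).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       sites = c("RBM", "FL"),
                       purity = c(RBM = 0.7, FL = 0.7),
                       depth = 85,
                       error_rate = 1e-3,
                       genome = sim_genome(),
                       n_cells = c(rna = 600L, atac = 600L),
                       n_ref_cells = 150L,
                       dosage_effect = 1.5,
                       nb_size = 10,
                       atac_mean_fragments = 6000,
                       n_truncal_snvs = 60L,
                       n_snvs_per_subclone = 25L,
                       n_truncal_cna = 2L,
                       min_prevalence = 0.25,
                       clonotype_freqs = default_clonotype_freqs(),
                       single_chain_fraction = 0.15,
                       cell_type_props = default_tme_props(sites)) {
  stopifnot(all(purity > 0), all(purity <= 1),
            depth > 0, error_rate >= 0, error_rate < 0.5,
            dosage_effect > 0)
  if (abs(sum(clonotype_freqs) - 1) > 1e-9)
    stop("clonotype frequencies must sum to 1", call. = FALSE)
  for (p in cell_type_props)
    stopifnot(abs(sum(p) - 1) < 1e-8)
  g <- genome$genes
  ok <- tapply(g$start, g$chrom, function(s) all(diff(s) > 0))
  if (!all(ok)) stop("gene positions must be strictly increasing", call. = FALSE)
  structure(list(
    seed = as.integer(seed), sites = sites, purity = purity, depth = depth,
    error_rate = error_rate, genome = genome, n_cells = n_cells,
    n_ref_cells = as.integer(n_ref_cells), dosage_effect = dosage_effect,
    nb_size = nb_size, atac_mean_fragments = atac_mean_fragments,
    n_truncal_snvs = as.integer(n_truncal_snvs),
    n_snvs_per_subclone = as.integer(n_snvs_per_subclone),
    n_truncal_cna = as.integer(n_truncal_cna),
    min_prevalence = min_prevalence,
    clonotype_freqs = clonotype_freqs,
    single_chain_fraction = single_chain_fraction,
    cell_type_props = cell_type_props
  ), class = "sim_config")
}

#' @rdname sim_config
#' @export
default_clonotype_freqs <- function(n_small = 400) {
  big <- c(0.06, 0.03, 0.02, 0.015, 0.012, 0.01)
  small <- rep((1 - sum(big)) / n_small, n_small)
  c(big, small)
}

#' @rdname sim_config
#' @export
default_tme_props <- function(sites = c("RBM", "FL")) {
  types <- c("CD14_Mono", "CD16_Mono", "Macrophage", "GMP",
             "CD4_Naive", "CD4_Memory", "CD8_Naive", "CD8_Effector_2",
             "CD8_Memory_2", "Treg", "NK", "B", "pDC", "cDC2")
  rbm <- c(0.16, 0.05, 0.04, 0.03,
           0.14, 0.10, 0.08, 0.05,
           0.08, 0.03, 0.10, 0.10, 0.02, 0.02)
  # monocyte/macrophage compartment depleted ~3x in the focal lesion,
  # CD8 effector cells enriched
  fl <- c(0.053, 0.017, 0.013, 0.012,
          0.15, 0.11, 0.09, 0.11,
          0.10, 0.035, 0.12, 0.13, 0.025, 0.035)
  rbm <- rbm / sum(rbm); fl <- fl / sum(fl)
  names(rbm) <- names(fl) <- types
  out <- list(rbm, fl)[seq_along(sites)]
  names(out) <- sites
  out
}

#' Simulate a clonal tree with site-specific subclone prevalences
#'
#' Builds a clone tree with one root (truncal) clone and `n_subclones - 1`
#' derived subclones, each owning a private set of SNV and copy-number event
#' ids. Per site, subclone prevalences (fractions of tumor cells whose most
#' derived clone is that subclone) are non-negative and sum to 1. Subclones
#' flagged `site_unique` are present at exactly one (dominant) site;
#' additionally, prevalence draws below `min_prevalence` are rounded to
#' absence, so every non-zero prevalence is detectable.
#'
#' @param n_subclones total number of subclones including the root (>= 1).
#' @param n_sites number of sites (default 2).
#' @param site_unique logical vector over subclones (or indices) flagging
#'   subclones restricted to a single site; the root cannot be flagged.
#' @param seed integer seed.
#' @param config a [sim_config()]; supplies event counts, site labels and
#'   the prevalence floor.
#' @param unique_prev_range prevalence range of a site-unique subclone at
#'   its home site (it is the dominant clone there).
#' @param n_cna_per_subclone copy-number events owned by each non-root
#'   subclone (default 1).
#' @return list of class `clone_tree` with elements `subclones`
#'   (data.frame: `id`, `parent`, `site_unique`, `home_site`), `events`
#'   (data.frame: `event_id`, `type` snv/cna, `owner`), `prevalence`
#'   (subclone x site matrix), and `ccf` (subtree prevalence sums; the CCF
#'   of every event owned by each subclone, per site).
#' @export
simulate_clone_tree <- function(n_subclones, n_sites = 2, site_unique = NULL,
                                seed = 1L, config = sim_config(),
                                unique_prev_range = c(0.75, 0.9),
                                n_cna_per_subclone = 1L) {
  if (n_subclones < 1) stop("n_subclones must be >= 1", call. = FALSE)
  set.seed(seed)
  sites <- config$sites[seq_len(n_sites)]
  if (is.numeric(site_unique)) {
    su <- rep(FALSE, n_subclones); su[site_unique] <- TRUE
    site_unique <- su
  }
  if (is.null(site_unique)) site_unique <- rep(FALSE, n_subclones)
  stopifnot(length(site_unique) == n_subclones)
  if (site_unique[1L]) stop("the root clone cannot be site-unique", call. = FALSE)

  parent <- c(NA_integer_, rep(1L, max(0L, n_subclones - 1L)))
  home <- rep(NA_character_, n_subclones)
  uniq_idx <- which(site_unique)
  # alternate home sites, starting with the focal-lesion-like last site
  if (length(uniq_idx))
    home[uniq_idx] <- rev(sites)[(seq_along(uniq_idx) - 1L) %% n_sites + 1L]

  prevalence <- matrix(0, n_subclones, n_sites,
                       dimnames = list(paste0("S", seq_len(n_subclones)), sites))
  for (si in seq_len(n_sites)) {
    p <- numeric(n_subclones)
    here_unique <- uniq_idx[home[uniq_idx] == sites[si]]
    u_total <- 0
    if (length(here_unique)) {
      u <- stats::runif(length(here_unique), unique_prev_range[1L],
                        unique_prev_range[2L]) / length(here_unique)
      p[here_unique] <- u
      u_total <- sum(u)
    }
    open <- setdiff(which(!site_unique), integer(0))
    w <- stats::rgamma(length(open), shape = 5)
    p[open] <- (1 - u_total) * w / sum(w)
    # round sub-detectable subclones (not the root) to absence
    low <- p < config$min_prevalence & seq_len(n_subclones) != 1L & p > 0
    p[low] <- 0
    p <- p / sum(p)
    prevalence[, si] <- p
  }
  # a subclone absent everywhere is re-seeded at the least crowded site
  # (so a dominant site-unique clone is not diluted), with just enough mass
  # to stay above the floor after renormalisation
  m <- config$min_prevalence
  uniq_at_site <- vapply(sites, function(s)
    sum(site_unique & !is.na(home) & home == s), integer(1))
  dead <- which(rowSums(prevalence) == 0)
  for (d in dead) {
    si <- order(uniq_at_site, apply(prevalence, 2, max))[1L]
    prevalence[d, si] <- 1.1 * m / (1 - m)
    prevalence[, si] <- prevalence[, si] / sum(prevalence[, si])
  }
  # re-seeding shrinks neighbours: re-apply the floor, but never remove a
  # subclone from its only site
  for (it in seq_len(5)) {
    changed <- FALSE
    for (si in seq_len(n_sites)) {
      p <- prevalence[, si]
      other_ok <- rowSums(prevalence) - p > 0
      low <- which(p > 0 & p < m & seq_len(n_subclones) != 1L & other_ok)
      if (length(low)) {
        drop <- low[which.min(p[low])]
        prevalence[drop, si] <- 0
        prevalence[, si] <- prevalence[, si] / sum(prevalence[, si])
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  n_snv <- c(config$n_truncal_snvs,
             rep(config$n_snvs_per_subclone, max(0L, n_subclones - 1L)))
  n_cna <- c(config$n_truncal_cna,
             rep(as.integer(n_cna_per_subclone), max(0L, n_subclones - 1L)))
  events <- do.call(rbind, lapply(seq_len(n_subclones), function(s) {
    rbind(
      if (n_snv[s] > 0) data.frame(
        event_id = sprintf("snv_S%d_%03d", s, seq_len(n_snv[s])),
        type = "snv", owner = s, stringsAsFactors = FALSE),
      if (n_cna[s] > 0) data.frame(
        event_id = sprintf("cna_S%d_%02d", s, seq_len(n_cna[s])),
        type = "cna", owner = s, stringsAsFactors = FALSE)
    )
  }))

  # subtree prevalence sums: CCF of each subclone's own events
  ccf <- prevalence
  for (s in rev(seq_len(n_subclones))) {
    kids <- which(parent == s)
    if (length(kids)) ccf[s, ] <- ccf[s, ] + colSums(ccf[kids, , drop = FALSE])
  }

  structure(list(
    subclones = data.frame(id = seq_len(n_subclones), parent = parent,
                           site_unique = site_unique, home_site = home,
                           stringsAsFactors = FALSE),
    events = events, prevalence = prevalence, ccf = ccf, sites = sites
  ), class = "clone_tree")
}

#' Plant a one-modality artifact subclone into a clone tree
#'
#' Adds a synthetic cell population that carries only a subset of another
#' subclone's copy-number events — an event combination that the true tree
#' never produces. Feeding the modified tree to one single-cell simulation
#' (and the true tree to bulk and the other modality) creates the situation
#' where one modality suggests a genotype that cannot be confirmed.
#'
#' @param tree a `clone_tree`.
#' @param event_id the single event the artifact population carries.
#' @param site site where the artifact population appears.
#' @param prev its prevalence there (other subclones are scaled down).
#' @return the modified `clone_tree` (artifact subclone has the highest id).
#' @export
plant_artifact_subclone <- function(tree, event_id, site, prev = 0.15) {
  stopifnot(event_id %in% tree$events$event_id,
            site %in% colnames(tree$prevalence))
  new_id <- nrow(tree$subclones) + 1L
  tree$subclones <- rbind(tree$subclones, data.frame(
    id = new_id, parent = 1L, site_unique = TRUE, home_site = site,
    stringsAsFactors = FALSE))
  tree$events <- rbind(tree$events, data.frame(
    event_id = event_id, type = "cna", owner = new_id,
    stringsAsFactors = FALSE))
  prevalence <- rbind(tree$prevalence, 0)
  rownames(prevalence)[new_id] <- paste0("S", new_id)
  si <- match(site, colnames(prevalence))
  prevalence[, si] <- prevalence[, si] * (1 - prev)
  prevalence[new_id, si] <- prev
  tree$prevalence <- prevalence
  ccf <- prevalence
  for (s in rev(seq_len(new_id))) {
    kids <- which(tree$subclones$parent == s)
    if (length(kids)) ccf[s, ] <- ccf[s, ] + colSums(ccf[kids, , drop = FALSE])
  }
  tree$ccf <- ccf
  tree
}

# event ids carried by subclone s: its own plus all ancestors'
carried_events <- function(tree, s) {
  anc <- s
  while (!is.na(tree$subclones$parent[anc[1L]]))
    anc <- c(tree$subclones$parent[anc[1L]], anc)
  tree$events$event_id[tree$events$owner %in% anc]
}

#' Place the tree's copy-number events on the genome
#'
#' Each copy-number event occupies a large interval (a fraction of a whole
#' chromosome) on its own chromosome; truncal and subclonal events never
#' share a chromosome, and direction alternates gain/loss. Also places a few
#' short (< 200 kb) clonal events to exercise the length filter.
#'
#' @param tree a `clone_tree`.
#' @param config a `sim_config`.
#' @param seed integer seed.
#' @param span_range fraction of the chromosome covered by an event.
#' @param n_small_events number of short decoy events (length 150 kb).
#' @return data.frame: `event_id`, `owner`, `chrom`, `start`, `end`,
#'   `direction` (+1 gain / -1 loss), `total_cn`.
#' @export
place_cna_events <- function(tree, config, seed = 1L,
                             span_range = c(0.7, 0.9), n_small_events = 2L) {
  set.seed(seed)
  ev <- tree$events[tree$events$type == "cna", , drop = FALSE]
  lens <- config$genome$chrom_lengths
  n_need <- nrow(ev) + n_small_events
  if (n_need > length(lens))
    stop("not enough chromosomes for the requested events", call. = FALSE)
  chroms <- sample(names(lens), n_need)
  rows <- lapply(seq_len(nrow(ev)), function(k) {
    L <- lens[[chroms[k]]]
    span <- stats::runif(1, span_range[1L], span_range[2L])
    start <- round(stats::runif(1, 0, L * (1 - span)))
    dir <- if (k %% 2L == 1L) 1L else -1L
    data.frame(event_id = ev$event_id[k], owner = ev$owner[k],
               chrom = chroms[k], start = start,
               end = start + round(L * span),
               direction = dir, total_cn = 2L + dir,
               stringsAsFactors = FALSE)
  })
  small <- lapply(seq_len(n_small_events), function(k) {
    ch <- chroms[nrow(ev) + k]
    start <- round(stats::runif(1, 0, lens[[ch]] - 1.5e5))
    data.frame(event_id = sprintf("cna_small_%02d", k), owner = 1L,
               chrom = ch, start = start, end = start + 1.5e5,
               direction = 1L, total_cn = 3L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, small))
  rownames(out) <- NULL
  out
}
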