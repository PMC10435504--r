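#' Quality-control filter for single-cell matrices
#'
#' RNA cells are kept when mitochondrial fraction <= 5%, detected genes in
#' \[200, 5000\] and doublet score <= 0.3. ATAC cells are kept when TSS
#' enrichment >= 8, fragments >= 3000, doublet enrichment <= 6 and the
#' predicted doublet score <= 200. Removal reasons are recorded.
#'
#' @param mat a `cell_feature_matrix` (see [simulate_sc_counts()]).
#' @param modality `"rna"` or `"atac"` (default: the matrix's own).
#' @return the filtered `cell_feature_matrix`, with a `qc_log` data.frame
#'   attached (`cell`, `reason`) listing removed cells.
#' @export
qc_filter_cells <- function(mat, modality = mat$modality) {
  stopifnot(inherits(mat, "cell_feature_matrix"))
  cells <- mat$cells
  need <- if (modality == "rna")
    c("mito_frac", "n_features", "doublet_score")
  else
    c("tss_score", "n_fragments", "doublet_enrichment", "doublet_score_pred")
  missing <- setdiff(need, names(cells))
  if (length(missing))
    stop("missing QC column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)

  if (modality == "rna") {
    reasons <- list(
      high_mito = cells$mito_frac > 0.05,
      few_features = cells$n_features < 200,
      many_features = cells$n_features > 5000,
      doublet = cells$doublet_score > 0.3
    )
  } else {
    reasons <- list(
      low_tss = cells$tss_score < 8,
      few_fragments = cells$n_fragments < 3000,
      doublet_enrichment = cells$doublet_enrichment > 6,
      doublet_predicted = cells$doublet_score_pred > 200
    )
  }
  fail <- Reduce(`|`, reasons)
  log_rows <- do.call(rbind, lapply(names(reasons), function(r)
    if (any(reasons[[r]])) data.frame(cell = cells$cell[reasons[[r]]],
                                      reason = r, stringsAsFactors = FALSE)))
  keep <- which(!fail)
  out <- mat
  out$counts <- mat$counts[, keep, drop = FALSE]
  out$cells <- cells[keep, , drop = FALSE]
  rownames(out$cells) <- NULL
  out$qc_log <- if (is.null(log_rows))
    data.frame(cell = character(0), reason = character(0)) else log_rows
  out
}

#' Combine per-site cell matrices into one
#'
#' @param ... `cell_feature_matrix` objects sharing the same features.
#' @return a single `cell_feature_matrix` with cells concatenated.
#' @export
merge_cell_matrices <- function(...) {
  mats <- list(...)
  stopifnot(length(mats) >= 1)
  feats <- mats[[1L]]$features
  for (m in mats)
    stopifnot(identical(m$features$gene, feats$gene))
  structure(list(
    counts = do.call(cbind, lapply(mats, `[[`, "counts")),
    features = feats,
    cells = do.call(rbind, lapply(mats, `[[`, "cells")),
    modality = mats[[1L]]$modality
  ), class = "cell_feature_matrix")
}

#' Average relative expression over subclonal copy-number regions (RNA)
#'
#' Depth-normalises counts (counts per 10k, log1p), centers each gene on the
#' reference-cell mean, smooths along genomic order with a running mean, and
#' averages member genes per region. Only regions that are subclonal by bulk
#' WGS are interrogated; genes expressed in no cell are excluded, and a
#' region retaining fewer than `min_genes` genes is dropped with a warning.
#'
#' @param mat a `cell_feature_matrix` (RNA) containing reference cells.
#' @param regions data.frame of subclonal regions: `chrom`, `start`, `end`
#'   (0-based half-open), `event_id`, `direction` optional.
#' @param min_genes minimum genes per region (default 20).
#' @param window running-mean window in genes (odd; default 51,
#'   edge-truncated).
#' @return numeric matrix, cells x regions, of centered smoothed signals;
#'   attribute `region_genes` gives gene counts per region.
#' @export
region_signal_rna <- function(mat, regions, min_genes = 20, window = 51) {
  stopifnot(inherits(mat, "cell_feature_matrix"))
  if (!any(mat$cells$reference))
    stop("reference cells are required for centering", call. = FALSE)
  counts <- mat$counts
  expressed <- Matrix::rowSums(counts) > 0
  counts <- counts[expressed, , drop = FALSE]
  feats <- mat$features[expressed, , drop = FALSE]

  depth <- Matrix::colSums(counts)
  depth[depth == 0] <- 1
  norm <- log1p(t(t(as.matrix(counts)) / depth * 1e4))

  ref <- mat$cells$reference
  centered <- norm - rowMeans(norm[, ref, drop = FALSE])

  # smooth along genomic order within chromosome
  ord <- order(match(feats$chrom, unique(feats$chrom)), feats$mid)
  centered <- centered[ord, , drop = FALSE]
  feats <- feats[ord, , drop = FALSE]
  sm <- centered
  for (ch in unique(feats$chrom)) {
    idx <- which(feats$chrom == ch)
    if (length(idx) > 1)
      sm[idx, ] <- apply(centered[idx, , drop = FALSE], 2, running_mean,
                         window = window)
  }
  # per-cell median centering: removes cell-level offsets (depth/log1p
  # interaction) that would leak correlated noise into every region
  sm <- sweep(sm, 2, apply(sm, 2, stats::median))

  sig <- matrix(NA_real_, ncol(counts), 0,
                dimnames = list(mat$cells$cell, NULL))
  gene_counts <- integer(0)
  for (k in seq_len(nrow(regions))) {
    inside <- feats$chrom == regions$chrom[k] &
      feats$mid >= regions$start[k] & feats$mid < regions$end[k]
    if (sum(inside) < min_genes) {
      warning(sprintf("region %s dropped: %d gene(s) < %d",
                      regions$event_id[k], sum(inside), min_genes),
              call. = FALSE)
      next
    }
    sig <- cbind(sig, colMeans(sm[inside, , drop = FALSE]))
    colnames(sig)[ncol(sig)] <- regions$event_id[k]
    gene_counts <- c(gene_counts, sum(inside))
  }
  attr(sig, "region_genes") <- gene_counts
  attr(sig, "ref_sd") <- apply(sig[mat$cells$reference, , drop = FALSE],
                               2, stats::sd)
  sig
}

running_mean <- function(x, window) {
  half <- (window - 1) %/% 2
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Genome-bin z-scores over subclonal regions (ATAC)
#'
#' Builds overlapping 10 Mb bins (5 Mb step) over the genome, computes each
#' cell's fraction of fragments per bin, standardises every bin against the
#' normal-plasma-cell reference cells (z = (x - ref mean) / ref sd; bins
#' with zero reference variance are excluded), and averages the z-scores of
#' the bins overlapping each subclonal region.
#'
#' @param fragments data.frame: `chrom`, `start`, `end` (0-based half-open),
#'   `barcode`, `count`; aggregated rows allowed.
#' @param regions subclonal regions as in [region_signal_rna()].
#' @param genome named chromosome lengths.
#' @param reference_barcodes barcodes of the reference cells.
#' @param bin_width,bin_step bin geometry in bp (defaults 10 Mb / 5 Mb).
#' @return numeric matrix, cells x regions, of mean bin z-scores; attribute
#'   `bin_z` carries the full cell x bin z matrix.
#' @export
region_signal_atac <- function(fragments, regions, genome,
                               reference_barcodes,
                               bin_width = 1e7, bin_step = 5e6) {
  bad <- !(fragments$chrom %in% names(genome)) |
    fragments$end > genome[fragments$chrom] | fragments$start < 0
  if (any(bad))
    stop(sprintf("%d fragment(s) outside chromosome bounds (first: %s:%d-%d)",
                 sum(bad), fragments$chrom[which(bad)[1L]],
                 fragments$start[which(bad)[1L]],
                 fragments$end[which(bad)[1L]]), call. = FALSE)
  if (!length(reference_barcodes))
    stop("reference cells are required", call. = FALSE)

  bins <- do.call(rbind, lapply(names(genome), function(ch) {
    starts <- seq(0, max(0, genome[[ch]] - 1), by = bin_step)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + bin_width, genome[[ch]]),
               stringsAsFactors = FALSE)
  }))
  bin_gr <- GenomicRanges::GRanges(bins$chrom,
                                   IRanges::IRanges(bins$start + 1L, bins$end))

  cells <- unique(fragments$barcode)
  frag_gr <- GenomicRanges::GRanges(
    fragments$chrom, IRanges::IRanges(fragments$start + 1L, fragments$end))
  hits <- GenomicRanges::findOverlaps(frag_gr, bin_gr)
  counts <- Matrix::sparseMatrix(
    i = S4Vectors::subjectHits(hits),
    j = match(fragments$barcode, cells)[S4Vectors::queryHits(hits)],
    x = fragments$count[S4Vectors::queryHits(hits)],
    dims = c(nrow(bins), length(cells)))
  colnames(counts) <- cells

  tot <- Matrix::colSums(counts)
  tot[tot == 0] <- 1
  frac <- as.matrix(t(t(counts) / tot))

  ref_idx <- match(intersect(reference_barcodes, cells), cells)
  mu <- rowMeans(frac[, ref_idx, drop = FALSE])
  sd <- apply(frac[, ref_idx, drop = FALSE], 1, stats::sd)
  ok <- sd > 0
  z <- (frac[ok, , drop = FALSE] - mu[ok]) / sd[ok]
  bins <- bins[ok, , drop = FALSE]
  kept_gr <- bin_gr[ok]

  sig <- matrix(NA_real_, length(cells), 0, dimnames = list(cells, NULL))
  reg_gr <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$start + 1L, regions$end))
  for (k in seq_len(nrow(regions))) {
    ov <- S4Vectors::subjectHits(
      GenomicRanges::findOverlaps(reg_gr[k], kept_gr))
    if (!length(ov)) next
    sig <- cbind(sig, colMeans(z[ov, , drop = FALSE]))
    colnames(sig)[ncol(sig)] <- regions$event_id[k]
  }
  attr(sig, "bin_z") <- t(z)
  ref_rows <- colnames(z) %in% reference_barcodes
  attr(sig, "ref_sd") <- apply(sig[ref_rows, , drop = FALSE], 2, stats::sd)
  sig
}

#' Cluster cells into CNA-defined subclones
#'
#' Ward-linkage (`ward.D2`) hierarchical clustering on Euclidean distances
#' over the cell x region signal matrix. The dendrogram cut is chosen over
#' `k_range` (defaulting to 2 through number of candidate genotypes + 1) as
#' the cut that reveals the most distinct called CNA genotypes among
#' clusters of at least `min_cluster_cells` cells; ties are broken by the
#' higher mean silhouette width, then by the smaller cut. This genotype-
#' saturation rule is the automated surrogate for the WGS-guided visual
#' dendrogram inspection it replaces: a small genotype-distinct cluster is
#' kept even when a global fit index would absorb it into a neighbour.
#' Each cluster receives a genotype by
#' sign-thresholding its mean region signal (gain above `tau`, loss below
#' `-tau`) and is matched to the nearest candidate genotype; clusters whose
#' genotype matches no candidate are labelled provisional. `tau` is in the
#' units of the signal matrix: 0.1 suits centered log-expression signals;
#' use ~1 for z-score signals.
#'
#' @param signal cell x region matrix (tumor cells only).
#' @param candidates list of candidate genotypes: named integer vectors over
#'   region event ids with values -1/0/+1 (direction of carried events).
#' @param k_range integer(2) range of cluster counts to scan.
#' @param tau genotype-call threshold on mean region signal (default 0.1).
#' @param scale optional per-region noise scale (e.g. the `ref_sd`
#'   attribute of the signal matrix); distances are computed on
#'   signal / scale so regions contribute in units of reference noise,
#'   while genotype calls stay on the raw signal.
#' @param min_cluster_cells smallest cluster that can contribute a new
#'   genotype during cut selection (default 10).
#' @return list of class `subclone_assignment`: `cluster` (per cell),
#'   `genotypes` (cluster x region calls), `labels` (per-cluster matched
#'   candidate or `"provisional_*"`), `subclone` (per-cell label), `k`,
#'   `silhouette` (mean width per candidate k; NA when degenerate).
#' @export
cluster_subclones <- function(signal, candidates, k_range = NULL, tau = 0.1,
                              scale = attr(signal, "ref_sd"),
                              min_cluster_cells = 10) {
  if (is.null(dim(signal)) || ncol(signal) < 1)
    stop("empty region signal matrix", call. = FALSE)
  n <- nrow(signal)
  if (n < 2) stop("need at least two cells", call. = FALSE)
  if (is.null(k_range)) k_range <- c(2L, length(candidates) + 1L)
  k_max <- min(k_range[2L], n - 1L)
  ks <- seq(max(2L, k_range[1L]), max(2L, k_max))
  if (any(ks > n)) stop("fewer cells than clusters requested", call. = FALSE)

  dmat <- signal
  if (!is.null(scale) && all(is.finite(scale)) && all(scale > 0))
    dmat <- sweep(signal, 2, scale, "/")
  d <- stats::dist(dmat)
  hc <- stats::hclust(d, method = "ward.D2")

  regions <- colnames(signal)
  cand_mat <- if (length(candidates))
    do.call(rbind, lapply(candidates, function(g) as.integer(g[regions])))
    else NULL
  call_genotypes <- function(cl) {
    k <- max(cl)
    calls <- vapply(seq_len(k), function(g) {
      m <- colMeans(signal[cl == g, , drop = FALSE])
      ifelse(m > tau, 1L, ifelse(m < -tau, -1L, 0L))
    }, integer(length(regions)))
    genotypes <- matrix(calls, nrow = k, ncol = length(regions),
                        byrow = TRUE,
                        dimnames = list(NULL, regions))
    labels <- character(k)
    for (g in seq_len(k)) {
      if (is.null(cand_mat)) {
        labels[g] <- sprintf("provisional_%d", g); next
      }
      dist_to <- rowSums(cand_mat != matrix(genotypes[g, ], nrow(cand_mat),
                                            length(regions), byrow = TRUE))
      best <- which.min(dist_to)
      labels[g] <- if (dist_to[best] == 0) names(candidates)[best]
                   else sprintf("provisional_%d", g)
    }
    list(genotypes = genotypes, labels = labels)
  }

  degenerate <- max(d) == 0
  sil <- rep(NA_real_, length(ks))
  n_geno <- rep(0L, length(ks))
  if (!degenerate) {
    for (j in seq_along(ks)) {
      cl <- stats::cutree(hc, k = ks[j])
      if (length(unique(cl)) < 2) next
      sw <- cluster::silhouette(cl, d)
      sil[j] <- mean(sw[, "sil_width"])
      gt <- call_genotypes(cl)
      big <- tabulate(cl, nbins = ks[j]) >= min_cluster_cells
      n_geno[j] <- length(unique(
        apply(gt$genotypes[big, , drop = FALSE], 1, paste, collapse = ",")))
    }
  }
  if (all(is.na(sil))) {
    k <- 1L
    cl <- rep(1L, n)
  } else {
    pick <- order(-n_geno, -ifelse(is.na(sil), -Inf, sil), ks)[1L]
    k <- ks[pick]
    cl <- stats::cutree(hc, k = k)
  }

  gt <- call_genotypes(cl)
  genotypes <- gt$genotypes
  labels <- gt$labels

  structure(list(
    cluster = stats::setNames(cl, rownames(signal)),
    genotypes = genotypes, labels = labels,
    subclone = stats::setNames(labels[cl], rownames(signal)),
    k = k,
    silhouette = stats::setNames(sil, ks),
    degenerate = degenerate
  ), class = "subclone_assignment")
}

#' Detect subclones in one modality end to end
#'
#' Convenience driver: computes the region signal for the modality
#' (log-expression signal for RNA; 10 Mb bin z-scores for ATAC), restricts
#' to tumor cells and runs [cluster_subclones()] with a modality-appropriate
#' genotype threshold (`tau` 0.1 in log-expression units, 1 in z units).
#'
#' @param mat a QC-filtered `cell_feature_matrix` (both sites merged,
#'   reference cells included).
#' @param regions WGS subclonal regions ([wgs_subclonal_regions()]).
#' @param candidates candidate genotypes ([candidate_genotypes()]).
#' @param genome named chromosome lengths (ATAC only).
#' @param tau genotype threshold override.
#' @param ... passed to [cluster_subclones()].
#' @return a `subclone_assignment` with an extra `cells` element (the tumor
#'   cell metadata, aligned with the assignment).
#' @export
detect_subclones <- function(mat, regions, candidates, genome = NULL,
                             tau = NULL, ...) {
  stopifnot(inherits(mat, "cell_feature_matrix"))
  if (mat$modality == "rna") {
    sig <- region_signal_rna(mat, regions)
    if (is.null(tau)) tau <- 0.1
  } else {
    if (is.null(genome)) stop("genome lengths required for ATAC",
                              call. = FALSE)
    frags <- fragments_from_tiles(mat)
    sig <- region_signal_atac(frags, regions, genome,
                              mat$cells$cell[mat$cells$reference])
    sig <- sig[match(mat$cells$cell, rownames(sig)), , drop = FALSE]
    attr(sig, "ref_sd") <- apply(
      sig[mat$cells$reference, , drop = FALSE], 2, stats::sd)
    if (is.null(tau)) tau <- 1
  }
  tum <- !mat$cells$reference
  scale <- attr(sig, "ref_sd")
  asn <- cluster_subclones(sig[tum, , drop = FALSE], candidates,
                           tau = tau, scale = scale, ...)
  asn$cells <- mat$cells[tum, , drop = FALSE]
  asn
}

#' Candidate subclone genotypes from a clone tree
#'
#' @param tree a `clone_tree`; @param cna_events placed events.
#' @param regions region event ids to restrict to.
#' @return named list of -1/0/+1 genotype vectors over `regions`.
#' @export
candidate_genotypes <- function(tree, cna_events, regions) {
  out <- lapply(seq_len(nrow(tree$subclones)), function(s) {
    carried <- carried_events(tree, s)
    g <- stats::setNames(integer(length(regions)), regions)
    ev <- cna_events[cna_events$event_id %in% carried &
                       cna_events$event_id %in% regions, , drop = FALSE]
    g[ev$event_id] <- ev$direction
    g
  })
  names(out) <- paste0("S", seq_len(nrow(tree$subclones)))
  out
}

#' Confirm subclones across modalities and bulk WGS
#'
#' A subclone (cluster genotype) is confirmed when its genotype matches a
#' WGS-consistent candidate (it was matched, i.e. not provisional, and its
#' defining events are in the bulk WGS subclonal region set), or when the
#' identical genotype is independently recovered in the second single-cell
#' modality. Provisional genotypes supported by neither are excluded — the
#' situation where one modality suggests an event combination that bulk
#' WGS and the other modality never show.
#'
#' @param rna a `subclone_assignment`; @param atac one or `NULL`.
#' @param wgs_regions data.frame of WGS subclonal regions (with `event_id`).
#' @return data.frame: `label`, `genotype` (collapsed string), `in_rna`,
#'   `in_atac`, `wgs_support`, `confirmed`, `evidence`.
#' @export
confirm_subclones <- function(rna, atac = NULL, wgs_regions) {
  gstring <- function(asn) apply(asn$genotypes, 1, paste, collapse = ",")
  tab <- data.frame(label = rna$labels, genotype = gstring(rna),
                    in_rna = TRUE, stringsAsFactors = FALSE)
  tab <- tab[!duplicated(tab$genotype), , drop = FALSE]
  atac_geno <- if (!is.null(atac)) gstring(atac) else character(0)
  tab$in_atac <- tab$genotype %in% atac_geno

  wgs_ids <- wgs_regions$event_id
  regions <- colnames(rna$genotypes)
  tab$wgs_support <- vapply(seq_len(nrow(tab)), function(i) {
    gt <- rna$genotypes[match(tab$genotype[i], gstring(rna)), ]
    defining <- regions[gt != 0]
    !grepl("^provisional", tab$label[i]) && all(defining %in% wgs_ids)
  }, logical(1))

  tab$confirmed <- tab$wgs_support | tab$in_atac
  tab$evidence <- vapply(seq_len(nrow(tab)), function(i)
    paste(c("RNA", if (tab$in_atac[i]) "ATAC",
            if (tab$wgs_support[i]) "WGS"), collapse = "+"), character(1))
  tab
}

#' Per-site composition of confirmed subclones
#'
#' @param assignment a `subclone_assignment` (per-cell `subclone` labels).
#' @param sites character vector of per-cell site labels (same order).
#' @param confirmed character vector of confirmed subclone labels.
#' @param unique_frac,unique_cells a subclone is site-unique when at the
#'   other site it has fewer than `unique_cells` cells and less than
#'   `unique_frac` of that site's cells (defaults 5 and 1%).
#' @param plasticity_cells cells needed at both sites for the
#'   plasticity-eligible flag (default > 50).
#' @return data.frame: `subclone`, one count and one proportion column per
#'   site, `unique_to`, `plasticity_eligible`.
#' @export
site_composition <- function(assignment, sites, confirmed = NULL,
                             unique_frac = 0.01, unique_cells = 5,
                             plasticity_cells = 50) {
  labels <- assignment$subclone
  stopifnot(length(sites) == length(labels))
  if (!is.null(confirmed)) {
    keep <- labels %in% confirmed
    labels <- labels[keep]; sites <- sites[keep]
  }
  site_levels <- unique(sites)
  if (any(table(factor(sites, site_levels)) == 0))
    warning("site with zero tumor cells: proportions undefined", call. = FALSE)
  tab <- table(subclone = labels, site = factor(sites, site_levels))
  props <- prop.table(tab, margin = 2)
  out <- data.frame(subclone = rownames(tab), stringsAsFactors = FALSE)
  for (s in site_levels) {
    out[[paste0("n_", s)]] <- as.integer(tab[, s])
    out[[paste0("prop_", s)]] <- as.numeric(props[, s])
  }
  if (length(site_levels) == 2) {
    a <- site_levels[1L]; b <- site_levels[2L]
    uniq <- function(n_other, p_other, here_n)
      here_n > 0 & n_other < unique_cells & p_other < unique_frac
    out$unique_to <- ifelse(
      uniq(out[[paste0("n_", b)]], out[[paste0("prop_", b)]],
           out[[paste0("n_", a)]]), a,
      ifelse(uniq(out[[paste0("n_", a)]], out[[paste0("prop_", a)]],
                  out[[paste0("n_", b)]]), b, NA_character_))
    out$plasticity_eligible <- out[[paste0("n_", a)]] > plasticity_cells &
      out[[paste0("n_", b)]] > plasticity_cells
  }
  out
}

#' Per-variant site enrichment test on single-cell mutation calls
#'
#' For each variant, counts mutant and covered cells per site (cells with at
#' least one read over the position), computes the odds ratio and a
#' two-sided Fisher exact p-value, and flags site-enriched variants at
#' Benjamini-Hochberg adjusted p < `alpha`.
#'
#' @param cell_calls data.frame: `cell`, `variant`, `ref_reads`, `alt_reads`,
#'   `site` (two site labels).
#' @param alpha significance level on adjusted p (default 0.05).
#' @return data.frame per variant: per-site mutant/covered counts, `odds_ratio`,
#'   `p`, `p_adj`, `enriched_site` (NA when not significant), `testable`.
#' @export
sc_snv_site_test <- function(cell_calls, alpha = 0.05) {
  covered <- cell_calls$ref_reads + cell_calls$alt_reads >= 1
  cc <- cell_calls[covered, , drop = FALSE]
  sites <- unique(cell_calls$site)
  stopifnot(length(sites) == 2)
  variants <- unique(cell_calls$variant)

  rows <- lapply(variants, function(v) {
    d <- cc[cc$variant == v, , drop = FALSE]
    n_cov <- vapply(sites, function(s) sum(d$site == s), integer(1))
    n_mut <- vapply(sites, function(s)
      sum(d$site == s & d$alt_reads > 0), integer(1))
    testable <- sum(n_cov) > 0 && all(n_cov > 0)
    if (!testable) {
      return(data.frame(variant = v, mut_a = n_mut[1L], cov_a = n_cov[1L],
                        mut_b = n_mut[2L], cov_b = n_cov[2L],
                        odds_ratio = NA_real_, p = NA_real_,
                        testable = FALSE, stringsAsFactors = FALSE))
    }
    m <- matrix(c(n_mut[1L], n_cov[1L] - n_mut[1L],
                  n_mut[2L], n_cov[2L] - n_mut[2L]), 2, byrow = TRUE)
    ft <- stats::fisher.test(m)
    p1 <- n_mut[1L] / n_cov[1L]; p2 <- n_mut[2L] / n_cov[2L]
    or <- (p1 / (1 - p1 + 1e-300)) / max(p2 / (1 - p2 + 1e-300), 1e-300)
    if (sum(n_mut) == 0) or <- 1
    data.frame(variant = v, mut_a = n_mut[1L], cov_a = n_cov[1L],
               mut_b = n_mut[2L], cov_b = n_cov[2L],
               odds_ratio = or, p = if (sum(n_mut) == 0) 1 else ft$p.value,
               testable = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  tested <- out$testable
  out$p_adj[tested] <- stats::p.adjust(out$p[tested], method = "BH")
  prop_a <- out$mut_a / out$cov_a
  prop_b <- out$mut_b / out$cov_b
  out$enriched_site <- ifelse(
    tested & !is.na(out$p_adj) & out$p_adj < alpha,
    ifelse(prop_a > prop_b, sites[1L], sites[2L]), NA_character_)
  names(out)[names(out) == "mut_a"] <- paste0("mut_", sites[1L])
  names(out)[names(out) == "cov_a"] <- paste0("cov_", sites[1L])
  names(out)[names(out) == "mut_b"] <- paste0("mut_", sites[2L])
  names(out)[names(out) == "cov_b"] <- paste0("cov_", sites[2L])
  out
}
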