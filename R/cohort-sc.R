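#' Simulate single-cell counts with copy-number dosage effects
#'
#' Draws a per-cell subclone label from the site's prevalences, then samples
#' feature counts from a count model whose mean scales with the carrier's
#' local copy number: a feature inside an event carried by the cell's
#' subclone has its mean multiplied by `1 + (CN - 2) * (dosage_effect - 1)`
#' (gain 1.5x, single-copy loss 0.5x at the default dosage effect). RNA uses
#' a negative binomial over genes; ATAC uses a Poisson over fixed genomic
#' tiles from which a fragment table can be expanded. A block of neutral
#' normal-plasma-cell reference cells is appended, and per-cell QC metadata
#' (with a small fraction of deliberately failing cells) is populated.
#'
#' @param tree a `clone_tree`; @param config a `sim_config`.
#' @param site site label; @param modality `"rna"` or `"atac"`.
#' @param cna_events placed events ([place_cna_events()]); derived from
#'   `config$seed` when omitted so modalities and sites agree.
#' @param n_cells tumor cells to draw (default from config).
#' @param tile_width ATAC elementary tile width in bp.
#' @return list of class `cell_feature_matrix`: `counts` (features x cells,
#'   sparse), `features` (coordinates; 0-based half-open), `cells`
#'   (metadata: `cell`, `site`, `modality`, `reference`, `subclone` truth
#'   label, QC columns), `modality`.
#' @export
simulate_sc_counts <- function(tree, config, site, modality = c("rna", "atac"),
                               cna_events = NULL, n_cells = NULL,
                               tile_width = 2.5e6) {
  modality <- match.arg(modality)
  stopifnot(site %in% colnames(tree$prevalence))
  if (is.null(n_cells)) n_cells <- config$n_cells[[modality]]
  if (n_cells < 1) stop("at least one cell must be requested", call. = FALSE)
  if (is.null(cna_events))
    cna_events <- place_cna_events(tree, config, seed = config$seed)

  si <- match(site, colnames(tree$prevalence))
  set.seed(config$seed + 104729L * si + if (modality == "rna") 0L else 1L)

  n_ref <- config$n_ref_cells
  n_sub <- nrow(tree$subclones)
  labels <- sample(seq_len(n_sub), n_cells, replace = TRUE,
                   prob = tree$prevalence[, si])

  if (modality == "rna") {
    feats <- config$genome$genes
    feat_gr_mid <- feats$mid
    base_mean <- stats::rexp(nrow(feats), rate = 2)   # mean ~0.5 UMI
  } else {
    lens <- config$genome$chrom_lengths
    feats <- do.call(rbind, lapply(names(lens), function(ch) {
      starts <- seq(0, lens[[ch]] - 1, by = tile_width)
      data.frame(gene = sprintf("%s_tile_%05d", ch, seq_along(starts)),
                 chrom = ch, start = starts,
                 end = pmin(starts + tile_width, lens[[ch]]),
                 stringsAsFactors = FALSE)
    }))
    feats$mid <- (feats$start + feats$end) / 2
    feat_gr_mid <- feats$mid
    base_mean <- stats::runif(nrow(feats), 0.7, 1.3) *
      config$atac_mean_fragments / nrow(feats)
  }

  # feature x subclone copy-number multiplier
  mult <- matrix(1, nrow(feats), n_sub)
  d <- config$dosage_effect
  for (s in seq_len(n_sub)) {
    carried <- carried_events(tree, s)
    ev <- cna_events[cna_events$event_id %in% carried, , drop = FALSE]
    for (k in seq_len(nrow(ev))) {
      inside <- feats$chrom == ev$chrom[k] & feat_gr_mid >= ev$start[k] &
        feat_gr_mid < ev$end[k]
      cn <- ev$total_cn[k]
      mult[inside, s] <- mult[inside, s] * max(0, 1 + (cn - 2) * (d - 1))
    }
  }

  all_labels <- c(labels, rep(NA_integer_, n_ref))   # NA = reference cell
  n_tot <- n_cells + n_ref
  depth_factor <- stats::rlnorm(n_tot, 0, 0.25)
  counts <- matrix(0L, nrow(feats), n_tot)
  for (i in seq_len(n_tot)) {
    m <- base_mean * depth_factor[i]
    if (!is.na(all_labels[i])) m <- m * mult[, all_labels[i]]
    counts[, i] <- if (modality == "rna")
      stats::rnbinom(nrow(feats), mu = m, size = config$nb_size)
    else
      stats::rpois(nrow(feats), m)
  }
  counts <- Matrix::Matrix(counts, sparse = TRUE)
  cell_ids <- sprintf("%s_%s_c%04d", site, modality, seq_len(n_tot))
  dimnames(counts) <- list(feats$gene, cell_ids)

  cells <- data.frame(
    cell = cell_ids, site = site, modality = modality,
    reference = is.na(all_labels), subclone = all_labels,
    stringsAsFactors = FALSE
  )
  fail <- stats::runif(n_tot) < 0.04   # small block of QC-failing cells
  if (modality == "rna") {
    cells$mito_frac <- stats::rbeta(n_tot, 2, 80)
    cells$mito_frac[fail] <- stats::runif(sum(fail), 0.06, 0.2)
    cells$n_features <- Matrix::colSums(counts > 0)
    cells$doublet_score <- stats::rbeta(n_tot, 2, 30)
    dbl <- stats::runif(n_tot) < 0.03
    cells$doublet_score[dbl] <- stats::runif(sum(dbl), 0.35, 0.9)
  } else {
    cells$tss_score <- pmax(0.5, stats::rnorm(n_tot, 13, 2))
    cells$tss_score[fail] <- stats::runif(sum(fail), 3, 7.5)
    cells$n_fragments <- Matrix::colSums(counts)
    cells$doublet_enrichment <- stats::rexp(n_tot, 1)
    dbl <- stats::runif(n_tot) < 0.03
    cells$doublet_enrichment[dbl] <- stats::runif(sum(dbl), 6.5, 12)
    cells$doublet_score_pred <- stats::runif(n_tot, 0, 150)
    cells$doublet_score_pred[dbl] <- stats::runif(sum(dbl), 210, 400)
  }

  structure(list(counts = counts, features = feats, cells = cells,
                 modality = modality),
            class = "cell_feature_matrix")
}

#' Expand a tiled ATAC matrix into a fragment table
#'
#' @param mat a `cell_feature_matrix` with `modality == "atac"`.
#' @return data.frame: `chrom`, `start`, `end`, `barcode`, `count`
#'   (aggregated fragments per cell per tile; zero rows dropped).
#' @export
fragments_from_tiles <- function(mat) {
  stopifnot(inherits(mat, "cell_feature_matrix"), mat$modality == "atac")
  tm <- methods::as(mat$counts, "TsparseMatrix")
  data.frame(
    chrom = mat$features$chrom[tm@i + 1L],
    start = mat$features$start[tm@i + 1L],
    end = mat$features$end[tm@i + 1L],
    barcode = colnames(mat$counts)[tm@j + 1L],
    count = tm@x,
    stringsAsFactors = FALSE
  )
}

#' Simulate a peak-by-cell accessibility matrix
#'
#' Peaks are laid out along one chromosome at a fixed spacing with
#' independent Poisson counts. Optionally a pair of peaks is made truly
#' co-accessible by coupling both to a shared latent on/off state across
#' cells, optionally restricted to a group of cells (so the link exists only
#' in that group).
#'
#' @param n_cells,n_peaks matrix dimensions.
#' @param spacing center-to-center peak spacing in bp.
#' @param mean_count Poisson mean of an accessible peak.
#' @param seed integer seed.
#' @param planted_pair integer(2) peak indices to couple, or NULL.
#' @param planted_on_prob probability the latent state is on.
#' @param groups optional character vector of cell group labels.
#' @param planted_group restrict the planted coupling to this group.
#' @return list of class `peak_matrix`: `counts` (peaks x cells sparse),
#'   `peaks` (chrom/start/end), `cells` (cell, group), `planted_pair`.
#' @export
simulate_peak_matrix <- function(n_cells, n_peaks, spacing = 2e4,
                                 mean_count = 1, seed = 1L,
                                 planted_pair = NULL, planted_on_prob = 0.5,
                                 groups = NULL, planted_group = NULL) {
  set.seed(seed)
  counts <- matrix(stats::rpois(n_peaks * n_cells, mean_count),
                   n_peaks, n_cells)
  if (is.null(groups)) groups <- rep("all", n_cells)
  if (!is.null(planted_pair)) {
    stopifnot(length(planted_pair) == 2L)
    state <- stats::rbinom(n_cells, 1L, planted_on_prob)
    target <- if (is.null(planted_group)) rep(TRUE, n_cells)
              else groups == planted_group
    for (pk in planted_pair) {
      lam <- ifelse(state == 1L, mean_count * 3, mean_count * 0.05)
      new <- stats::rpois(n_cells, lam)
      counts[pk, target] <- new[target]
    }
  }
  peaks <- data.frame(
    peak = sprintf("peak_%04d", seq_len(n_peaks)), chrom = "chr1",
    start = seq_len(n_peaks) * spacing,
    end = seq_len(n_peaks) * spacing + 500L, stringsAsFactors = FALSE)
  cells <- data.frame(cell = sprintf("c%05d", seq_len(n_cells)),
                      group = groups, stringsAsFactors = FALSE)
  counts <- Matrix::Matrix(counts, sparse = TRUE,
                           dimnames = list(peaks$peak, cells$cell))
  structure(list(counts = counts, peaks = peaks, cells = cells,
                 planted_pair = planted_pair), class = "peak_matrix")
}
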