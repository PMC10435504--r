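#' Build clonotypes from chain-level contig records
#'
#' Only productive contigs with a non-empty CDR3 enter clonotyping. Cells
#' with both a TRA and a TRB define clonotypes by the (TRA, TRB) CDR3 pair;
#' a cell with a single sequenced chain is merged into an existing clonotype
#' iff its chain matches exactly one clonotype's corresponding chain,
#' otherwise it remains its own singleton clonotype.
#'
#' @param contigs data.frame: `cell_id`, `chain` (TRA/TRB), `cdr3`,
#'   `productive`, `site`.
#' @return list with `clonotypes` (data.frame: `clonotype_id`, `cdr3_tra`,
#'   `cdr3_trb`, per-site `n_<site>` counts, `n_total`), `cell_map`
#'   (`cell_id`, `clonotype_id`, `site`, `merged` flag for single-chain
#'   merges) and `assignment_rate` (assigned cells / cells with any
#'   productive chain).
#' @export
assign_clonotypes <- function(contigs) {
  ct <- contigs[contigs$productive & !is.na(contigs$cdr3) &
                  nzchar(contigs$cdr3), , drop = FALSE]
  dup <- stats::aggregate(cdr3 ~ cell_id + chain, ct,
                          function(x) length(unique(x)))
  conflict <- dup$cell_id[dup$cdr3 > 1]
  if (length(conflict))
    stop("conflicting CDR3 for the same chain in cell(s): ",
         paste(unique(conflict), collapse = ", "), call. = FALSE)
  ct <- ct[!duplicated(ct[c("cell_id", "chain")]), , drop = FALSE]

  wide <- merge(
    stats::setNames(ct[ct$chain == "TRA", c("cell_id", "cdr3", "site")],
                    c("cell_id", "tra", "site")),
    stats::setNames(ct[ct$chain == "TRB", c("cell_id", "cdr3", "site")],
                    c("cell_id", "trb", "site")),
    by = c("cell_id", "site"), all = TRUE)

  paired <- !is.na(wide$tra) & !is.na(wide$trb)
  key <- paste(wide$tra, wide$trb, sep = "|")
  pair_keys <- unique(key[paired])
  clon_id <- stats::setNames(seq_along(pair_keys), pair_keys)
  wide$clonotype <- NA_integer_
  wide$clonotype[paired] <- clon_id[key[paired]]
  wide$merged <- FALSE

  clon_tra <- sub("\\|.*", "", pair_keys)
  clon_trb <- sub(".*\\|", "", pair_keys)
  next_id <- length(pair_keys)
  for (i in which(!paired)) {
    chain_val <- if (is.na(wide$trb[i])) wide$tra[i] else wide$trb[i]
    pool <- if (is.na(wide$trb[i])) clon_tra else clon_trb
    hit <- which(pool == chain_val)
    if (length(hit) == 1L) {
      wide$clonotype[i] <- hit
      wide$merged[i] <- TRUE
    } else {
      next_id <- next_id + 1L
      wide$clonotype[i] <- next_id
      clon_tra <- c(clon_tra, if (is.na(wide$trb[i])) chain_val else NA)
      clon_trb <- c(clon_trb, if (is.na(wide$trb[i])) NA else chain_val)
    }
  }

  sites <- unique(wide$site)
  clons <- data.frame(clonotype_id = seq_len(next_id),
                      cdr3_tra = clon_tra, cdr3_trb = clon_trb,
                      stringsAsFactors = FALSE)
  for (s in sites)
    clons[[paste0("n_", s)]] <- as.integer(
      table(factor(wide$clonotype[wide$site == s], levels = seq_len(next_id))))
  clons$n_total <- rowSums(as.matrix(
    clons[paste0("n_", sites)], rownames.force = FALSE))

  list(clonotypes = clons,
       cell_map = wide[c("cell_id", "site", "clonotype", "merged")],
       assignment_rate = sum(!is.na(wide$clonotype)) / nrow(wide))
}

#' Classify clonotype expansion
#'
#' A clonotype is \emph{expanded} when it comprises at least `expanded_prop`
#' (default 1%) of the site's T cells at one or more sites and has at least
#' `min_cells` (default 5) cells in one of the paired samples;
#' \emph{hyperexpanded} when its proportion reaches `hyper_prop` (default
#' 5%, same count floor); otherwise `none`.
#'
#' @param clonotypes data.frame with per-site `n_<site>` counts.
#' @param totals named per-site T-cell totals (> 0); defaults to column
#'   sums of the count columns.
#' @param expanded_prop,hyper_prop,min_cells thresholds.
#' @param pooled use the pooled (across-site) proportion instead of per-site
#'   proportions (default FALSE).
#' @return `clonotypes` with per-site `prop_<site>` columns and an
#'   `expansion` column (`none`/`expanded`/`hyperexpanded`).
#' @export
classify_expansion <- function(clonotypes, totals = NULL,
                               expanded_prop = 0.01, hyper_prop = 0.05,
                               min_cells = 5, pooled = FALSE) {
  count_cols <- grep("^n_(?!total)", names(clonotypes), value = TRUE,
                     perl = TRUE)
  sites <- sub("^n_", "", count_cols)
  if (is.null(totals))
    totals <- stats::setNames(colSums(clonotypes[count_cols]), sites)
  if (any(totals <= 0)) stop("per-site totals must be > 0", call. = FALSE)
  counts <- as.matrix(clonotypes[count_cols])
  if (any(counts > matrix(totals[sites], nrow(counts), length(sites),
                          byrow = TRUE)))
    stop("clonotype count exceeds site total", call. = FALSE)

  props <- t(t(counts) / as.numeric(totals[sites]))
  if (pooled)
    props <- matrix(rowSums(counts) / sum(totals), nrow(counts),
                    length(sites))
  floor_ok <- apply(counts, 1, max) >= min_cells
  expanded <- apply(props, 1, max) >= expanded_prop & floor_ok
  hyper <- apply(props, 1, max) >= hyper_prop & floor_ok

  out <- clonotypes
  for (k in seq_along(sites))
    out[[paste0("prop_", sites[k])]] <- counts[, k] / totals[[sites[k]]]
  out$expansion <- ifelse(hyper, "hyperexpanded",
                          ifelse(expanded, "expanded", "none"))
  out
}

#' Compare clonotype proportions between paired sites
#'
#' Clonotypes with at least `min_pair_cells` (default 10) cells at one site
#' are pairing-eligible; eligible clonotypes with zero cells at the other
#' site are site-unique. The spatial-variation flag marks an at least
#' `fold` (default 3) difference between site proportions; when one side is
#' zero the ratio uses a 0.5-cell pseudocount.
#'
#' @param clonotypes classified table from [classify_expansion()] with
#'   per-site `n_<site>` and `prop_<site>` columns.
#' @param totals named per-site totals (defaults to count-column sums).
#' @param min_pair_cells,fold thresholds.
#' @return `clonotypes` with `pairing_eligible`, `site_unique` (site label
#'   or NA), `fold_ratio` and `spatial_variation` columns.
#' @export
compare_sites <- function(clonotypes, totals = NULL, min_pair_cells = 10,
                          fold = 3) {
  count_cols <- grep("^n_(?!total)", names(clonotypes), value = TRUE,
                     perl = TRUE)
  sites <- sub("^n_", "", count_cols)
  stopifnot(length(sites) == 2)
  counts <- as.matrix(clonotypes[count_cols])
  if (is.null(totals))
    totals <- stats::setNames(colSums(clonotypes[count_cols]), sites)

  out <- clonotypes
  out$pairing_eligible <- apply(counts, 1, max) >= min_pair_cells
  out$site_unique <- ifelse(
    out$pairing_eligible & counts[, 2L] == 0, sites[1L],
    ifelse(out$pairing_eligible & counts[, 1L] == 0, sites[2L],
           NA_character_))
  pseudo <- counts
  pseudo[pseudo == 0] <- 0.5
  p1 <- pseudo[, 1L] / totals[[sites[1L]]]
  p2 <- pseudo[, 2L] / totals[[sites[2L]]]
  out$fold_ratio <- pmax(p1 / p2, p2 / p1)
  out$spatial_variation <- out$pairing_eligible & out$fold_ratio >= fold
  out
}

#' Gene-set module score with expression-matched controls
#'
#' Per cell, the score is the mean normalised expression of the target gene
#' set minus the mean of control genes sampled (seeded) from expression bins
#' matched to each target gene — the conventional single-cell signature
#' score (used here for T-cell exhaustion and cytotoxicity sets).
#'
#' @param mat a `cell_feature_matrix` (RNA) or a plain genes x cells matrix.
#' @param gene_set character vector of target genes; at least one must be
#'   present.
#' @param n_bins number of average-expression bins (default 24).
#' @param n_ctrl control genes sampled per target gene (default 100).
#' @param seed integer seed.
#' @param normalize depth-normalise and log1p the counts first (default
#'   TRUE; set FALSE when the matrix is already normalised).
#' @return named numeric vector of per-cell scores.
#' @export
module_score <- function(mat, gene_set, n_bins = 24, n_ctrl = 100,
                         seed = 1L, normalize = TRUE) {
  x <- if (inherits(mat, "cell_feature_matrix")) as.matrix(mat$counts)
       else as.matrix(mat)
  present <- intersect(gene_set, rownames(x))
  if (!length(present))
    stop("no gene of the set found in the matrix; missing: ",
         paste(gene_set, collapse = ", "), call. = FALSE)
  if (normalize) {
    depth <- colSums(x)
    depth[depth == 0] <- 1
    x <- log1p(t(t(x) / depth * 1e4))
  }
  avg <- rowMeans(x)
  brk <- unique(stats::quantile(avg, seq(0, 1, length.out = n_bins + 1)))
  bin <- if (length(brk) < 2) rep(1L, length(avg))
         else cut(avg, breaks = brk, include.lowest = TRUE, labels = FALSE)

  set.seed(seed)
  ctrl <- unique(unlist(lapply(present, function(g) {
    pool <- setdiff(rownames(x)[bin == bin[match(g, rownames(x))]], present)
    if (!length(pool)) return(character(0))
    sample(pool, min(n_ctrl, length(pool)))
  })))
  target_mean <- colMeans(x[present, , drop = FALSE])
  ctrl_mean <- if (length(ctrl)) colMeans(x[ctrl, , drop = FALSE]) else 0
  target_mean - ctrl_mean
}

#' Canonical T-cell state gene sets
#' @return named list with `exhaustion` and `cytotoxicity` gene symbols.
#' @export
tcell_state_gene_sets <- function() {
  list(
    exhaustion = c("TIGIT", "HAVCR2", "CTLA4", "PDCD1", "LAG3", "LAYN"),
    cytotoxicity = c("NKG7", "CCL4", "CST7", "PRF1", "GZMA", "GZMB",
                     "IFNG", "CCL3")
  )
}
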