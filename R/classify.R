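#' Classify one SNV across a paired sample
#'
#' Applies the paired-site heterogeneity rules to the CCF estimates of the
#' same variant in the two bone-marrow sites (random aspirate vs focal
#' lesion):
#' \itemize{
#'   \item \strong{filtered} — the CCF exceeds 0.15 in neither sample.
#'   \item \strong{major / minor} — a mutation is \emph{major} when the upper
#'     bound of its 95% CCF interval reaches 1 at the dominant (higher-CCF)
#'     site, \emph{minor} otherwise.
#'   \item \strong{unshared} — the variant is undetectable at the partner
#'     site: its CCF is below the detection floor and its variant read count
#'     does not exceed what the sequencing error rate alone would produce.
#'   \item \strong{enriched} — detected at both sites, major at the dominant
#'     site, and the CCF point-estimate ratio is at least `enrich_ratio`
#'     (default 3).
#'   \item \strong{shared} — everything retained that is neither unshared
#'     nor enriched.
#' }
#'
#' @param est_a,est_b one-row `ccf_estimate` data.frames for the same variant
#'   in samples A and B (as returned by [estimate_ccf()]).
#' @param sites character(2), labels of the two samples (default
#'   `c("RBM","FL")`).
#' @param ccf_floor retain only variants with CCF above this in at least one
#'   sample (default 0.15).
#' @param detection_floor CCF below which a variant can count as absent
#'   (default 0.05).
#' @param err_rate per-base substitution error rate used for the
#'   absent-partner read-count allowance (default 1e-3).
#' @param enrich_ratio fold-difference in CCF called enriched (default 3;
#'   ties at exactly the ratio count as enriched).
#'
#' @return one-row data.frame with columns `class` (one of `shared_major`,
#'   `shared_minor`, `unshared_major`, `unshared_minor`, `enriched`,
#'   `filtered`), `dominant_site`, `ccf_a`, `ccf_b`.
#' @export
classify_snv_pair <- function(est_a, est_b, sites = c("RBM", "FL"),
                              ccf_floor = 0.15, detection_floor = 0.05,
                              err_rate = 1e-3, enrich_ratio = 3) {
  stopifnot(inherits(est_a, "ccf_estimate") || is.data.frame(est_a),
            inherits(est_b, "ccf_estimate") || is.data.frame(est_b))
  ccfs <- c(est_a$ccf, est_b$ccf)
  dom <- which.max(ccfs)
  res <- function(class) data.frame(
    class = class, dominant_site = sites[dom],
    ccf_a = ccfs[1L], ccf_b = ccfs[2L], stringsAsFactors = FALSE)

  if (max(ccfs) <= ccf_floor) return(res("filtered"))

  est <- list(est_a, est_b)
  dom_est <- est[[dom]]
  min_est <- est[[3L - dom]]
  major <- dom_est$ci_high >= 1
  grade <- if (major) "major" else "minor"

  # absent at the partner site: CCF under the floor and no more variant
  # reads than sequencing error alone would explain
  err_allow <- 1 + min_est$total * err_rate
  absent <- min_est$ccf < detection_floor && min_est$alt <= err_allow
  if (absent) return(res(paste0("unshared_", grade)))

  # enrichment requires detection at both sites and a clonal-compatible
  # dominant call
  if (major && min_est$ccf > detection_floor &&
      dom_est$ccf / min_est$ccf >= enrich_ratio) return(res("enriched"))

  res(paste0("shared_", grade))
}

#' Classify paired-site SNVs in bulk
#'
#' @param est_tab_a,est_tab_b CCF tables from [estimate_ccf_table()] for the
#'   two samples; rows are matched by (`chrom`, `pos`).
#' @param ... passed to [classify_snv_pair()].
#' @return data.frame with one row per matched variant: `chrom`, `pos`,
#'   classification columns.
#' @export
classify_snv_table <- function(est_tab_a, est_tab_b, ...) {
  key_a <- paste(est_tab_a$chrom, est_tab_a$pos)
  key_b <- paste(est_tab_b$chrom, est_tab_b$pos)
  if (anyDuplicated(key_a) || anyDuplicated(key_b))
    stop("duplicate variant positions within a sample", call. = FALSE)
  common <- intersect(key_a, key_b)
  ia <- match(common, key_a); ib <- match(common, key_b)
  out <- do.call(rbind, lapply(seq_along(common), function(k) {
    classify_snv_pair(est_tab_a[ia[k], , drop = FALSE],
                      est_tab_b[ib[k], , drop = FALSE], ...)
  }))
  cbind(est_tab_a[ia, c("chrom", "pos")], out)
}

#' Classify one copy-number event across a paired sample
#'
#' Paired-site rules for copy-number aberrations: events no longer than the
#' minimum length are dropped; the segment CCF threshold 0.6 separates major
#' (dominant) from minor subclonal events. An event present in only one
#' sample is `unshared_major`/`unshared_minor` by that threshold; an event
#' dominating one sample (CCF > 0.6) while only a minor subclone
#' (0 < CCF <= 0.6) in the partner is `enriched`; anything else retained is
#' `shared`.
#'
#' @param seg_a,seg_b one-row data.frames with `chrom`, `start`, `end`
#'   (0-based half-open) and `seg_ccf`; either may be `NULL` when the event
#'   was not observed in that sample.
#' @param sites character(2) site labels.
#' @param min_length minimum event length in bp (default 200e3; events of
#'   exactly this length or shorter are filtered).
#' @param major_ccf segment-CCF cut separating major from minor events
#'   (default 0.6).
#' @return one-row data.frame with `class` and `dominant_site`.
#' @export
classify_cna_pair <- function(seg_a, seg_b, sites = c("RBM", "FL"),
                              min_length = 2e5, major_ccf = 0.6) {
  segs <- list(seg_a, seg_b)
  present <- !vapply(segs, is.null, logical(1))
  if (!any(present)) stop("event absent from both samples", call. = FALSE)
  len <- max(vapply(segs[present],
                    function(s) s$end - s$start, numeric(1)))
  ccf <- vapply(seq_along(segs), function(i)
    if (present[i]) segs[[i]]$seg_ccf else 0, numeric(1))
  dom <- which.max(ccf)
  res <- function(class) data.frame(
    class = class, dominant_site = sites[dom],
    ccf_a = ccf[1L], ccf_b = ccf[2L], stringsAsFactors = FALSE)

  if (len <= min_length) return(res("filtered"))

  grade <- if (ccf[dom] > major_ccf) "major" else "minor"
  if (sum(present) == 1L) return(res(paste0("unshared_", grade)))
  if (ccf[dom] > major_ccf && ccf[3L - dom] > 0 &&
      ccf[3L - dom] <= major_ccf) return(res("enriched"))
  res(paste0("shared_", grade))
}

#' Match and classify copy-number events between paired samples
#'
#' Events are matched across samples by 50% reciprocal interval overlap
#' (both directions) restricted to the same direction of change (gain with
#' gain, loss with loss); unmatched events are classified one-sided.
#'
#' @param segs_a,segs_b data.frames of CNA events per sample with columns
#'   `chrom`, `start`, `end`, `total_cn`, `seg_ccf`.
#' @param reciprocal minimum reciprocal-overlap fraction (default 0.5).
#' @param ... passed to [classify_cna_pair()].
#' @return data.frame of classifications, one row per matched event or
#'   one-sided event.
#' @export
classify_cna_table <- function(segs_a, segs_b, reciprocal = 0.5, ...) {
  for (s in list(segs_a, segs_b)) {
    if (is.null(s) || !nrow(s)) next
    gr <- GenomicRanges::GRanges(s$chrom,
                                 IRanges::IRanges(s$start + 1L, s$end))
    self <- GenomicRanges::findOverlaps(gr, drop.self = TRUE)
    if (length(self))
      stop("overlapping copy-number events within one sample", call. = FALSE)
  }
  dir_a <- sign(segs_a$total_cn - 2)
  dir_b <- sign(segs_b$total_cn - 2)
  gr_a <- GenomicRanges::GRanges(segs_a$chrom,
                                 IRanges::IRanges(segs_a$start + 1L, segs_a$end))
  gr_b <- GenomicRanges::GRanges(segs_b$chrom,
                                 IRanges::IRanges(segs_b$start + 1L, segs_b$end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr_a, gr_b))
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(IRanges::ranges(gr_a)[qi],
                                           IRanges::ranges(gr_b)[si]))
  keep <- ov >= reciprocal * IRanges::width(gr_a)[qi] &
    ov >= reciprocal * IRanges::width(gr_b)[si] &
    dir_a[qi] == dir_b[si]
  qi <- qi[keep]; si <- si[keep]

  rows <- list()
  for (k in seq_along(qi)) {
    rows[[length(rows) + 1L]] <- cbind(
      segs_a[qi[k], c("chrom", "start", "end")],
      classify_cna_pair(segs_a[qi[k], , drop = FALSE],
                        segs_b[si[k], , drop = FALSE], ...))
  }
  for (i in setdiff(seq_len(nrow(segs_a)), qi)) {
    rows[[length(rows) + 1L]] <- cbind(
      segs_a[i, c("chrom", "start", "end")],
      classify_cna_pair(segs_a[i, , drop = FALSE], NULL, ...))
  }
  for (j in setdiff(seq_len(nrow(segs_b)), si)) {
    rows[[length(rows) + 1L]] <- cbind(
      segs_b[j, c("chrom", "start", "end")],
      classify_cna_pair(NULL, segs_b[j, , drop = FALSE], ...))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise paired-site heterogeneity classes
#'
#' @param classes data.frame with a `class` column as produced by
#'   [classify_snv_table()] or [classify_cna_table()].
#' @return list with `counts` (named vector over all classes), `retained`
#'   (number of non-filtered events), `heterogeneous` (unshared + enriched
#'   count) and `heterogeneous_fraction` (as a percentage of retained;
#'   `NA` with `empty = TRUE` when nothing is retained).
#' @export
summarize_heterogeneity <- function(classes) {
  levels <- c("shared_major", "shared_minor", "unshared_major",
              "unshared_minor", "enriched", "filtered")
  cls <- if (nrow(classes)) classes$class else character(0)
  bad <- setdiff(unique(cls), levels)
  if (length(bad)) stop("unknown class label: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  counts <- table(factor(cls, levels = levels))
  retained <- sum(counts) - counts[["filtered"]]
  het <- counts[["unshared_major"]] + counts[["unshared_minor"]] +
    counts[["enriched"]]
  list(
    counts = c(counts),
    retained = retained,
    heterogeneous = het,
    heterogeneous_fraction = if (retained > 0) 100 * het / retained else NA_real_,
    empty = retained == 0
  )
}
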