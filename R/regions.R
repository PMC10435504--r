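#' Subclonal regions from paired bulk copy-number segments
#'
#' Collects copy-number events that are subclonal by bulk WGS (segment CCF
#' strictly between 0 and the clonal threshold at one or more sites); these
#' are the regions admitted to single-cell subclone detection.
#'
#' @param segments_by_site named list of per-site segment data.frames
#'   (`chrom`, `start`, `end`, `total_cn`, `seg_ccf`, `event_id`).
#' @param clonal_threshold segment CCF at or above which an event is clonal
#'   (default 0.95).
#' @return data.frame: `event_id`, `chrom`, `start`, `end`, `direction`,
#'   plus one `ccf_<site>` column per site (0 when absent).
#' @export
wgs_subclonal_regions <- function(segments_by_site, clonal_threshold = 0.95) {
  ids <- unique(unlist(lapply(segments_by_site, `[[`, "event_id")))
  rows <- lapply(ids, function(id) {
    recs <- lapply(segments_by_site, function(s)
      s[s$event_id == id, , drop = FALSE])
    present <- vapply(recs, nrow, integer(1)) > 0
    ref <- recs[[which(present)[1L]]]
    ccfs <- vapply(recs, function(r)
      if (nrow(r)) r$seg_ccf[1L] else 0, numeric(1))
    data.frame(event_id = id, chrom = ref$chrom[1L], start = ref$start[1L],
               end = ref$end[1L],
               direction = sign(ref$total_cn[1L] - 2),
               t(ccfs), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[seq(6, 5 + length(segments_by_site))] <-
    paste0("ccf_", names(segments_by_site))
  ccf_cols <- grep("^ccf_", names(out))
  sub <- apply(out[, ccf_cols, drop = FALSE], 1, function(x)
    any(x > 0 & x < clonal_threshold))
  out[sub, , drop = FALSE]
}
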