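#' Place the tree's SNVs on the genome
#'
#' SNV positions are drawn uniformly over the genome, excluding subclonal
#' copy-number regions so that every SNV sits on a locus whose total copy
#' number is the same in all tumor cells (diploid, or a clonal event's copy
#' number). Truncal SNVs falling inside a clonal gain are assigned a random
#' multiplicity in `1..n_locus`; all other SNVs have multiplicity 1.
#'
#' @param tree a `clone_tree`; @param config a `sim_config`.
#' @param cna_events placed events from [place_cna_events()].
#' @param seed integer seed.
#' @return data.frame: `event_id`, `owner`, `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `n_locus`, `multiplicity`.
#' @export
place_snvs <- function(tree, config, cna_events, seed = 1L) {
  set.seed(seed)
  ev <- tree$events[tree$events$type == "snv", , drop = FALSE]
  lens <- config$genome$chrom_lengths
  subclonal <- cna_events[cna_events$owner != 1L, , drop = FALSE]
  clonal <- cna_events[cna_events$owner == 1L, , drop = FALSE]

  n <- nrow(ev)
  chrom <- character(n); pos <- numeric(n)
  cum <- cumsum(as.numeric(lens))
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(1, 0, cum[length(cum)])
      ci <- findInterval(u, c(0, cum), rightmost.closed = TRUE)
      p <- ceiling(u - c(0, cum)[ci])
      p <- max(1, min(p, lens[[ci]]))
      ch <- names(lens)[ci]
      in_sub <- any(subclonal$chrom == ch & subclonal$start < p &
                      p <= subclonal$end)
      # subclonal SNVs stay off clonal events too (always diploid)
      in_clonal <- any(clonal$chrom == ch & clonal$start < p & p <= clonal$end)
      if (!in_sub && !(ev$owner[i] != 1L && in_clonal)) break
    }
    chrom[i] <- ch; pos[i] <- p
  }
  n_locus <- rep(2L, n)
  for (i in seq_len(n)) {
    hit <- clonal$chrom == chrom[i] & clonal$start < pos[i] &
      pos[i] <= clonal$end
    if (any(hit)) n_locus[i] <- clonal$total_cn[which(hit)[1L]]
  }
  if (any(n_locus == 0))
    stop("SNV placed on a locus with total copy number 0", call. = FALSE)
  # multiplicity > 1 only arises on clonally gained loci (truncal variants
  # preceding or following the gain); diploid and lost loci carry m = 1
  mult <- ifelse(n_locus > 2 & ev$owner == 1L,
                 vapply(n_locus, function(k) sample.int(k, 1L), integer(1)),
                 1L)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  data.frame(event_id = ev$event_id, owner = ev$owner, chrom = chrom,
             pos = as.integer(pos), ref = ref, alt = alt,
             n_locus = n_locus, multiplicity = as.integer(mult),
             stringsAsFactors = FALSE)
}

#' Simulate bulk whole-genome read counts for one site
#'
#' Inverts the mutation-copy-number relation to obtain the expected VAF of
#' each SNV, \eqn{f = m \cdot CCF \cdot p / (p\,n_{locus} + 2(1-p))}, mixes
#' in a symmetric substitution error, draws the total depth from a Poisson
#' around the configured coverage and the variant reads binomially. Also
#' emits the copy-number segment table detectable at the site (truncal
#' events at segment CCF 1; subclonal events at their carrier subtree CCF).
#'
#' @param tree a `clone_tree`; @param config a `sim_config`.
#' @param site site label (must be a column of `tree$prevalence`).
#' @param snvs,cna_events placements from [place_snvs()] /
#'   [place_cna_events()]; generated deterministically from `config$seed`
#'   when omitted, so paired sites share positions.
#' @return list with `variants` (chrom, pos, ref, alt, alt_reads,
#'   total_reads plus truth columns `true_ccf`, `true_multiplicity`,
#'   `n_locus`, `owner`) and `segments` (chrom, start, end, total_cn,
#'   seg_ccf, event_id).
#' @export
simulate_bulk_reads <- function(tree, config, site,
                                snvs = NULL, cna_events = NULL) {
  stopifnot(site %in% colnames(tree$prevalence))
  if (is.null(cna_events))
    cna_events <- place_cna_events(tree, config, seed = config$seed)
  if (is.null(snvs))
    snvs <- place_snvs(tree, config, cna_events, seed = config$seed)
  if (any(cna_events$total_cn < 0))
    stop("negative copy number in event table", call. = FALSE)

  p <- config$purity[[site]]
  si <- match(site, colnames(tree$ccf))
  set.seed(config$seed + 7919L * si)

  ccf <- tree$ccf[snvs$owner, si]
  denom <- p * snvs$n_locus + 2 * (1 - p)
  vaf <- snvs$multiplicity * ccf * p / denom
  vaf <- pmin(1, pmax(0, vaf))
  err <- config$error_rate
  vaf_eff <- vaf * (1 - err) + (1 - vaf) * err

  total <- pmax(1L, stats::rpois(nrow(snvs), config$depth))
  alt <- stats::rbinom(nrow(snvs), total, vaf_eff)

  variants <- data.frame(
    chrom = snvs$chrom, pos = snvs$pos, ref = snvs$ref, alt = snvs$alt,
    alt_reads = alt, total_reads = total,
    true_ccf = ccf, true_multiplicity = snvs$multiplicity,
    n_locus = snvs$n_locus, owner = snvs$owner,
    event_id = snvs$event_id, stringsAsFactors = FALSE
  )

  seg_ccf <- ifelse(cna_events$owner == 1L, 1, tree$ccf[cna_events$owner, si])
  keep <- seg_ccf > 0
  segments <- data.frame(
    chrom = cna_events$chrom[keep], start = cna_events$start[keep],
    end = cna_events$end[keep], total_cn = cna_events$total_cn[keep],
    seg_ccf = seg_ccf[keep], event_id = cna_events$event_id[keep],
    stringsAsFactors = FALSE
  )
  list(variants = variants, segments = segments)
}
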