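#' Cancer clonal fraction from bulk allele counts
#'
#' Converts the variant allele frequency (VAF) of a somatic SNV into a cancer
#' clonal fraction (CCF) given tumor purity and the locus total copy number.
#' The mutation copy number is
#' \deqn{n_{mut} = f_s \frac{1}{p}\left[p\, n_{locus} + 2(1 - p)\right]}
#' where \eqn{f_s} is the VAF, \eqn{p} the tumor purity and \eqn{n_{locus}}
#' the tumor total copy number at the locus. The multiplicity \eqn{n_{chr}}
#' (number of chromosome copies carrying the mutation) is chosen by maximum
#' likelihood: for each candidate \eqn{C \in \{1, \ldots, n_{locus}\}} the
#' expected VAF \eqn{C p / (p\,n_{locus} + 2(1-p))} (capped at 1) is scored
#' under a binomial model of the observed read counts, and the best-scoring
#' \eqn{C} is kept (ties resolved toward the smaller multiplicity). The CCF is
#' \eqn{n_{mut}/n_{chr}}.
#'
#' The 95% confidence interval on the CCF is a Wilson score interval on
#' \eqn{f_s} propagated through the (monotone) mutation-copy-number map with
#' \eqn{n_{chr}} held fixed.
#'
#' @param alt variant-supporting read count (may be non-integral when an
#'   exact expected VAF is scored analytically).
#' @param total total read depth at the position; must be positive.
#' @param purity tumor purity \eqn{p} in (0, 1].
#' @param n_locus tumor total copy number at the locus (integer >= 0).
#' @param detection_floor CCF below which a variant is considered
#'   undetectable in this sample (default 0.05).
#' @param conf confidence level for the interval (default 0.95).
#'
#' @return A one-row data.frame of class `ccf_estimate` with columns
#'   `alt`, `total`, `f_s`, `purity`, `n_locus`, `n_mut`, `n_chr`, `ccf`,
#'   `ci_low`, `ci_high`, `detected`, and `cn_conflict` (TRUE when variant
#'   reads are observed on a homozygously deleted locus).
#' @export
#' @examples
#' estimate_ccf(alt = 25, total = 100, purity = 0.5, n_locus = 2)
estimate_ccf <- function(alt, total, purity, n_locus,
                         detection_floor = 0.05, conf = 0.95) {
  stopifnot(length(alt) == 1L, length(total) == 1L)
  if (!is.finite(total) || total <= 0)
    stop("'total' read depth must be positive", call. = FALSE)
  if (!is.finite(purity) || purity <= 0 || purity > 1)
    stop("'purity' must be in (0, 1]", call. = FALSE)
  if (!is.finite(n_locus) || n_locus < 0)
    stop("'n_locus' must be a non-negative integer", call. = FALSE)
  if (alt < 0 || alt > total)
    stop("'alt' must satisfy 0 <= alt <= total", call. = FALSE)

  f_s <- alt / total
  denom <- purity * n_locus + 2 * (1 - purity)
  n_mut <- f_s * denom / purity

  cn_conflict <- n_locus == 0 && alt > 0
  if (cn_conflict)
    warning("variant reads observed on a locus with total copy number 0",
            call. = FALSE)

  cands <- seq_len(max(1L, as.integer(n_locus)))
  exp_vaf <- pmin(1, cands * purity / denom)
  ll <- vapply(exp_vaf, binom_loglik, numeric(1), x = alt, n = total)
  n_chr <- cands[which.max(ll)]

  ccf <- n_mut / n_chr

  wi <- wilson_interval(alt, total, conf = conf)
  ci <- wi * denom / purity / n_chr

  out <- data.frame(
    alt = alt, total = total, f_s = f_s, purity = purity,
    n_locus = n_locus, n_mut = n_mut, n_chr = n_chr, ccf = ccf,
    ci_low = ci[[1L]], ci_high = ci[[2L]],
    detected = ccf > detection_floor, cn_conflict = cn_conflict
  )
  class(out) <- c("ccf_estimate", class(out))
  out
}

# Binomial log-likelihood up to the (multiplicity-independent) binomial
# coefficient; tolerates non-integral x so analytically exact VAFs can be
# scored.  Log-safe at q in {0, 1}.
binom_loglik <- function(q, x, n) {
  if (q <= 0) return(if (x == 0) 0 else -Inf)
  if (q >= 1) return(if (x == n) 0 else -Inf)
  x * log(q) + (n - x) * log1p(-q)
}

#' Wilson score interval for a binomial proportion
#'
#' @param x successes; @param n trials; @param conf confidence level.
#' @return numeric(2): lower and upper bound.
#' @keywords internal
wilson_interval <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  phat <- x / n
  z2 <- z^2
  centre <- (phat + z2 / (2 * n)) / (1 + z2 / n)
  half <- z * sqrt(phat * (1 - phat) / n + z2 / (4 * n^2)) / (1 + z2 / n)
  c(max(0, centre - half), min(1, centre + half))
}

#' Estimate CCFs for a variant table in one sample
#'
#' Vectorised wrapper around [estimate_ccf()]. Each variant's locus copy
#' number is looked up from the copy-number segments; positions not covered
#' by any segment are treated as diploid (`n_locus = 2`).
#'
#' @param variants data.frame with columns `chrom`, `pos` (1-based), `alt_reads`,
#'   `total_reads`.
#' @param segments data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `total_cn`; may be NULL for a fully diploid genome.
#' @param purity tumor purity of the sample.
#' @param ... passed to [estimate_ccf()].
#' @return `variants` with the `ccf_estimate` columns appended.
#' @export
estimate_ccf_table <- function(variants, segments = NULL, purity, ...) {
  stopifnot(all(c("chrom", "pos", "alt_reads", "total_reads") %in%
                  names(variants)))
  n_locus <- rep(2L, nrow(variants))
  if (!is.null(segments) && nrow(segments)) {
    vr <- GenomicRanges::GRanges(variants$chrom,
                                 IRanges::IRanges(variants$pos, width = 1L))
    sr <- GenomicRanges::GRanges(segments$chrom,
                                 IRanges::IRanges(segments$start + 1L,
                                                  segments$end))
    hit <- suppressWarnings(
      GenomicRanges::findOverlaps(vr, sr, select = "first"))
    n_locus[!is.na(hit)] <- as.integer(segments$total_cn[hit[!is.na(hit)]])
  }
  est <- lapply(seq_len(nrow(variants)), function(i) {
    estimate_ccf(variants$alt_reads[i], variants$total_reads[i],
                 purity = purity, n_locus = n_locus[i], ...)
  })
  est <- do.call(rbind, est)
  cbind(variants[setdiff(names(variants), names(est))], est)
}
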