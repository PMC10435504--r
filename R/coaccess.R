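#' Peak-peak co-accessibility at single-cell resolution
#'
#' For every peak pair whose centers lie within `window` bp, computes the
#' Pearson correlation of accessibility across single cells, without any
#' aggregation of cells. Accessibility is binarized (count > 0) by default;
#' raw counts may be correlated instead. Pairs involving a zero-variance
#' vector are excluded.
#'
#' @param mat a `peak_matrix` (see [simulate_peak_matrix()]), or any list
#'   with `counts` (peaks x cells) and `peaks` (chrom/start/end).
#' @param window maximum center-to-center distance in bp (default 250 kb).
#' @param binarize correlate binarized accessibility (default TRUE).
#' @param cells optional logical/index subset of cells (e.g. one group).
#' @return data.frame of links: `peak_i`, `peak_j` (i < j), `distance`,
#'   `correlation`, `pct_i`, `pct_j` (percent of cells accessible).
#' @export
compute_links <- function(mat, window = 2.5e5, binarize = TRUE, cells = NULL) {
  if (window <= 0) stop("window must be positive", call. = FALSE)
  counts <- mat$counts
  if (!is.null(cells)) counts <- counts[, cells, drop = FALSE]
  if (nrow(counts) < 2) stop("need at least two peaks", call. = FALSE)
  if (ncol(counts) < 20)
    stop("need at least 20 cells in the group", call. = FALSE)
  x <- as.matrix(counts)
  if (binarize) x <- (x > 0) * 1
  centers <- (mat$peaks$start + mat$peaks$end) / 2
  chrom <- mat$peaks$chrom

  pct <- 100 * colMeans(t(x) > 0)
  v <- apply(x, 1, stats::var)

  pairs <- which(outer(chrom, chrom, "==") &
                   abs(outer(centers, centers, "-")) <= window &
                   upper.tri(matrix(0, nrow(x), nrow(x))), arr.ind = TRUE)
  if (!nrow(pairs))
    return(data.frame(peak_i = integer(0), peak_j = integer(0),
                      distance = numeric(0), correlation = numeric(0),
                      pct_i = numeric(0), pct_j = numeric(0)))
  i <- pairs[, 1L]; j <- pairs[, 2L]
  ok <- v[i] > 0 & v[j] > 0
  i <- i[ok]; j <- j[ok]
  cor_ij <- vapply(seq_along(i), function(k)
    stats::cor(x[i[k], ], x[j[k], ]), numeric(1))
  out <- data.frame(peak_i = i, peak_j = j,
                    distance = abs(centers[j] - centers[i]),
                    correlation = cor_ij, pct_i = pct[i], pct_j = pct[j])
  rownames(out) <- NULL
  out
}

#' Shuffled-background co-accessibility threshold
#'
#' Estimates the null distribution of co-accessibility by randomly shuffling
#' the accessibility values jointly over the cells-by-peaks matrix. By
#' default the threshold is the 99th percentile of the per-shuffle maximum
#' within-window correlation; `mode = "pooled"` instead takes the 99th
#' percentile of all shuffled correlations pooled.
#'
#' @inheritParams compute_links
#' @param n_shuffles number of shuffles (>= 10; default 100).
#' @param seed integer seed.
#' @param probs percentile of the background (default 0.99).
#' @param mode `"max"` (per-shuffle maxima) or `"pooled"`.
#' @return numeric threshold; attribute `background` carries the per-shuffle
#'   maxima (or pooled correlations).
#' @export
shuffled_threshold <- function(mat, window = 2.5e5, n_shuffles = 100,
                               seed = 1L, binarize = TRUE, cells = NULL,
                               probs = 0.99, mode = c("max", "pooled")) {
  mode <- match.arg(mode)
  if (n_shuffles < 10) stop("n_shuffles must be >= 10", call. = FALSE)
  counts <- mat$counts
  if (!is.null(cells)) counts <- counts[, cells, drop = FALSE]
  x <- as.matrix(counts)
  if (binarize) x <- (x > 0) * 1
  if (stats::var(as.vector(x)) == 0)
    stop("degenerate matrix: all accessibility values identical",
         call. = FALSE)
  set.seed(seed)
  shuffled_mat <- mat
  bg <- c()
  maxima <- numeric(n_shuffles)
  for (b in seq_len(n_shuffles)) {
    xs <- matrix(sample(x), nrow(x), ncol(x))
    shuffled_mat$counts <- xs
    links <- compute_links(shuffled_mat, window = window, binarize = FALSE,
                           cells = NULL)
    if (!nrow(links)) { maxima[b] <- -Inf; next }
    maxima[b] <- max(links$correlation)
    if (mode == "pooled") bg <- c(bg, links$correlation)
  }
  if (mode == "max") {
    thr <- stats::quantile(maxima, probs, names = FALSE)
    attr(thr, "background") <- maxima
  } else {
    thr <- stats::quantile(bg, probs, names = FALSE)
    attr(thr, "background") <- bg
  }
  thr
}

#' Filter co-accessibility links against a background threshold
#'
#' @param links data.frame from [compute_links()].
#' @param threshold correlation threshold from [shuffled_threshold()].
#' @param min_pct minimum percent of cells accessible in both peaks
#'   (default 5).
#' @return `links` with a `significant` logical column.
#' @export
filter_links <- function(links, threshold, min_pct = 5) {
  if (!is.finite(threshold)) stop("threshold must be finite", call. = FALSE)
  links$significant <- links$correlation >= threshold &
    links$pct_i >= min_pct & links$pct_j >= min_pct
  links
}
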