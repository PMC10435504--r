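#' Exact two-sided Wilcoxon signed-rank test for paired samples
#'
#' Computes the exact null distribution of the positive-rank sum by
#' enumerating all 2^n sign assignments (via generating-function
#' convolution, equivalent to full enumeration; midranks handle ties).
#' Zero differences are dropped. The two-sided p-value is
#' `min(1, 2 * min(P(W <= w), P(W >= w)))`.
#'
#' @param x,y paired numeric vectors.
#' @param max_exact_n largest number of non-zero pairs for which the exact
#'   null is used (default 25); beyond it the normal approximation applies.
#' @return list: `statistic` (positive-rank sum), `p_value`, `n` (non-zero
#'   pairs), `exact`.
#' @export
exact_signed_rank_test <- function(x, y, max_exact_n = 25) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(statistic = 0, p_value = 1, n = 0L, exact = TRUE))
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= max_exact_n) {
    # integer support on doubled midranks
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    dist <- rep(0, total + 1L)   # counts over W2 = 0..total
    dist[1L] <- 1
    for (rk in r2) {
      shifted <- c(rep(0, rk), dist[seq_len(total + 1L - rk)])
      dist <- dist + shifted
    }
    dist <- dist / 2^n
    w2 <- as.integer(round(2 * w))
    p_le <- sum(dist[seq_len(w2 + 1L)])
    p_ge <- sum(dist[seq(w2 + 1L, total + 1L)])
    p <- min(1, 2 * min(p_le, p_ge))
    list(statistic = w, p_value = p, n = n, exact = TRUE)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (w - mu) / sqrt(sig2)
    list(statistic = w, p_value = 2 * stats::pnorm(-abs(z)), n = n,
         exact = FALSE)
  }
}

#' Compare paired-site microenvironment composition
#'
#' Per patient and site, cell-type proportions are computed from the
#' annotation table; patients missing one site are excluded with a warning.
#' For each cell type, an exact two-sided Wilcoxon signed-rank test is run
#' on the paired per-patient proportions, the fold change of mean
#' proportions (first site over second) is computed, and cell types with a
#' fold change of at least `fold` (default 2.5, in either direction) and
#' raw p < `alpha` are flagged depleted (or enriched) at the lower site.
#' Benjamini-Hochberg adjusted p-values over the tested cell types are
#' reported alongside the raw ones.
#'
#' @param annotations data.frame: `patient`, `site`, `cell`, `cell_type`.
#' @param sites character(2) ordered site labels (default the two present).
#' @param fold,alpha flag thresholds.
#' @return data.frame per cell type: `mean_<site>` columns, `fold_change`
#'   (ratio of means, larger over smaller), `direction` (site with the
#'   lower mean), `p`, `p_adj`, `flagged`.
#' @export
compare_tme_composition <- function(annotations, sites = NULL, fold = 2.5,
                                    alpha = 0.05) {
  if (is.null(sites)) sites <- unique(annotations$site)
  stopifnot(length(sites) == 2)
  pats <- unique(annotations$patient)
  have_both <- vapply(pats, function(p) {
    all(sites %in% annotations$site[annotations$patient == p])
  }, logical(1))
  if (any(!have_both)) {
    warning("excluding patient(s) missing one site: ",
            paste(pats[!have_both], collapse = ", "), call. = FALSE)
    pats <- pats[have_both]
  }
  if (length(pats) < 2)
    stop("need at least 2 patients with both sites", call. = FALSE)
  ann <- annotations[annotations$patient %in% pats, , drop = FALSE]
  types <- sort(unique(ann$cell_type))

  # patient x type proportion matrices per site
  prop <- lapply(sites, function(s) {
    t(vapply(pats, function(p) {
      lab <- ann$cell_type[ann$patient == p & ann$site == s]
      as.numeric(table(factor(lab, levels = types)) / length(lab))
    }, numeric(length(types))))
  })
  names(prop) <- sites

  rows <- lapply(seq_along(types), function(k) {
    a <- prop[[1L]][, k]; b <- prop[[2L]][, k]
    tst <- exact_signed_rank_test(a, b)
    m <- c(mean(a), mean(b))
    fc <- if (min(m) > 0) max(m) / min(m) else Inf
    data.frame(cell_type = types[k],
               mean_a = m[1L], mean_b = m[2L],
               fold_change = fc,
               direction = sites[which.min(m)],
               p = tst$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "mean_a"] <- paste0("mean_", sites[1L])
  names(out)[names(out) == "mean_b"] <- paste0("mean_", sites[2L])
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$flagged <- out$fold_change >= fold & out$p < alpha
  out
}

#' Assemble a per-patient summary report
#'
#' @param patient patient id.
#' @param ccf_summary output of [summarize_heterogeneity()] for SNVs.
#' @param cna_summary optional CNA class summary (same shape).
#' @param subclone_composition optional [site_composition()] table of
#'   confirmed subclones.
#' @param links optional significant-link counts per group (named vector).
#' @param clonotypes optional classified clonotype table.
#' @param composition optional [compare_tme_composition()] table.
#' @return list of class `patient_report`; serialise with
#'   [write_patient_report()].
#' @export
build_patient_report <- function(patient, ccf_summary, cna_summary = NULL,
                                 subclone_composition = NULL, links = NULL,
                                 clonotypes = NULL, composition = NULL) {
  rep <- list(
    patient = patient,
    snv_class_counts = as.list(ccf_summary$counts),
    snv_retained = unname(ccf_summary$retained),
    heterogeneous_snv_fraction = unname(ccf_summary$heterogeneous_fraction)
  )
  if (!is.null(cna_summary))
    rep$cna_class_counts <- as.list(cna_summary$counts)
  if (!is.null(subclone_composition)) {
    rep$confirmed_subclones <- nrow(subclone_composition)
    uniq <- subclone_composition$unique_to
    rep$site_unique_subclones <- as.list(stats::setNames(
      uniq[!is.na(uniq)], subclone_composition$subclone[!is.na(uniq)]))
  }
  if (!is.null(links)) rep$significant_links <- as.list(links)
  if (!is.null(clonotypes)) {
    rep$expanded_clonotypes <- sum(clonotypes$expansion == "expanded")
    rep$hyperexpanded_clonotypes <-
      sum(clonotypes$expansion == "hyperexpanded")
  }
  if (!is.null(composition))
    rep$tme_flagged_types <- composition$cell_type[composition$flagged]
  class(rep) <- "patient_report"
  rep
}

#' @rdname build_patient_report
#' @param report a `patient_report`; @param path output JSON path.
#' @export
write_patient_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname build_patient_report
#' @export
read_patient_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(rep) <- "patient_report"
  rep
}

#' Run the full paired-site pipeline on a synthetic cohort
#'
#' Simulates a cohort, runs CCF estimation and paired classification per
#' patient, compares microenvironment composition across the cohort and
#' writes per-patient report JSONs plus cohort-level tables. Deterministic
#' given the seed.
#'
#' @param out_dir output directory (created if needed).
#' @param seed master seed.
#' @param n_patients cohort size.
#' @param cohort optionally a pre-simulated cohort from [simulate_cohort()].
#' @return invisibly, a list with the cohort-level summary tables and
#'   report paths.
#' @export
run_pipeline <- function(out_dir, seed = 7L, n_patients = 8, cohort = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(cohort)) cohort <- simulate_cohort(n_patients, seed = seed)

  reports <- character(0)
  het <- numeric(0)
  for (pt in cohort) {
    sites <- pt$config$sites
    est <- lapply(sites, function(s)
      estimate_ccf_table(pt$bulk[[s]]$variants, pt$bulk[[s]]$segments,
                         purity = pt$config$purity[[s]]))
    classes <- classify_snv_table(est[[1L]], est[[2L]],
                                  sites = sites,
                                  err_rate = pt$config$error_rate)
    cna_classes <- classify_cna_table(pt$bulk[[sites[1L]]]$segments,
                                      pt$bulk[[sites[2L]]]$segments,
                                      sites = sites)
    summ <- summarize_heterogeneity(classes)
    cna_summ <- summarize_heterogeneity(cna_classes)
    het <- c(het, summ$heterogeneous_fraction)
    rep <- build_patient_report(pt$patient, summ, cna_summary = cna_summ)
    path <- file.path(out_dir, paste0(pt$patient, "_report.json"))
    write_patient_report(rep, path)
    reports <- c(reports, path)
    utils::write.table(
      classes, file.path(out_dir, paste0(pt$patient, "_snv_classes.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  cfg <- cohort[[1L]]$config
  ann <- simulate_tme_annotations(cfg, vapply(cohort, `[[`, "",
                                              "patient"),
                                  seed = seed + 17L)
  tme <- compare_tme_composition(ann, sites = cfg$sites)
  utils::write.table(tme, file.path(out_dir, "tme_composition.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  summary <- list(
    n_patients = length(cohort),
    mean_heterogeneous_fraction = mean(het),
    reports = basename(reports)
  )
  jsonlite::write_json(summary, file.path(out_dir, "cohort_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(heterogeneous_fractions = het, tme = tme,
                 reports = reports, cohort = cohort))
}
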