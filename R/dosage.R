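# Dosage-compensation statistics: X-vs-autosome and female-vs-male
# comparisons per tissue, X:A and F:M ratio summaries, and a qualitative
# compensation-status call.

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration is used when the smaller group has at most 8
#' observations and the pooled data are tie-free (mode `"auto"`); otherwise
#' the normal approximation with tie-corrected variance and continuity
#' correction.  Symmetric in a group swap.
#'
#' @param x,y Non-empty numeric vectors.
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return List with `statistic` (Mann-Whitney U for `x`), `p.value`, and
#'   the `method` used.
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (length(x) == 0 || length(y) == 0)
    stop("both groups must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- switch(mode,
                  auto = min(length(x), length(y)) <= 8 && !ties,
                  exact = TRUE,
                  normal = FALSE)
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       method = if (exact && !ties) "exact" else "normal")
}

#' @noRd
split_by_class <- function(te, classification) {
  lab <- stats::setNames(classification$label, classification$chrom)
  cls <- lab[te$chrom]
  keep <- te$retained & !is.na(cls) & cls %in% c("X", "autosome")
  list(x = te[keep & cls == "X", , drop = FALSE],
       auto = te[keep & cls == "autosome", , drop = FALSE])
}

#' X:A median expression ratio in one sex
#'
#' Median FPKM of retained X-linked genes divided by the median over
#' retained autosomal genes, within the given sex.
#'
#' @param te A filtered `tissue_expression` data frame with `chrom`.
#' @param classification A `chrom_classification`.
#' @param sex `"F"` or `"M"`.
#' @return The ratio (NA with a warning when a class is empty).
#' @export
xa_ratio <- function(te, classification, sex = c("F", "M")) {
  sex <- match.arg(sex)
  col <- if (sex == "F") "mean_F" else "mean_M"
  parts <- split_by_class(te, classification)
  if (nrow(parts$x) == 0 || nrow(parts$auto) == 0) {
    warning("no retained ", if (nrow(parts$x) == 0) "X-linked" else "autosomal",
            " genes; X:A ratio undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::median(parts$x[[col]]) / stats::median(parts$auto[[col]])
}

#' Per-gene female:male expression ratios by chromosome class
#'
#' For every retained gene, `ratio = mean_F / mean_M` after flooring both
#' sides at `floor` (pseudo-FPKM guard against division by zero); reports
#' the per-class medians and a Wilcoxon rank-sum comparison of the X and
#' autosomal ratio distributions.
#'
#' @param te A filtered `tissue_expression` data frame.
#' @param classification A `chrom_classification`.
#' @param floor Pseudo-FPKM floor (default 0.01).
#' @return List: `ratios` (gene_id, chrom, class, ratio), `median_x`,
#'   `median_auto`, `p_x_vs_auto`, and `n_floored` (genes touched by the
#'   floor).
#' @export
fm_ratio_distribution <- function(te, classification, floor = 0.01) {
  parts <- split_by_class(te, classification)
  both <- rbind(cbind(parts$x, class = if (nrow(parts$x)) "X" else character(0)),
                cbind(parts$auto, class = if (nrow(parts$auto)) "autosome" else character(0)))
  if (nrow(parts$x) == 0 || nrow(parts$auto) == 0)
    warning("empty chromosome class in F:M ratio computation", call. = FALSE)
  n_floored <- sum(both$mean_F < floor | both$mean_M < floor)
  ratio <- pmax(both$mean_F, floor) / pmax(both$mean_M, floor)
  ratios <- data.frame(gene_id = both$gene_id, chrom = both$chrom,
                       class = both$class, ratio = ratio,
                       stringsAsFactors = FALSE)
  med_x <- safe_median(ratio[both$class == "X"])
  med_a <- safe_median(ratio[both$class == "autosome"])
  p <- if (nrow(parts$x) > 0 && nrow(parts$auto) > 0) {
    wilcoxon_rank_sum(ratio[both$class == "X"],
                      ratio[both$class == "autosome"])$p.value
  } else NA_real_
  list(ratios = ratios, median_x = med_x, median_auto = med_a,
       p_x_vs_auto = p, n_floored = n_floored)
}

#' @noRd
status_call <- function(fm_x, xa_m, delta, epsilon) {
  if (is.na(fm_x) || is.na(xa_m)) return(NA_character_)
  balanced <- fm_x >= 1 - delta && fm_x <= 1 + delta
  xa_ok <- xa_m >= 1 - epsilon && xa_m <= 1 + epsilon
  if (balanced && xa_ok) return("complete_with_balance")
  if (balanced) return("complete_unbalanced")
  if (fm_x >= 2 - delta) return("absent")
  "partial"
}

#' Per-tissue dosage-compensation report
#'
#' Assembles, for every tissue with both sexes: retained gene counts per
#' chromosome class; Wilcoxon p-values for X-vs-autosome expression within
#' each sex and for female-vs-male expression within each class; X:A
#' ratios per sex; medians of the per-gene F:M ratio per class with the
#' X-vs-autosome Wilcoxon comparison; and a compensation-status label.
#'
#' The status rule: `complete_with_balance` when the X-linked F:M median
#' lies in `[1 - delta, 1 + delta]` and the male X:A ratio in
#' `[1 - epsilon, 1 + epsilon]`; `complete_unbalanced` when only the F:M
#' condition holds; `absent` when the X-linked F:M median is at least
#' `2 - delta` (the two-fold signature of an uncompensated single-copy X);
#' `partial` otherwise.  The "median F:M ratio" is the median of per-gene
#' ratios, matching a ratio *distribution*; the ratio of the two class
#' medians is also reported (`fm_x_ratio_of_medians`) for transparency.
#'
#' @param tissue_exprs A list of filtered `tissue_expression` data frames
#'   (as from [average_replicates()] + [filter_expressed()]).
#' @param classification A `chrom_classification`.
#' @param delta Half-width of the balance band on the F:M median (default 0.15).
#' @param epsilon Half-width of the band on the male X:A ratio (default 0.15).
#' @param floor Pseudo-FPKM floor passed to [fm_ratio_distribution()].
#' @return A `dosage_report` data frame, one row per tissue.
#' @export
dosage_report <- function(tissue_exprs, classification, delta = 0.15,
                          epsilon = 0.15, floor = 0.01) {
  stopifnot(length(tissue_exprs) >= 1)
  rows <- list()
  for (tis in names(tissue_exprs)) {
    te <- tissue_exprs[[tis]]
    if (!all(c("mean_F", "mean_M") %in% names(te)) ||
        all(is.na(te$mean_F)) || all(is.na(te$mean_M))) {
      warning("tissue ", tis, " lacks one sex; skipped", call. = FALSE)
      next
    }
    parts <- split_by_class(te, classification)
    nx <- nrow(parts$x); na_ <- nrow(parts$auto)
    p_xa_f <- if (nx > 0 && na_ > 0)
      wilcoxon_rank_sum(parts$x$mean_F, parts$auto$mean_F)$p.value else NA_real_
    p_xa_m <- if (nx > 0 && na_ > 0)
      wilcoxon_rank_sum(parts$x$mean_M, parts$auto$mean_M)$p.value else NA_real_
    p_fm_x <- if (nx > 0)
      wilcoxon_rank_sum(parts$x$mean_F, parts$x$mean_M)$p.value else NA_real_
    p_fm_a <- if (na_ > 0)
      wilcoxon_rank_sum(parts$auto$mean_F, parts$auto$mean_M)$p.value else NA_real_
    xa_f <- suppressWarnings(xa_ratio(te, classification, "F"))
    xa_m <- suppressWarnings(xa_ratio(te, classification, "M"))
    fm <- suppressWarnings(fm_ratio_distribution(te, classification, floor))
    fm_x_rom <- if (nx > 0)
      stats::median(pmax(parts$x$mean_F, floor)) /
        stats::median(pmax(parts$x$mean_M, floor)) else NA_real_
    rows[[tis]] <- data.frame(
      tissue = tis, n_genes_x = nx, n_genes_auto = na_,
      xa_ratio_f = xa_f, xa_ratio_m = xa_m,
      fm_median_x = fm$median_x, fm_median_auto = fm$median_auto,
      fm_x_ratio_of_medians = fm_x_rom,
      p_x_vs_auto_f = p_xa_f, p_x_vs_auto_m = p_xa_m,
      p_f_vs_m_x = p_fm_x, p_f_vs_m_auto = p_fm_a,
      p_fm_x_vs_auto = fm$p_x_vs_auto,
      status = status_call(fm$median_x, xa_m, delta, epsilon),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) stop("no tissue with both sexes", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("dosage_report", "data.frame")
  out
}
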