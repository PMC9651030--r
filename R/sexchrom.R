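# X-chromosome identification from male:female windowed coverage ratios.
# In an XX/XO system the male X carries one copy against two in females, so
# its M:F depth ratio sits near 0.5 while autosomes fluctuate around 1.

#' Per-window male:female coverage ratios
#'
#' Windows with female depth below `min_depth` or zero male depth are
#' dropped (and counted in the `n_dropped` attribute).  With
#' `normalize_libsize`, provisional ratios are divided by their genome-wide
#' median, a two-pass scaling that centres the autosomal ratio at 1 when
#' the two sexes were sequenced to different total depths.  Ratios are kept
#' on the natural scale for classification; log2 is carried for plotting
#' and smoothing.
#'
#' @param cov A `coverage_windows` data frame (see [read_coverage()]).
#' @param min_depth Minimum female window depth retained (default 5).
#' @param normalize_libsize Apply the median-centring scaling (default TRUE).
#' @return A `ratio_track` data frame: chrom, midpoint, ratio, log2_ratio;
#'   attributes `n_dropped` and `scale_factor`.
#' @export
compute_window_ratios <- function(cov, min_depth = 5, normalize_libsize = TRUE) {
  cov <- validate_coverage(cov)
  keep <- cov$depth_female >= max(min_depth, .Machine$double.eps) &
    cov$depth_male > 0
  n_dropped <- sum(!keep)
  cov <- cov[keep, , drop = FALSE]
  if (nrow(cov) == 0) stop("no informative windows", call. = FALSE)
  ratio <- cov$depth_male / cov$depth_female
  scale_factor <- 1
  if (normalize_libsize) {
    scale_factor <- stats::median(ratio)
    ratio <- ratio / scale_factor
  }
  track <- data.frame(chrom = cov$chrom,
                      midpoint = (cov$start + cov$end) / 2,
                      ratio = ratio, log2_ratio = log2(ratio),
                      stringsAsFactors = FALSE)
  attr(track, "n_dropped") <- n_dropped
  attr(track, "scale_factor") <- scale_factor
  class(track) <- c("ratio_track", "data.frame")
  track
}

# Local linear (degree-1) fit with tricube weights over the k nearest
# neighbours of each point, computed chromosome by chromosome so smoothing
# never crosses a chromosome boundary.
#' @noRd
loess_fit_one <- function(x, y, k) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    d <- abs(x - x[i])
    nb <- order(d)[seq_len(k)]
    dmax <- max(d[nb])
    w <- if (dmax == 0) rep(1, length(nb)) else (1 - pmin(d[nb] / dmax, 1)^3)^3
    pos <- w > 0
    xs <- x[nb][pos]; ys <- y[nb][pos]; ws <- w[pos]
    if (length(unique(xs)) < 2) return(sum(ws * ys) / sum(ws))
    xc <- xs - x[i]
    sw <- sum(ws); swx <- sum(ws * xc); swxx <- sum(ws * xc^2)
    swy <- sum(ws * ys); swxy <- sum(ws * xc * ys)
    det <- sw * swxx - swx^2
    if (det <= .Machine$double.eps * sw * swxx) return(swy / sw)
    # intercept at xc = 0 is the fitted value at x[i]
    (swxx * swy - swx * swxy) / det
  }, numeric(1))
}

#' LOESS-smooth a ratio track
#'
#' Adds a `smoothed_log2` column: per chromosome, a degree-1 local
#' regression of log2 ratio on window midpoint with tricube weights over
#' the `span` nearest fraction of windows.  Used for visualisation only;
#' classification works on raw per-window ratios.  Chromosomes with fewer
#' than 3 windows get their raw values copied, with a warning.
#'
#' @param track A `ratio_track`.
#' @param span Neighbourhood fraction in (0, 1] (default 0.3).
#' @return The track with `smoothed_log2` added.
#' @export
loess_smooth <- function(track, span = 0.3) {
  stopifnot(is.data.frame(track))
  if (!is.numeric(span) || span <= 0 || span > 1)
    abort_config("span", "must lie in (0, 1]")
  track$smoothed_log2 <- NA_real_
  few <- character(0)
  for (cn in unique(track$chrom)) {
    i <- which(track$chrom == cn)
    if (length(i) < 3) {
      track$smoothed_log2[i] <- track$log2_ratio[i]
      few <- c(few, cn)
      next
    }
    k <- max(3L, min(length(i), as.integer(ceiling(span * length(i)))))
    o <- i[order(track$midpoint[i])]
    track$smoothed_log2[o] <- loess_fit_one(track$midpoint[o],
                                            track$log2_ratio[o], k)
  }
  if (length(few) > 0)
    warning("chromosome(s) with < 3 windows, smoothed values copied from raw: ",
            paste(few, collapse = ", "), call. = FALSE)
  track
}

#' Classify chromosomes as X or autosome from median window ratios
#'
#' A chromosome is labelled `X` when its median M:F ratio falls in
#' `x_band` (default \[0.35, 0.65\], centred on the one-vs-two-copy
#' expectation of 0.5), `autosome` when in `auto_band` (default
#' \[0.8, 1.2\]), and `unassigned` otherwise or when fewer than
#' `min_windows` informative windows remain.
#'
#' @param track A `ratio_track` from [compute_window_ratios()].
#' @param x_band,auto_band Disjoint ratio intervals `c(lo, hi)`.
#' @param min_windows Minimum retained windows per chromosome (default 5).
#' @return A `chrom_classification` data frame: chrom, n_windows_used,
#'   median_ratio, label.
#' @export
classify_chromosomes <- function(track, x_band = c(0.35, 0.65),
                                 auto_band = c(0.8, 1.2), min_windows = 5L) {
  if (length(x_band) != 2 || length(auto_band) != 2 ||
      x_band[1] >= x_band[2] || auto_band[1] >= auto_band[2])
    abort_config("x_band/auto_band", "must each be an increasing interval c(lo, hi)")
  if (x_band[2] >= auto_band[1] && auto_band[2] >= x_band[1])
    abort_config("x_band/auto_band", "must be disjoint intervals")
  med <- tapply(track$ratio, track$chrom, stats::median)
  n <- tapply(track$ratio, track$chrom, length)
  chroms <- names(med)
  label <- vapply(chroms, function(cn) {
    if (n[[cn]] < min_windows) return("unassigned")
    m <- med[[cn]]
    if (m >= x_band[1] && m <= x_band[2]) return("X")
    if (m >= auto_band[1] && m <= auto_band[2]) return("autosome")
    "unassigned"
  }, character(1))
  out <- data.frame(chrom = chroms, n_windows_used = as.integer(n),
                    median_ratio = as.numeric(med), label = unname(label),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("chrom_classification", "data.frame")
  out
}
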