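# Expression normalisation: TMM scaling factors, FPKM, replicate averaging,
# the FPKM >= 1 expressed-gene filter, and replicate QC by Spearman
# correlation.

#' Trimmed-mean-of-M-values (TMM) scaling factors
#'
#' Between-sample scaling factors robust to composition bias.  The
#' reference is the sample whose upper-quartile count fraction is closest
#' to the mean; per sample, genes with a zero count in either member of the
#' pair are excluded, the log-ratio (M) and mean log-abundance (A) of count
#' fractions are doubly trimmed (default 30% on M, 5% on A), and the factor
#' is 2 to the precision-weighted mean of the retained M values.  Factors
#' are rescaled to multiply to 1.
#'
#' @param counts Numeric matrix, genes x samples (>= 2 columns).
#' @param trim_m,trim_a Two-sided trim fractions for M and A.
#' @return Named numeric vector of factors, one per sample.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("TMM requires at least 2 samples", call. = FALSE)
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("zero library size", call. = FALSE)
  f75 <- apply(counts, 2, function(y) stats::quantile(y, 0.75)) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  yr <- counts[, ref]; lr <- lib[ref]
  factors <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    yo <- counts[, j]; lo <- lib[j]
    keep <- yo > 0 & yr > 0
    if (!any(keep)) {
      warning("sample ", colnames(counts)[j] %||% j,
              " shares no expressed genes with the reference; factor set to 1",
              call. = FALSE)
      return(1)
    }
    po <- yo[keep] / lo; pr <- yr[keep] / lr
    M <- log2(po / pr)
    A <- (log2(po) + log2(pr)) / 2
    # delta-method variance of M from the two binomial count fractions
    v <- (lo - yo[keep]) / (lo * yo[keep]) + (lr - yr[keep]) / (lr * yr[keep])
    fin <- is.finite(M) & is.finite(A) & is.finite(v)
    M <- M[fin]; A <- A[fin]; v <- v[fin]
    n <- length(M)
    if (n == 0) return(1)
    if (max(abs(M)) < 1e-6) return(1)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    rM <- rank(M); rA <- rank(A)
    keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(keep2)) return(1)
    2^(sum(M[keep2] / v[keep2]) / sum(1 / v[keep2]))
  }, numeric(1))
  factors <- factors / exp(mean(log(factors)))
  stats::setNames(factors, colnames(counts))
}

#' FPKM matrix with optional TMM-effective library sizes
#'
#' `FPKM = count / (exonic_kb * effective_library/1e6)`, where the
#' effective library size is the column sum times the sample's TMM factor
#' (or the raw column sum when `tmm = FALSE`).
#'
#' @param counts A `count_matrix` (from [read_counts()] or
#'   [simulate_expression()] pieces) or a plain integer matrix.
#' @param gene_lengths Named vector of exonic lengths in bp covering every
#'   gene in the matrix.
#' @param samples Sample metadata (taken from `counts` when it is a
#'   `count_matrix`).
#' @param tmm Apply TMM scaling (default TRUE).
#' @return An `expression_matrix`: list with `fpkm`, `tmm_factors`,
#'   `eff_libsize`, `gene_lengths` and `samples`.
#' @export
compute_fpkm <- function(counts, gene_lengths, samples = NULL, tmm = TRUE) {
  if (inherits(counts, "count_matrix")) {
    samples <- samples %||% counts$samples
    counts <- counts$counts
  }
  counts <- as.matrix(counts)
  missing <- setdiff(rownames(counts), names(gene_lengths))
  if (length(missing) > 0)
    stop("gene length missing for: ", paste(utils::head(missing, 3), collapse = ", "),
         if (length(missing) > 3) ", ...", call. = FALSE)
  len_kb <- gene_lengths[rownames(counts)] / 1e3
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("zero library size", call. = FALSE)
  factors <- if (tmm && ncol(counts) >= 2) tmm_factors(counts)
             else stats::setNames(rep(1, ncol(counts)), colnames(counts))
  eff <- lib * factors
  fpkm <- sweep(counts / len_kb, 2, eff / 1e6, "/")
  structure(list(fpkm = fpkm, tmm_factors = factors, eff_libsize = eff,
                 gene_lengths = gene_lengths[rownames(counts)],
                 samples = samples),
            class = "expression_matrix")
}

#' Average replicate FPKM within tissue and sex
#'
#' @param expr An `expression_matrix`.
#' @param genes Optional gene table; when given, the chromosome of each
#'   gene is attached (needed by the dosage statistics).
#' @return A named list of `tissue_expression` data frames (gene_id,
#'   chrom, mean_F, mean_M, retained), one per tissue having both sexes.
#' @export
average_replicates <- function(expr, genes = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  meta <- expr$samples
  if (is.null(meta)) stop("expression matrix carries no sample metadata", call. = FALSE)
  chrom <- if (!is.null(genes)) {
    stats::setNames(genes$chrom, genes$gene_id)[rownames(expr$fpkm)]
  } else rep(NA_character_, nrow(expr$fpkm))
  out <- list()
  for (tis in unique(meta$tissue)) {
    sub <- meta[meta$tissue == tis, , drop = FALSE]
    if (!all(c("F", "M") %in% sub$sex)) next
    mean_sex <- function(sex) {
      cols <- sub$sample_id[sub$sex == sex]
      rowMeans(expr$fpkm[, cols, drop = FALSE])
    }
    te <- data.frame(gene_id = rownames(expr$fpkm), chrom = unname(chrom),
                     mean_F = mean_sex("F"), mean_M = mean_sex("M"),
                     retained = TRUE, stringsAsFactors = FALSE)
    rownames(te) <- NULL
    attr(te, "tissue") <- tis
    class(te) <- c("tissue_expression", "data.frame")
    out[[tis]] <- te
  }
  out
}

#' Filter lowly expressed genes per tissue
#'
#' Under the default `both_below` rule a gene is dropped only when its mean
#' FPKM is below the threshold in *both* sexes, so genes expressed in one
#' sex only (sex-limited genes) survive; `either_below` drops a gene when
#' either sex falls below the threshold.
#'
#' @param te A `tissue_expression` data frame.
#' @param threshold FPKM threshold (default 1).
#' @param rule `"both_below"` or `"either_below"`.
#' @return The input with its `retained` flag updated.
#' @export
filter_expressed <- function(te, threshold = 1,
                             rule = c("both_below", "either_below")) {
  rule <- match.arg(rule)
  if (!is.numeric(threshold) || threshold < 0)
    abort_config("threshold", "must be >= 0")
  drop <- if (rule == "both_below") {
    te$mean_F < threshold & te$mean_M < threshold
  } else {
    te$mean_F < threshold | te$mean_M < threshold
  }
  te$retained <- te$retained & !drop
  te
}

#' Replicate QC: Spearman rank correlation between replicate pairs
#'
#' Computed on raw counts (ranks are invariant to monotone transforms, so
#' no log is applied); ties take average ranks.  A constant column yields a
#' missing coefficient with a warning.
#'
#' @param counts A `count_matrix` or plain matrix.
#' @param samples Sample metadata when `counts` is a plain matrix.
#' @return Data frame: tissue, sex, sample_a, sample_b, rho.
#' @export
spearman_replicates <- function(counts, samples = NULL) {
  if (inherits(counts, "count_matrix")) {
    samples <- samples %||% counts$samples
    counts <- counts$counts
  }
  out <- list()
  for (key in unique(paste(samples$tissue, samples$sex, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    ids <- samples$sample_id[samples$tissue == parts[1] & samples$sex == parts[2]]
    if (length(ids) < 2) next
    pairs <- utils::combn(ids, 2)
    for (p in seq_len(ncol(pairs))) {
      a <- counts[, pairs[1, p]]; b <- counts[, pairs[2, p]]
      rho <- if (stats::sd(a) == 0 || stats::sd(b) == 0) {
        warning("constant counts in replicate pair ", pairs[1, p], "/",
                pairs[2, p], "; correlation undefined", call. = FALSE)
        NA_real_
      } else {
        stats::cor(a, b, method = "spearman")
      }
      out[[length(out) + 1L]] <- data.frame(
        tissue = parts[1], sex = parts[2],
        sample_a = pairs[1, p], sample_b = pairs[2, p], rho = rho,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(tissue = character(0), sex = character(0),
                      sample_a = character(0), sample_b = character(0),
                      rho = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
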