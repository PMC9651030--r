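# Sex-biased gene calling and chromosomal enrichment.  Counts are modelled
# as negative binomial; replicated designs use a two-group likelihood-ratio
# test at a moment-estimated, shrunken tagwise dispersion, unreplicated
# designs a conditional exact test at a fixed BCV (default 0.2, i.e.
# dispersion 0.04).  Enrichment of biased genes on the X uses Fisher's
# exact test on a 2x2 biased/unbiased x X/autosome table.

#' Counts per million
#'
#' `CPM = count * 1e6 / (library size * TMM factor)`.
#'
#' @param counts Numeric matrix, genes x samples.
#' @param tmm_factors Optional per-sample scaling factors (default 1).
#' @return CPM matrix of the same shape.
#' @export
cpm <- function(counts, tmm_factors = NULL) {
  counts <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("zero library size", call. = FALSE)
  f <- tmm_factors %||% rep(1, ncol(counts))
  sweep(counts, 2, lib * f / 1e6, "/")
}

#' Low-expression filter on CPM
#'
#' Replicated design: a gene is kept when its CPM exceeds the threshold in
#' every replicate of at least one sex.  Unreplicated design: kept when it
#' exceeds the threshold in at least one of the samples, so sex-limited
#' genes are not discarded.
#'
#' @param cpm_mat CPM matrix (from [cpm()]).
#' @param samples Sample metadata aligned to the columns.
#' @param threshold CPM threshold, strict inequality (default 1).
#' @param design `"replicated"` or `"unreplicated"`.
#' @return Named logical vector of retained genes.
#' @export
cpm_filter <- function(cpm_mat, samples, threshold = 1,
                       design = c("replicated", "unreplicated")) {
  design <- match.arg(design)
  if (!is.numeric(threshold) || threshold < 0)
    abort_config("threshold", "must be >= 0")
  if (design == "unreplicated") {
    keep <- apply(cpm_mat > threshold, 1, any)
  } else {
    pass_sex <- vapply(c("F", "M"), function(sex) {
      cols <- samples$sample_id[samples$sex == sex]
      if (length(cols) == 0) return(rep(FALSE, nrow(cpm_mat)))
      apply(cpm_mat[, cols, drop = FALSE] > threshold, 1, all)
    }, logical(nrow(cpm_mat)))
    keep <- apply(pass_sex, 1, any)
  }
  stats::setNames(keep, rownames(cpm_mat))
}

#' Per-gene negative-binomial dispersion
#'
#' Unreplicated designs get the fixed dispersion `bcv^2` everywhere
#' (default BCV 0.2).  Replicated designs use a method-of-moments estimate
#' on depth-scaled counts within each sex, pooled across sexes, then
#' shrunk toward the across-gene median with weight `n / (n + prior_n)`
#' (`n` = pooled residual degrees of freedom), and floored at 1e-4.
#'
#' @param counts Count matrix, genes x samples.
#' @param samples Sample metadata.
#' @param design `"replicated"` or `"unreplicated"`.
#' @param bcv Square-root dispersion for the fixed-dispersion path.
#' @param prior_n Prior degrees of freedom of the shrinkage (default 10).
#' @return Named numeric vector of dispersions.
#' @export
estimate_dispersion <- function(counts, samples,
                                design = c("replicated", "unreplicated"),
                                bcv = 0.2, prior_n = 10) {
  design <- match.arg(design)
  counts <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  g <- nrow(counts)
  fixed <- stats::setNames(rep(bcv^2, g), rownames(counts))
  if (design == "unreplicated") return(fixed)
  groups <- lapply(c("F", "M"), function(sex)
    samples$sample_id[samples$sex == sex])
  groups <- groups[vapply(groups, length, 1L) >= 2]
  if (length(groups) == 0) {
    warning("no sex with >= 2 replicates; falling back to fixed BCV ", bcv,
            call. = FALSE)
    return(fixed)
  }
  lib <- colSums(counts)
  z <- sweep(counts, 2, mean(lib) / lib, "*")
  num <- rep(0, g); den <- rep(0, g); df <- 0
  for (cols in groups) {
    zz <- z[, cols, drop = FALSE]
    m <- rowMeans(zz)
    v <- apply(zz, 1, stats::var)
    ok <- m > 0
    raw <- rep(NA_real_, g)
    raw[ok] <- (v[ok] - m[ok]) / m[ok]^2
    w <- length(cols) - 1
    num <- num + ifelse(is.na(raw), 0, raw) * w
    den <- den + ifelse(is.na(raw), 0, w)
    df <- df + w
  }
  raw_phi <- ifelse(den > 0, num / den, NA_real_)
  common <- stats::median(raw_phi, na.rm = TRUE)
  common <- max(common, 0)
  tagwise <- pmax(raw_phi, 0)
  tagwise[is.na(tagwise)] <- common
  shrunk <- (df * tagwise + prior_n * common) / (df + prior_n)
  stats::setNames(pmax(shrunk, 1e-4), rownames(counts))
}

# Vectorised Newton solve of the NB group mean m per gene with sample
# offsets: sum_s (y_gs - m L_s) / (1 + phi_g m L_s) = 0 on beta = log m.
#' @noRd
fit_nb_mean <- function(Y, L, phi) {
  g <- nrow(Y)
  rs <- rowSums(Y)
  m <- rep(0, g)
  pos <- rs > 0
  if (!any(pos)) return(m)
  if (all(phi[pos] == 0)) {
    m[pos] <- rs[pos] / sum(L)
    return(m)
  }
  beta <- log(rs[pos] / sum(L))
  Yp <- Y[pos, , drop = FALSE]
  php <- phi[pos]
  for (it in 1:50) {
    mu <- exp(beta) %o% L
    den <- 1 + php * mu
    f <- rowSums((Yp - mu) / den)
    fp <- -rowSums(mu * (1 + php * Yp) / den^2)
    step <- f / fp
    step[!is.finite(step)] <- 0
    step <- pmin(pmax(step, -5), 5)
    beta <- beta - step
    if (max(abs(f) / (1 + rowSums(Yp))) < 1e-12) break
  }
  m[pos] <- exp(beta)
  m
}

#' @noRd
nb_loglik <- function(Y, L, m, phi) {
  mu <- pmax(m %o% L, 1e-300)
  ll <- matrix(0, nrow(Y), ncol(Y))
  nbrows <- phi > 0
  if (any(nbrows)) {
    ll[nbrows, ] <- stats::dnbinom(Y[nbrows, , drop = FALSE],
                                   size = 1 / phi[nbrows],
                                   mu = mu[nbrows, , drop = FALSE], log = TRUE)
  }
  if (any(!nbrows)) {
    ll[!nbrows, ] <- stats::dpois(Y[!nbrows, , drop = FALSE],
                                  mu[!nbrows, , drop = FALSE], log = TRUE)
  }
  rowSums(ll)
}

# Quantile-map counts from their own library size onto the common one,
# preserving the mid-P quantile under the fitted null NB; identity when all
# library sizes already agree.
#' @noRd
pseudo_counts <- function(Y, L, Lstar, m, phi) {
  if (all(abs(L - Lstar) < 1e-9 * Lstar)) return(Y)
  out <- Y
  for (s in seq_along(L)) {
    mu_s <- m * L[s]; mu_t <- m * Lstar
    y <- Y[, s]
    for (i in seq_len(nrow(Y))) {
      if (mu_s[i] <= 0) next
      if (phi[i] > 0) {
        p <- stats::pnbinom(y[i] - 1, size = 1 / phi[i], mu = mu_s[i]) +
          0.5 * stats::dnbinom(y[i], size = 1 / phi[i], mu = mu_s[i])
        p <- min(max(p, 1e-12), 1 - 1e-12)
        out[i, s] <- stats::qnbinom(p, size = 1 / phi[i], mu = mu_t[i])
      } else {
        p <- stats::ppois(y[i] - 1, mu_s[i]) + 0.5 * stats::dpois(y[i], mu_s[i])
        p <- min(max(p, 1e-12), 1 - 1e-12)
        out[i, s] <- stats::qpois(p, mu_t[i])
      }
    }
  }
  out
}

# Two-sided conditional exact p for group sums (S1, S2) given the total:
# the sum of k iid NB(mu, phi) is NB(k mu, phi/k), so the conditional law
# of S1 | S1 + S2 = T follows from the two group-sum pmfs; the p-value sums
# all outcomes no more probable than the observed one.
#' @noRd
nb_exact_p <- function(S1, S2, n1, n2, mu1, mu2, phi) {
  T_ <- S1 + S2
  if (T_ == 0) return(1)
  s <- 0:T_
  if (phi < 1e-12) {
    pr <- stats::dbinom(s, T_, mu1 / (mu1 + mu2))
  } else {
    lp <- stats::dnbinom(s, size = n1 / phi, mu = mu1, log = TRUE) +
      stats::dnbinom(T_ - s, size = n2 / phi, mu = mu2, log = TRUE)
    lp <- lp - max(lp)
    pr <- exp(lp); pr <- pr / sum(pr)
  }
  p_obs <- pr[S1 + 1]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-8)]))
}

#' Negative-binomial two-group test per gene
#'
#' `method = "lrt"` (default, mirroring a one-coefficient log-linear
#' model): maximum-likelihood NB means per sex with log link and
#' library-size offsets at fixed dispersion, likelihood-ratio statistic
#' against the equal-mean null referred to chi-squared(1).
#' `method = "exact"`: counts are quantile-adjusted to a common library
#' size and the conditional exact two-sided p of the female group sum
#' given the total is computed.  log2 fold changes are oriented female
#' over male and use a prior count of `prior_count` scaled by relative
#' library size.
#'
#' @param counts_F,counts_M Count matrices (genes x replicates) or vectors.
#' @param lib_F,lib_M Library sizes (effective, i.e. TMM-scaled, when
#'   available); default column sums.
#' @param phi Dispersion, scalar or per gene.
#' @param method `"lrt"` or `"exact"`.
#' @param prior_count Prior count for the fold change (default 0.5).
#' @return Data frame with `logFC` and `p`, rows named by gene.
#' @export
nb_two_group_test <- function(counts_F, counts_M, lib_F = NULL, lib_M = NULL,
                              phi, method = c("lrt", "exact"),
                              prior_count = 0.5) {
  method <- match.arg(method)
  YF <- if (is.matrix(counts_F)) counts_F else matrix(counts_F, ncol = 1)
  YM <- if (is.matrix(counts_M)) counts_M else matrix(counts_M, ncol = 1)
  stopifnot(nrow(YF) == nrow(YM))
  g <- nrow(YF)
  lib_F <- lib_F %||% colSums(YF)
  lib_M <- lib_M %||% colSums(YM)
  phi <- rep_len(phi, g)
  if (any(phi < 0)) stop("dispersion must be >= 0", call. = FALSE)

  # prior-count-adjusted mean CPM per sex
  Lbar <- mean(c(lib_F, lib_M))
  adj_cpm <- function(Y, lib) {
    pri <- prior_count * lib / Lbar
    rowMeans(sweep(sweep(Y, 2, pri, "+"), 2, lib, "/")) * 1e6
  }
  cF <- adj_cpm(YF, lib_F); cM <- adj_cpm(YM, lib_M)
  logFC <- log2(cF / cM)

  allzero <- rowSums(YF) + rowSums(YM) == 0
  p <- rep(1, g)

  if (method == "lrt") {
    mF <- fit_nb_mean(YF, lib_F, phi)
    mM <- fit_nb_mean(YM, lib_M, phi)
    m0 <- fit_nb_mean(cbind(YF, YM), c(lib_F, lib_M), phi)
    ll_alt <- nb_loglik(YF, lib_F, mF, phi) + nb_loglik(YM, lib_M, mM, phi)
    ll_null <- nb_loglik(cbind(YF, YM), c(lib_F, lib_M), m0, phi)
    lrt <- pmax(2 * (ll_alt - ll_null), 0)
    p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  } else {
    L <- c(lib_F, lib_M)
    Lstar <- exp(mean(log(L)))
    m0 <- fit_nb_mean(cbind(YF, YM), L, phi)
    PF <- pseudo_counts(YF, lib_F, Lstar, m0, phi)
    PM <- pseudo_counts(YM, lib_M, Lstar, m0, phi)
    S1 <- round(rowSums(PF)); S2 <- round(rowSums(PM))
    n1 <- ncol(YF); n2 <- ncol(YM)
    for (i in seq_len(g)) {
      if (allzero[i]) next
      p[i] <- nb_exact_p(S1[i], S2[i], n1, n2,
                         mu1 = n1 * m0[i] * Lstar, mu2 = n2 * m0[i] * Lstar,
                         phi = phi[i])
    }
  }
  p[allzero] <- 1
  logFC[allzero] <- 0
  out <- data.frame(logFC = logFC, p = p)
  rownames(out) <- rownames(YF)
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement, as in
#' `p.adjust(method = "BH")`.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Adjusted FDR values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Label genes as sex-biased from fold change and FDR
#'
#' Strict thresholds: `female_biased` when `logFC > lfc_threshold` and
#' `FDR < fdr_threshold`; `male_biased` when `logFC < -lfc_threshold` and
#' `FDR < fdr_threshold`; `unbiased` otherwise.  logFC is oriented female
#' over male.
#'
#' @param results Data frame with `logFC` and `FDR` columns.
#' @param lfc_threshold log2 fold-change threshold (default 2).
#' @param fdr_threshold FDR threshold (default 0.05).
#' @return The input with a `label` column added.
#' @export
call_sex_biased <- function(results, lfc_threshold = 2, fdr_threshold = 0.05) {
  if (!is.numeric(lfc_threshold) || lfc_threshold <= 0)
    abort_config("lfc_threshold", "must be > 0")
  if (!is.numeric(fdr_threshold) || fdr_threshold <= 0)
    abort_config("fdr_threshold", "must be > 0")
  label <- rep("unbiased", nrow(results))
  sig <- results$FDR < fdr_threshold
  label[sig & results$logFC > lfc_threshold] <- "female_biased"
  label[sig & results$logFC < -lfc_threshold] <- "male_biased"
  results$label <- label
  results
}

#' Fisher's exact test for X-vs-autosome enrichment of biased genes
#'
#' Builds the 2x2 table with rows (biased in the given direction,
#' unbiased) and columns (X, autosome); genes labelled `filtered`, biased
#' in the other direction, or on unassigned chromosomes are excluded.  The
#' two-sided p sums all hypergeometric outcomes no more probable than the
#' observed table; the odds ratio is the cross-product `ad/bc`
#' (OR > 1: biased genes over-represented on the X).
#'
#' @param bias_table Data frame with `chrom` and `label` columns.
#' @param classification A `chrom_classification`.
#' @param direction `"female"` or `"male"`.
#' @return An `enrichment_result` list: `table`, `odds_ratio`, `p.value`,
#'   `direction`, `enriched_on`.
#' @export
fisher_enrichment <- function(bias_table, classification,
                              direction = c("female", "male")) {
  direction <- match.arg(direction)
  lab <- stats::setNames(classification$label, classification$chrom)
  cls <- lab[bias_table$chrom]
  biased_lab <- paste0(direction, "_biased")
  keep <- cls %in% c("X", "autosome") & bias_table$label %in% c(biased_lab, "unbiased")
  cls <- cls[keep]
  biased <- bias_table$label[keep] == biased_lab
  a <- sum(biased & cls == "X"); b <- sum(biased & cls == "autosome")
  c_ <- sum(!biased & cls == "X"); d <- sum(!biased & cls == "autosome")
  tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE,
                dimnames = list(c("biased", "unbiased"), c("X", "autosome")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("empty margin in ", direction, "-biased enrichment table",
            call. = FALSE)
    return(structure(list(table = tab, odds_ratio = NA_real_,
                          p.value = NA_real_, direction = direction,
                          enriched_on = NA_character_),
                     class = "enrichment_result"))
  }
  or <- if (b * c_ == 0) {
    if (a * d == 0) NA_real_ else Inf
  } else (a * d) / (b * c_)
  p <- stats::fisher.test(tab)$p.value
  enriched_on <- if (a / (a + c_) >= b / (b + d)) "X" else "autosome"
  structure(list(table = tab, odds_ratio = or, p.value = p,
                 direction = direction, enriched_on = enriched_on),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("%s-biased enrichment: OR = %s, two-sided Fisher p = %s (%s)\n",
              x$direction, format(x$odds_ratio, digits = 4),
              format(x$p.value, digits = 4),
              if (is.na(x$enriched_on)) "undefined"
              else paste0("higher proportion on ", x$enriched_on)))
  print(x$table)
  invisible(x)
}

#' Full sex-bias analysis for one tissue
#'
#' CPM filter, dispersion estimation, NB two-group test (female vs male),
#' BH correction, bias labelling and X/autosome enrichment in both
#' directions.  Library sizes are TMM-scaled before testing.
#'
#' @param counts Count matrix for one tissue (genes x samples).
#' @param samples Sample metadata aligned to the columns.
#' @param gene_table Gene table supplying the chromosome of each gene.
#' @param classification A `chrom_classification`.
#' @param design `"replicated"` or `"unreplicated"`.
#' @param bcv Fixed BCV for the unreplicated design (default 0.2).
#' @param cpm_threshold CPM filter threshold (default 1).
#' @param lfc_threshold,fdr_threshold Bias-call thresholds (defaults 2, 0.05).
#' @param method Test method; defaults to `"lrt"` for replicated and
#'   `"exact"` for unreplicated designs.
#' @param prior_count Prior count for fold changes (default 0.5).
#' @return List: `bias_table` (gene_id, chrom, class, logFC, p, FDR,
#'   label), `enrichment` (list with `female` and `male`
#'   `enrichment_result`s), `n_retained`.
#' @export
sex_bias_analysis <- function(counts, samples, gene_table, classification,
                              design = c("replicated", "unreplicated"),
                              bcv = 0.2, cpm_threshold = 1,
                              lfc_threshold = 2, fdr_threshold = 0.05,
                              method = NULL, prior_count = 0.5) {
  design <- match.arg(design)
  counts <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  method <- method %||% if (design == "replicated") "lrt" else "exact"
  tf <- if (ncol(counts) >= 2) tmm_factors(counts) else rep(1, ncol(counts))
  cpm_mat <- cpm(counts, tf)
  keep <- cpm_filter(cpm_mat, samples, cpm_threshold, design)
  if (!any(keep)) stop("no genes pass the CPM filter", call. = FALSE)
  sub <- counts[keep, , drop = FALSE]
  phi <- estimate_dispersion(sub, samples, design, bcv = bcv)
  eff <- colSums(counts) * tf
  colF <- samples$sample_id[samples$sex == "F"]
  colM <- samples$sample_id[samples$sex == "M"]
  if (length(colF) == 0 || length(colM) == 0)
    stop("both sexes required for sex-bias analysis", call. = FALSE)
  res <- nb_two_group_test(sub[, colF, drop = FALSE], sub[, colM, drop = FALSE],
                           lib_F = eff[colF], lib_M = eff[colM],
                           phi = phi, method = method,
                           prior_count = prior_count)
  res$FDR <- bh_adjust(res$p)
  res <- call_sex_biased(res, lfc_threshold, fdr_threshold)

  chrom_of <- stats::setNames(gene_table$chrom, gene_table$gene_id)
  class_of <- stats::setNames(classification$label, classification$chrom)
  tab <- data.frame(gene_id = rownames(counts),
                    chrom = unname(chrom_of[rownames(counts)]),
                    stringsAsFactors = FALSE)
  tab$class <- unname(class_of[tab$chrom])
  tab$mean_cpm_F <- rowMeans(cpm_mat[, colF, drop = FALSE])
  tab$mean_cpm_M <- rowMeans(cpm_mat[, colM, drop = FALSE])
  idx <- match(tab$gene_id, rownames(res))
  tab$logFC <- res$logFC[idx]
  tab$p <- res$p[idx]
  tab$FDR <- res$FDR[idx]
  tab$label <- ifelse(is.na(idx), "filtered", res$label[idx])
  enrichment <- list(
    female = fisher_enrichment(tab, classification, "female"),
    male = fisher_enrichment(tab, classification, "male"))
  list(bias_table = tab, enrichment = enrichment, n_retained = sum(keep))
}
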