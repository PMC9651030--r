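# Sex-bias calling: CPM and its filter, dispersion estimation, the NB
# two-group tests against enumeration/convolution oracles and edgeR, BH,
# label thresholds, and Fisher enrichment against a hypergeometric oracle.

test_that("CPM scales counts per million and is inverse-linear in depth", {
  m <- matrix(c(100L, 999900L), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  expect_equal(cpm(m)["g1", "s1"], 100)
  expect_equal(colSums(cpm(m)), c(s1 = 1e6))
  m2 <- cbind(m, s2 = 2L * m[, 1])
  cc <- cpm(m2)
  expect_equal(cc[, 1], cc[, 2], ignore_attr = TRUE)  # pure depth change
  expect_error(cpm(matrix(0L, 2, 1)), "zero library")
})

test_that("CPM filter keeps genes passing in all replicates of one sex", {
  samples <- data.frame(sample_id = c("f1", "f2", "m1", "m2"),
                        tissue = "t", sex = c("F", "F", "M", "M"),
                        replicate = c(1:2, 1:2), stringsAsFactors = FALSE)
  cpm_mat <- rbind(g1 = c(2, 3, 0, 0),       # F passes in both reps -> kept
                   g2 = c(2, 0.5, 0.5, 0.5), # no sex passes in all reps -> out
                   g3 = c(0.5, 0.6, 4, 9))   # M passes -> kept
  colnames(cpm_mat) <- samples$sample_id
  keep <- cpm_filter(cpm_mat, samples, threshold = 1, design = "replicated")
  expect_equal(unname(keep), c(TRUE, FALSE, TRUE))
  # unreplicated: exceeding the threshold in any single sample suffices
  s2 <- samples[c(2, 3), ]
  keep2 <- cpm_filter(cpm_mat[, c("f2", "m1")], s2, design = "unreplicated")
  expect_equal(unname(keep2), c(TRUE, FALSE, TRUE))
  expect_true(all(cpm_filter(cpm_mat, samples, threshold = 0,
                             design = "replicated")))
})

test_that("dispersion is the fixed BCV^2 when unreplicated and shrinks toward truth", {
  samples <- data.frame(sample_id = paste0("s", 1:8), tissue = "t",
                        sex = rep(c("F", "M"), each = 4),
                        replicate = rep(1:4, 2), stringsAsFactors = FALSE)
  set.seed(20)
  m <- matrix(rpois(800, 100), 100, 8, dimnames = list(NULL, samples$sample_id))
  expect_equal(unname(estimate_dispersion(m[, c(1, 5)], samples[c(1, 5), ],
                                          "unreplicated")),
               rep(0.04, 100))

  # Poisson counts: high-count genes shrink to near-zero dispersion
  set.seed(21)
  mp <- matrix(rpois(2000 * 8, 800), 2000, 8,
               dimnames = list(NULL, samples$sample_id))
  phi_p <- estimate_dispersion(mp, samples, "replicated")
  expect_lte(median(phi_p), 0.01)

  # NB truth 0.1 with 4 reps/sex: median estimate inside the recovery band
  mu <- rlnorm(2000, 5, 1)
  mn <- matrix(rnbinom(2000 * 8, mu = rep(mu, 8), size = 10), 2000, 8,
               dimnames = list(NULL, samples$sample_id))
  phi_n <- estimate_dispersion(mn, samples, "replicated")
  expect_gte(median(phi_n), 0.05)
  expect_lte(median(phi_n), 0.2)
})

test_that("NB tests are null at symmetry and exact in the Poisson limit", {
  res <- nb_two_group_test(rbind(c(5, 5)), rbind(c(5, 5)),
                           lib_F = c(100, 100), lib_M = c(100, 100), phi = 0.1)
  expect_equal(res$p, 1)
  expect_equal(res$logFC, 0)
  # phi -> 0, counts (0, 10), equal libraries: conditional Binomial(10, 1/2)
  res <- nb_two_group_test(rbind(0), rbind(10), lib_F = 1e4, lib_M = 1e4,
                           phi = 0, method = "exact")
  expect_equal(res$p, 2 / 1024, tolerance = 1e-12)
  # all-zero gene: flagged null
  res <- nb_two_group_test(rbind(c(0, 0)), rbind(c(0, 0)), c(10, 10), c(10, 10),
                           phi = 0.04, method = "lrt")
  expect_equal(res$p, 1)
  expect_equal(res$logFC, 0)
})

# Independent route for the exact test: null mean by 1-d likelihood search,
# group-sum pmfs by explicit convolution of per-sample NB pmfs.
nb_exact_oracle <- function(yF, yM, L, phi) {
  Y <- c(yF, yM)
  T_ <- sum(Y)
  nll <- function(m) -sum(dnbinom(Y, size = 1 / phi, mu = m * L, log = TRUE))
  m0 <- optimize(nll, c(1e-9, 10 * (T_ + 1) / sum(L)))$minimum
  conv <- function(a, b) {
    vapply(seq_along(a), function(i) sum(a[1:i] * b[i:1]), numeric(1))
  }
  group_pmf <- function(k) {
    pmf <- dnbinom(0:T_, size = 1 / phi, mu = m0 * L[1])
    out <- pmf
    if (k > 1) for (i in 2:k) out <- conv(out, pmf)
    out
  }
  p1 <- group_pmf(length(yF))
  p2 <- group_pmf(length(yM))
  pr <- p1 * rev(p2)
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[sum(yF) + 1] * (1 + 1e-8)])
}

test_that("exact NB test matches the convolution oracle at small totals", {
  set.seed(22)
  for (i in 1:8) {
    yF <- rpois(2, 4)
    yM <- rpois(2, 4)
    if (sum(yF, yM) == 0) next
    L <- rep(1000, 4)
    mine <- nb_two_group_test(rbind(yF), rbind(yM), L[1:2], L[3:4],
                              phi = 0.04, method = "exact")$p
    expect_equal(mine, nb_exact_oracle(yF, yM, L, 0.04), tolerance = 1e-6)
  }
})

test_that("LRT p-values match edgeR's GLM at fixed dispersion", {
  set.seed(23)
  g <- 150
  mu <- rlnorm(g, 4, 1)
  fc <- ifelse(seq_len(g) <= 20, 4, 1)
  lib <- c(9e5, 1.1e6, 1e6, 1.05e6)
  YF <- matrix(rnbinom(2 * g, mu = rep(mu * fc, 2), size = 10), g, 2)
  YM <- matrix(rnbinom(2 * g, mu = rep(mu, 2), size = 10), g, 2)
  phi <- 0.1
  mine <- nb_two_group_test(YF, YM, lib[1:2], lib[3:4], phi = phi,
                            method = "lrt")
  counts <- cbind(YF, YM)
  design <- model.matrix(~ factor(c("F", "F", "M", "M"), levels = c("M", "F")))
  fit <- edgeR::glmFit(counts, design, dispersion = phi, lib.size = lib,
                       prior.count = 0)
  et <- edgeR::glmLRT(fit)
  expect_equal(mine$p, et$table$PValue, tolerance = 1e-4)
})

test_that("BH adjustment matches the step-up formula and preserves rank order", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(bh_adjust(p), rep(0.04, 4))
  manual <- function(p) {
    n <- length(p)
    o <- order(p, decreasing = TRUE)
    pmin(1, cummin(p[o] * n / (n:1)))[order(o)]
  }
  set.seed(24)
  q <- runif(50)
  expect_equal(bh_adjust(q), manual(q))
  expect_equal(bh_adjust(0.2), 0.2)
  # monotone: adjusted values are non-decreasing in p-value order
  expect_true(all(diff(bh_adjust(q)[order(q)]) >= 0))
})

test_that("bias labels apply strict logFC and FDR thresholds", {
  res <- data.frame(logFC = c(3, 2, -4, -4, 1),
                    FDR = c(0.01, 0.001, 0.2, 0.01, 0.0001))
  lab <- call_sex_biased(res)$label
  expect_equal(lab, c("female_biased", "unbiased", "unbiased",
                      "male_biased", "unbiased"))
})

# Direct hypergeometric summation oracle for the 2x2 exact test.
fisher_oracle <- function(a, b, c_, d) {
  m <- a + b
  n <- c_ + d
  k <- a + c_
  lo <- max(0, k - n)
  hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  sum(probs[probs <= dhyper(a, m, n, k) * (1 + 1e-7)])
}

test_that("Fisher enrichment matches hypergeometric enumeration", {
  cl <- two_class_classification()
  # table [[3,1],[1,3]]: 3 female-biased on X, 1 on an autosome, etc.
  bias <- data.frame(
    chrom = c(rep("chrX", 4), rep("chr1", 4)),
    label = c(rep("female_biased", 3), "unbiased",
              "female_biased", rep("unbiased", 3)),
    stringsAsFactors = FALSE)
  e <- fisher_enrichment(bias, cl, "female")
  expect_equal(unname(e$table), matrix(c(3, 1, 1, 3), 2, byrow = TRUE))
  expect_equal(e$p.value, 34 / 70, tolerance = 1e-12)

  # proportional rows: p = 1 and OR = 1 when ad = bc
  bias2 <- data.frame(
    chrom = c(rep("chrX", 6), rep("chr1", 24)),
    label = c(rep("male_biased", 2), rep("unbiased", 4),
              rep("male_biased", 8), rep("unbiased", 16)),
    stringsAsFactors = FALSE)
  e2 <- fisher_enrichment(bias2, cl, "male")
  expect_equal(e2$p.value, 1)
  expect_equal(e2$odds_ratio, 1)

  # random tables with small margins match the oracle exactly
  set.seed(25)
  for (i in 1:20) {
    a <- sample(0:12, 1)
    b <- sample(0:12, 1)
    c_ <- sample(1:12, 1)
    d <- sample(1:12, 1)
    if (a + b == 0) next
    bias3 <- data.frame(
      chrom = c(rep("chrX", a + c_), rep("chr1", b + d)),
      label = c(rep("female_biased", a), rep("unbiased", c_),
                rep("female_biased", b), rep("unbiased", d)),
      stringsAsFactors = FALSE)
    e3 <- fisher_enrichment(bias3, cl, "female")
    expect_equal(e3$p.value, fisher_oracle(a, b, c_, d), tolerance = 1e-9)
  }
  # empty margin: missing result with a warning
  none <- data.frame(chrom = c("chrX", "chr1"), label = "unbiased",
                     stringsAsFactors = FALSE)
  expect_warning(e4 <- fisher_enrichment(none, cl, "female"), "empty margin")
  expect_true(is.na(e4$p.value))
})

test_that("null simulations stay within FDR bounds and fold-8 genes are recovered", {
  # null: no true bias, replicated design, dispersion 0.1
  frac <- vapply(1:2, function(s) {
    cfg <- sim_config(n_genes_per_chrom = 150L, libsize = 1e6,
                      bias_fraction_female = 0, bias_fraction_male = 0,
                      dispersion = 0.1, seed = 100 + s)
    g <- simulate_genome(cfg)
    ex <- simulate_expression(g, cfg, tissue_plan("t", n_replicates = 2L))
    cl <- two_class_classification(auto_chroms = paste0("chr", 1:14))
    # empty-margin enrichment warnings are expected when nothing is biased
    sb <- suppressWarnings(sex_bias_analysis(ex$counts, ex$samples, g$genes,
                                             cl, design = "replicated"))
    tested <- sb$bias_table[sb$bias_table$label != "filtered", ]
    mean(tested$label %in% c("female_biased", "male_biased"))
  }, numeric(1))
  expect_lte(mean(frac), 0.05)

  # power: fold-8 biased genes at high expression called with the right label
  cfg <- sim_config(n_genes_per_chrom = 300L, libsize = 2e6,
                    bias_fraction_female = 0.05, bias_fraction_male = 0.05,
                    bias_fold = 8, seed = 41)
  g <- simulate_genome(cfg)
  ex <- simulate_expression(g, cfg, tissue_plan("t", n_replicates = 2L))
  cl <- two_class_classification(auto_chroms = paste0("chr", 1:14))
  sb <- sex_bias_analysis(ex$counts, ex$samples, g$genes, cl,
                          design = "replicated")
  truth <- merge(sb$bias_table,
                 ex$truth[, c("gene_id", "bias_label", "baseline_fpkm")],
                 by = "gene_id")
  hi <- truth[truth$baseline_fpkm >= 5 & truth$bias_label != "unbiased", ]
  expect_gt(nrow(hi), 20)
  expect_gte(mean(hi$label == hi$bias_label), 0.9)
})

test_that("female-biased genes concentrated on X give significant enrichment", {
  cfg <- sim_config(n_genes_per_chrom = 300L, libsize = 2e6,
                    bias_fraction_female = 0.05, bias_fraction_male = 0.05,
                    bias_fold = 8, bias_female_on_x = 0.3, seed = 52)
  g <- simulate_genome(cfg)
  ex <- simulate_expression(g, cfg, tissue_plan("t", n_replicates = 2L))
  cl <- two_class_classification(auto_chroms = paste0("chr", 1:14))
  sb <- sex_bias_analysis(ex$counts, ex$samples, g$genes, cl,
                          design = "replicated")
  e <- sb$enrichment$female
  expect_lt(e$p.value, 0.01)
  expect_gt(e$odds_ratio, 1)
})
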