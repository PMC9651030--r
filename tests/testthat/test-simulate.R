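# Synthetic-data generator: genome structure, Poisson coverage with the
# half-dose male X, NB counts under the compensation regimes, fixture I/O.

test_that("simulated genome has the XX/XO structure and valid gene spans", {
  g <- simulate_genome(small_config())
  expect_equal(nrow(g$chromosomes), 15L)
  expect_equal(sum(g$chromosomes$true_class == "X"), 1L)
  expect_equal(nrow(g$genes), 15L * 60L)
  len <- setNames(g$chromosomes$length, g$chromosomes$name)
  expect_true(all(g$genes$start >= 1))
  expect_true(all(g$genes$end <= len[g$genes$chrom]))
  expect_true(all(g$genes$exonic_length >= 1))
  expect_true(all(g$genes$exonic_length <= g$genes$end - g$genes$start + 1))
  # non-overlapping within chromosome (tiled in order)
  for (cn in unique(g$genes$chrom)) {
    gg <- g$genes[g$genes$chrom == cn, ]
    expect_true(all(gg$start[-1] > gg$end[-nrow(gg)]))
  }
  # degenerate config: X only
  g0 <- simulate_genome(small_config(n_autosomes = 0L))
  expect_equal(g0$chromosomes$name, "chrX")
})

test_that("identical seeds reproduce identical outputs, different seeds differ", {
  cfg <- small_config(seed = 11)
  g1 <- simulate_genome(cfg); g2 <- simulate_genome(cfg)
  expect_identical(g1, g2)
  expect_identical(simulate_dna_coverage(g1, cfg), simulate_dna_coverage(g2, cfg))
  e1 <- simulate_expression(g1, cfg); e2 <- simulate_expression(g1, cfg)
  expect_identical(e1, e2)
  g3 <- simulate_genome(small_config(seed = 12))
  expect_false(identical(g1$genes, g3$genes))
})

test_that("invalid configurations are rejected naming the field", {
  expect_error(small_config(regime = "bogus"), "regime.*complete_compensation")
  expect_error(small_config(bias_fraction_female = 1.5), "bias_fraction_female")
  expect_error(small_config(bias_fold = 1), "bias_fold")
  expect_error(small_config(libsize = 0), "libsize")
  expect_error(small_config(window_size = -1), "window_size")
})

test_that("coverage follows the half-dose Poisson model", {
  # zero library: all depths zero
  cfg0 <- small_config(depth_female = 0)
  g <- simulate_genome(cfg0)
  cov0 <- simulate_dna_coverage(g, cfg0)
  expect_true(all(cov0$depth_male == 0) && all(cov0$depth_female == 0))

  # >= 200 windows per chromosome at depth 100
  cfg <- small_config(window_size = 500, depth_female = 100, seed = 4)
  g <- simulate_genome(cfg)
  cov <- simulate_dna_coverage(g, cfg)
  x <- cov[cov$chrom == "chrX", ]
  expect_gte(nrow(x), 200)
  expect_lt(abs(mean(x$depth_male) / 50 - 1), 0.1)
  auto <- cov[cov$chrom != "chrX", ]
  expect_lt(abs(mean(auto$depth_male) / mean(auto$depth_female) - 1), 0.1)
  # Poisson: variance tracks the mean
  expect_lt(abs(var(x$depth_female) / mean(x$depth_female) - 1), 0.3)

  # window larger than the chromosome is rejected
  expect_error(simulate_dna_coverage(g, small_config(window_size = 1e9)),
               "window_size")
})

test_that("expression regimes set the male:female mean-count ratio on X", {
  for (case in list(c("complete_compensation", 1), c("no_compensation", 0.5))) {
    cfg <- small_config(n_genes_per_chrom = 400L, regime = case[1],
                        bias_fraction_female = 0, bias_fraction_male = 0,
                        seed = 21)
    g <- simulate_genome(cfg)
    ex <- simulate_expression(g, cfg, tissue_plan("t", n_replicates = 1L))
    on_x <- ex$truth$chrom == "chrX" & ex$counts[, "t_F_rep1"] >= 10
    # median of per-gene ratios: robust to the heavy-tailed baseline
    ratio <- median(ex$counts[on_x, "t_M_rep1"] / ex$counts[on_x, "t_F_rep1"])
    expect_lt(abs(ratio / as.numeric(case[2]) - 1), 0.1)
    expect_true(all(ex$truth$bias_label == "unbiased"))
  }
})

test_that("bias labels and X placement follow the configured fractions", {
  cfg <- small_config(bias_fraction_female = 0.1, bias_fraction_male = 0.1,
                      bias_female_on_x = 0.5, seed = 8)
  g <- simulate_genome(cfg)
  ex <- simulate_expression(g, cfg)
  n <- nrow(ex$truth)
  expect_equal(sum(ex$truth$bias_label == "female_biased"), round(0.1 * n))
  expect_equal(sum(ex$truth$bias_label == "male_biased"), round(0.1 * n))
  fb <- ex$truth[ex$truth$bias_label == "female_biased", ]
  expect_gte(sum(fb$chrom == "chrX"), round(0.5 * nrow(fb)) - 1)
  # unknown regime at expression time is impossible by construction, but the
  # favoured sex must actually be favoured in the counts
  fb_ids <- fb$gene_id
  f_cols <- ex$samples$sample_id[ex$samples$sex == "F"]
  m_cols <- ex$samples$sample_id[ex$samples$sex == "M"]
  fc <- rowSums(ex$counts[fb_ids, f_cols, drop = FALSE]) /
    pmax(rowSums(ex$counts[fb_ids, m_cols, drop = FALSE]), 1)
  expect_gt(median(fc), 4)
})

test_that("fixture sets round-trip losslessly and the manifest is complete", {
  cfg <- small_config(seed = 5)
  g <- simulate_genome(cfg)
  cov <- simulate_dna_coverage(g, cfg)
  ex <- simulate_expression(g, cfg)
  dir <- withr::local_tempdir()
  manifest <- write_fixture_set(g, cov, ex, dir)

  genes_tsv <- read_gene_table(file.path(dir, "genes.tsv"))
  expect_equal(genes_tsv, g$genes)
  genes_gff <- read_gene_table(file.path(dir, "genes.gff3"))
  expect_equal(genes_gff[order(genes_gff$gene_id), ],
               g$genes[order(g$genes$gene_id), ], ignore_attr = TRUE)

  cov2 <- read_coverage(file.path(dir, "coverage.tsv"))
  expect_equal(as.data.frame(cov2), as.data.frame(cov)[order(cov$chrom, cov$start), ],
               ignore_attr = TRUE)

  cm <- read_counts(file.path(dir, "counts.tsv"), file.path(dir, "samples.tsv"))
  expect_equal(cm$counts, ex$counts)
  expect_equal(cm$samples, ex$samples)

  keys <- vapply(manifest$files, `[[`, "", "key")
  rows <- vapply(manifest$files, function(f) f$rows, 1)
  expect_setequal(keys, c("genes_tsv", "genes_gff3", "coverage", "counts",
                          "samples", "truth"))
  expect_equal(rows[keys == "counts"], nrow(ex$counts), ignore_attr = TRUE)
})

test_that("an empty gene list still yields valid files with headers", {
  g <- structure(list(
    chromosomes = data.frame(name = "chr1", length = 1e5, true_class = "autosome",
                             stringsAsFactors = FALSE),
    genes = data.frame(gene_id = character(0), chrom = character(0),
                       start = integer(0), end = integer(0),
                       exonic_length = integer(0), stringsAsFactors = FALSE)),
    class = "genome_model")
  cov <- data.frame(chrom = "chr1", start = 0, end = 1e5,
                    depth_male = 10, depth_female = 10)
  samples <- data.frame(sample_id = "t_F_rep1", tissue = "t", sex = "F",
                        replicate = 1L, stringsAsFactors = FALSE)
  counts <- matrix(integer(0), nrow = 0, ncol = 1,
                   dimnames = list(NULL, "t_F_rep1"))
  ex <- list(counts = counts, samples = samples,
             truth = data.frame(gene_id = character(0)))
  dir <- withr::local_tempdir()
  write_fixture_set(g, cov, ex, dir)
  expect_equal(nrow(read_gene_table(file.path(dir, "genes.tsv"))), 0L)
  cm <- read_counts(file.path(dir, "counts.tsv"), file.path(dir, "samples.tsv"))
  expect_equal(dim(cm$counts), c(0L, 1L))
})
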