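# Shared fixture builders: compact configurations so unit tests run in
# seconds, plus hand-rolled containers for the statistics tests.

small_config <- function(...) {
  args <- list(...)
  defaults <- list(n_genes_per_chrom = 60L, gene_spacing = 2000,
                   window_size = 2e4, libsize = 2e5, depth_female = 50)
  do.call(sim_config, utils::modifyList(defaults, args))
}

as_count_matrix <- function(counts, samples) {
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

# Minimal tissue_expression with explicit per-class means, for the dosage
# statistics tests.
make_te <- function(mean_F, mean_M, chrom, retained = TRUE) {
  te <- data.frame(gene_id = sprintf("g%03d", seq_along(mean_F)),
                   chrom = chrom, mean_F = mean_F, mean_M = mean_M,
                   retained = retained, stringsAsFactors = FALSE)
  class(te) <- c("tissue_expression", "data.frame")
  te
}

two_class_classification <- function(x_chrom = "chrX", auto_chroms = "chr1") {
  data.frame(chrom = c(auto_chroms, x_chrom),
             n_windows_used = 10L,
             median_ratio = c(rep(1, length(auto_chroms)), 0.5),
             label = c(rep("autosome", length(auto_chroms)), "X"),
             stringsAsFactors = FALSE)
}

# Simulation -> filtered per-tissue expression -> dosage report, the path
# the regime-recovery checks exercise.
run_dosage_path <- function(cfg, plan = tissue_plan("gonad", n_replicates = 2L)) {
  genome <- simulate_genome(cfg)
  coverage <- simulate_dna_coverage(genome, cfg)
  classes <- classify_chromosomes(compute_window_ratios(coverage))
  ex <- simulate_expression(genome, cfg, plan)
  expr <- compute_fpkm(as_count_matrix(ex$counts, ex$samples), ex$gene_lengths)
  tes <- lapply(average_replicates(expr, genome$genes), filter_expressed)
  list(report = dosage_report(tes, classes), classes = classes,
       genome = genome, expr = ex)
}
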