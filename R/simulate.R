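# Synthetic-data generator: XX/XO genome models, windowed DNA coverage and
# negative-binomial RNA-seq counts under named dosage-compensation regimes.

VALID_REGIMES <- c("complete_compensation", "no_compensation",
                   "female_downregulation")

#' Simulation configuration for the XX/XO generator
#'
#' Collects and validates every tunable of the synthetic-data module in one
#' object.  Defaults emulate the study system the package targets: a
#' planthopper-like genome of 14 autosomes plus a single X (about 2,000
#' genes per chromosome, roughly 30k genes in total), 100-kb coverage
#' windows at 100x female depth, and RNA-seq counts with a biological
#' coefficient of variation of 0.2 (negative-binomial dispersion 0.04).
#'
#' @param n_autosomes Number of autosomes (the genome always carries one X).
#' @param n_genes_per_chrom Genes tiled on each chromosome.
#' @param gene_spacing Distance in bp between successive gene starts; fixes
#'   chromosome length at `n_genes_per_chrom * gene_spacing`.
#' @param window_size Coverage window width in bp.
#' @param depth_female Mean female read depth per window (Poisson mean).
#' @param regime Dosage-compensation regime applied to X-linked genes:
#'   `"complete_compensation"` (male X expression equals female),
#'   `"no_compensation"` (male X halved), or `"female_downregulation"`
#'   (female X halved to the one-dose level).
#' @param bias_fraction_female,bias_fraction_male Proportions of genes made
#'   female- or male-biased.
#' @param bias_fold Fold change applied to the favoured sex of a biased gene.
#' @param bias_female_on_x Fraction of the female-biased genes forced onto
#'   the X chromosome (0 = placed uniformly at random genome-wide); used to
#'   measure enrichment-test power against a known truth.
#' @param dispersion Negative-binomial dispersion of the counts (BCV^2);
#'   0 gives Poisson counts.
#' @param libsize Nominal reads per RNA-seq library.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   baseline expression level on the FPKM-like scale.
#' @param seed Global seed; each simulator draws from its own named stream
#'   derived from it.
#' @return A validated list of class `xo_sim_config`.
#' @export
sim_config <- function(n_autosomes = 14L,
                       n_genes_per_chrom = 2000L,
                       gene_spacing = 6000,
                       window_size = 1e5,
                       depth_female = 100,
                       regime = "complete_compensation",
                       bias_fraction_female = 0.05,
                       bias_fraction_male = 0.05,
                       bias_fold = 8,
                       bias_female_on_x = 0,
                       dispersion = 0.04,
                       libsize = 5e6,
                       baseline_meanlog = 3,
                       baseline_sdlog = 1.5,
                       seed = 1L) {
  if (!is_count(n_autosomes)) abort_config("n_autosomes", "must be a non-negative integer")
  if (!is_count(n_genes_per_chrom) || n_genes_per_chrom < 1)
    abort_config("n_genes_per_chrom", "must be a positive integer")
  if (!is.numeric(gene_spacing) || gene_spacing <= 0)
    abort_config("gene_spacing", "must be > 0")
  if (!is.numeric(window_size) || window_size <= 0)
    abort_config("window_size", "must be > 0")
  if (!is.numeric(depth_female) || depth_female < 0)
    abort_config("depth_female", "must be >= 0")
  if (!is.character(regime) || length(regime) != 1L || !regime %in% VALID_REGIMES)
    abort_config("regime", paste0("must be one of: ", paste(VALID_REGIMES, collapse = ", ")))
  for (f in c("bias_fraction_female", "bias_fraction_male", "bias_female_on_x")) {
    v <- get(f)
    if (!is.numeric(v) || v < 0 || v > 1) abort_config(f, "must lie in [0, 1]")
  }
  if (!is.numeric(bias_fold) || bias_fold <= 1)
    abort_config("bias_fold", "must be > 1")
  if (!is.numeric(dispersion) || dispersion < 0)
    abort_config("dispersion", "must be >= 0")
  if (!is.numeric(libsize) || libsize <= 0)
    abort_config("libsize", "must be > 0")
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    abort_config("seed", "must be a single integer")
  structure(list(
    n_autosomes = as.integer(n_autosomes),
    n_genes_per_chrom = as.integer(n_genes_per_chrom),
    gene_spacing = gene_spacing,
    window_size = window_size,
    depth_female = depth_female,
    regime = regime,
    bias_fraction_female = bias_fraction_female,
    bias_fraction_male = bias_fraction_male,
    bias_fold = bias_fold,
    bias_female_on_x = bias_female_on_x,
    dispersion = dispersion,
    libsize = libsize,
    baseline_meanlog = baseline_meanlog,
    baseline_sdlog = baseline_sdlog,
    seed = as.integer(seed)
  ), class = "xo_sim_config")
}

#' Tissue/sample plan for expression simulation
#'
#' @param tissue Character vector of tissue names.
#' @param n_replicates Integer vector (recycled) of replicates per sex.
#' @param sexes Comma-separated sexes sampled per tissue (recycled).
#' @param regime Optional per-tissue regime overriding the config regime
#'   (`NA` = use the config value); lets one run mix compensated somatic
#'   tissues with an uncompensated gonad.
#' @return A data frame with one row per tissue.
#' @export
tissue_plan <- function(tissue, n_replicates = 2L, sexes = "F,M", regime = NA_character_) {
  plan <- data.frame(tissue = as.character(tissue),
                     sexes = rep_len(as.character(sexes), length(tissue)),
                     n_replicates = rep_len(as.integer(n_replicates), length(tissue)),
                     regime = rep_len(as.character(regime), length(tissue)),
                     stringsAsFactors = FALSE)
  bad <- !is.na(plan$regime) & !plan$regime %in% VALID_REGIMES
  if (any(bad))
    abort_config("regime", paste0("must be one of: ", paste(VALID_REGIMES, collapse = ", ")))
  if (any(plan$n_replicates < 1L)) abort_config("n_replicates", "must be >= 1")
  plan
}

#' Simulate an XX/XO genome model
#'
#' Builds a genome of `n_autosomes` autosomes plus one X chromosome, each
#' carrying `n_genes_per_chrom` non-overlapping genes tiled at regular
#' starts, with randomised gene spans and exonic lengths.
#'
#' @param config A [sim_config()] object.
#' @return A `genome_model`: list with `chromosomes` (name, length,
#'   true_class) and `genes` (gene_id, chrom, start, end, exonic_length;
#'   1-based inclusive coordinates).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "xo_sim_config"))
  chrom_names <- c(if (config$n_autosomes > 0) paste0("chr", seq_len(config$n_autosomes)),
                   "chrX")
  chrom_len <- config$n_genes_per_chrom * config$gene_spacing
  chromosomes <- data.frame(
    name = chrom_names,
    length = rep(chrom_len, length(chrom_names)),
    true_class = c(rep("autosome", config$n_autosomes), "X"),
    stringsAsFactors = FALSE
  )
  genes <- with_stream(config$seed, "genome", {
    do.call(rbind, lapply(chrom_names, function(cn) {
      n <- config$n_genes_per_chrom
      start <- (seq_len(n) - 1L) * config$gene_spacing + 1
      max_span <- max(2, floor(config$gene_spacing * 0.8))
      span <- pmax(2L, round(stats::runif(n, 0.2, 1) * max_span))
      exonic <- pmax(1L, round(span * stats::runif(n, 0.3, 0.9)))
      data.frame(gene_id = sprintf("%s_g%05d", cn, seq_len(n)),
                 chrom = cn, start = start, end = start + span - 1,
                 exonic_length = exonic, stringsAsFactors = FALSE)
    }))
  })
  rownames(genes) <- NULL
  structure(list(chromosomes = chromosomes, genes = genes),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %d chromosomes (%d autosomes + %d X), %d genes\n",
              nrow(x$chromosomes), sum(x$chromosomes$true_class == "autosome"),
              sum(x$chromosomes$true_class == "X"), nrow(x$genes)))
  invisible(x)
}

# Window starts (0-based) for one chromosome; the trailing partial window is
# kept only when at least half a window wide, to avoid high-variance stubs.
#' @noRd
tile_windows <- function(chrom_len, window_size) {
  starts <- seq(0, chrom_len - 1, by = window_size)
  ends <- pmin(starts + window_size, chrom_len)
  keep <- (ends - starts) >= window_size / 2
  cbind(start = starts[keep], end = ends[keep])
}

#' Simulate male/female windowed DNA coverage
#'
#' Per-window depth is Poisson with female mean `depth_female` everywhere;
#' the male mean equals the female mean on autosomes and half of it on the
#' X, emulating one versus two X copies at matched sequencing depth.
#'
#' @param genome A `genome_model`.
#' @param config A [sim_config()] object.
#' @return A `coverage_windows` data frame (chrom, start, end, depth_male,
#'   depth_female) in 0-based half-open coordinates.
#' @export
simulate_dna_coverage <- function(genome, config) {
  stopifnot(inherits(genome, "genome_model"), inherits(config, "xo_sim_config"))
  if (config$window_size > min(genome$chromosomes$length))
    stop("window_size (", config$window_size,
         ") exceeds the shortest chromosome length (",
         min(genome$chromosomes$length), ")", call. = FALSE)
  cov <- with_stream(config$seed, "coverage", {
    do.call(rbind, lapply(seq_len(nrow(genome$chromosomes)), function(i) {
      ch <- genome$chromosomes[i, ]
      w <- tile_windows(ch$length, config$window_size)
      n <- nrow(w)
      mu_m <- if (ch$true_class == "X") config$depth_female / 2 else config$depth_female
      data.frame(chrom = ch$name, start = w[, "start"], end = w[, "end"],
                 depth_male = stats::rpois(n, mu_m),
                 depth_female = stats::rpois(n, config$depth_female),
                 stringsAsFactors = FALSE)
    }))
  })
  rownames(cov) <- NULL
  validate_coverage(cov)
}

#' Simulate RNA-seq counts under a compensation regime
#'
#' Baseline expression per gene is log-normal on an FPKM-like scale and is
#' shared across tissues (with a mild log-normal tissue jitter); expected
#' counts follow the FPKM identity (expression x exonic kb x library
#' size/1e6) and realised counts are negative-binomial at the configured
#' dispersion.  The regime rescales X-linked means in one sex; sex-biased
#' genes multiply the favoured sex by `bias_fold`.
#'
#' @param genome A `genome_model`.
#' @param config A [sim_config()] object.
#' @param plan A [tissue_plan()] data frame; a per-tissue `regime` column
#'   overrides `config$regime`.
#' @return A `sim_expression` list: integer `counts` (genes x samples),
#'   `samples` metadata (sample_id, tissue, sex, replicate), `truth`
#'   (gene_id, chrom, bias_label, baseline_fpkm), and `gene_lengths`
#'   (exonic bp, named by gene).
#' @export
simulate_expression <- function(genome, config,
                                plan = tissue_plan("tissue1", n_replicates = 2L)) {
  stopifnot(inherits(genome, "genome_model"), inherits(config, "xo_sim_config"))
  genes <- genome$genes
  g <- nrow(genes)
  on_x <- genes$chrom %in% genome$chromosomes$name[genome$chromosomes$true_class == "X"]

  sim <- with_stream(config$seed, "expression", {
    baseline <- stats::rlnorm(g, config$baseline_meanlog, config$baseline_sdlog)

    # Truth labels: biased genes drawn without replacement, uniformly over
    # the genome unless a fraction of female-biased genes is pinned to X.
    n_f <- round(config$bias_fraction_female * g)
    n_m <- round(config$bias_fraction_male * g)
    label <- rep("unbiased", g)
    idx_f <- integer(0)
    if (n_f > 0) {
      n_fx <- min(round(config$bias_female_on_x * n_f), sum(on_x))
      idx_fx <- if (n_fx > 0) sample(which(on_x), n_fx) else integer(0)
      pool <- setdiff(seq_len(g), idx_fx)
      idx_f <- c(idx_fx, sample(pool, n_f - n_fx))
      label[idx_f] <- "female_biased"
    }
    if (n_m > 0) {
      pool <- setdiff(seq_len(g), idx_f)
      idx_m <- sample(pool, min(n_m, length(pool)))
      label[idx_m] <- "male_biased"
    }

    len_kb <- genes$exonic_length / 1e3
    samples <- list(); counts <- list()
    for (t in seq_len(nrow(plan))) {
      tis <- plan$tissue[t]
      regime <- if (is.na(plan$regime[t])) config$regime else plan$regime[t]
      sexes <- trimws(strsplit(plan$sexes[t], ",")[[1]])
      tissue_eff <- stats::rlnorm(g, 0, 0.2)
      for (sex in sexes) {
        x_factor <- 1
        if (sex == "M" && regime == "no_compensation") x_factor <- 0.5
        if (sex == "F" && regime == "female_downregulation") x_factor <- 0.5
        expr <- baseline * tissue_eff
        expr[on_x] <- expr[on_x] * x_factor
        if (sex == "F") expr[label == "female_biased"] <- expr[label == "female_biased"] * config$bias_fold
        if (sex == "M") expr[label == "male_biased"] <- expr[label == "male_biased"] * config$bias_fold
        for (r in seq_len(plan$n_replicates[t])) {
          lib <- config$libsize * stats::runif(1, 0.9, 1.1)
          mu <- expr * len_kb * lib / 1e6
          y <- if (config$dispersion > 0) {
            stats::rnbinom(g, mu = mu, size = 1 / config$dispersion)
          } else {
            stats::rpois(g, mu)
          }
          sid <- sprintf("%s_%s_rep%d", tis, sex, r)
          samples[[sid]] <- data.frame(sample_id = sid, tissue = tis, sex = sex,
                                       replicate = r, stringsAsFactors = FALSE)
          counts[[sid]] <- y
        }
      }
    }
    list(counts = do.call(cbind, counts), samples = do.call(rbind, samples),
         label = label, baseline = baseline)
  })

  counts <- sim$counts
  rownames(counts) <- genes$gene_id
  rownames(sim$samples) <- NULL
  gene_lengths <- stats::setNames(genes$exonic_length, genes$gene_id)
  structure(list(
    counts = counts,
    samples = sim$samples,
    truth = data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                       bias_label = sim$label, baseline_fpkm = sim$baseline,
                       stringsAsFactors = FALSE),
    gene_lengths = gene_lengths
  ), class = "sim_expression")
}

#' Write a complete fixture set to disk
#'
#' Emits the gene table (GFF3 and TSV), BED-like coverage TSV, count matrix
#' TSV, sample metadata TSV, truth-label TSV and a JSON manifest listing
#' every file with its row count.  All files round-trip losslessly through
#' the package readers.
#'
#' @param genome A `genome_model`.
#' @param coverage A `coverage_windows` data frame.
#' @param expr A `sim_expression` object.
#' @param out_dir Output directory (created if absent).
#' @return The manifest, invisibly, as a named list.
#' @export
write_fixture_set <- function(genome, coverage, expr, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir, call. = FALSE)
  paths <- list(
    genes_tsv = file.path(out_dir, "genes.tsv"),
    genes_gff3 = file.path(out_dir, "genes.gff3"),
    coverage = file.path(out_dir, "coverage.tsv"),
    counts = file.path(out_dir, "counts.tsv"),
    samples = file.path(out_dir, "samples.tsv"),
    truth = file.path(out_dir, "truth.tsv")
  )
  write_gene_table(genome$genes, paths$genes_tsv, dialect = "tsv")
  write_gene_table(genome$genes, paths$genes_gff3, dialect = "gff3",
                   chrom_lengths = stats::setNames(genome$chromosomes$length,
                                                   genome$chromosomes$name))
  write_coverage(coverage, paths$coverage)
  write_counts(expr$counts, expr$samples, paths$counts, paths$samples)
  utils::write.table(expr$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  rows <- list(genes_tsv = nrow(genome$genes), genes_gff3 = nrow(genome$genes),
               coverage = nrow(coverage), counts = nrow(expr$counts),
               samples = nrow(expr$samples), truth = nrow(expr$truth))
  manifest <- list(files = lapply(names(paths), function(k) {
    list(key = k, path = basename(paths[[k]]), rows = rows[[k]])
  }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
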