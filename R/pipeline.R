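# End-to-end orchestration: simulate -> sexchrom -> normalize -> dosage ->
# sexbias -> report, driven by a single (YAML-serialisable) configuration,
# with stage TSV artifacts and a combined JSON report assembled from them.

PIPELINE_STAGES <- c("simulate", "sexchrom", "normalize", "dosage",
                     "sexbias", "report")

#' @noRd
default_pipeline_config <- function() {
  list(
    out_dir = NULL,
    seed = 1L,
    paths = list(gene_table = NULL, coverage = NULL, counts = NULL,
                 metadata = NULL),
    simulate = list(n_autosomes = 14L, n_genes_per_chrom = 2000L,
                    gene_spacing = 6000, window_size = 1e5,
                    depth_female = 100, regime = "complete_compensation",
                    bias_fraction_female = 0.05, bias_fraction_male = 0.05,
                    bias_fold = 8, bias_female_on_x = 0, dispersion = 0.04,
                    libsize = 5e6,
                    tissues = list(list(tissue = "tissue1", sexes = "F,M",
                                        n_replicates = 2L, regime = NA))),
    sexchrom = list(min_depth = 5, normalize_libsize = TRUE,
                    x_band = c(0.35, 0.65), auto_band = c(0.8, 1.2),
                    min_windows = 5L),
    normalize = list(tmm = TRUE, filter_threshold = 1,
                     filter_rule = "both_below"),
    dosage = list(delta = 0.15, epsilon = 0.15, floor = 0.01),
    sexbias = list(bcv = 0.2, cpm_threshold = 1, lfc_threshold = 2,
                   fdr_threshold = 0.05, prior_count = 0.5, designs = list())
  )
}

#' @noRd
merge_config <- function(base, override, path = character(0)) {
  for (key in names(override)) {
    here <- c(path, key)
    if (!key %in% names(base))
      stop("unknown configuration key: ", paste(here, collapse = "."),
           call. = FALSE)
    if (is.list(base[[key]]) && is.list(override[[key]]) &&
        !key %in% c("tissues", "designs")) {
      base[[key]] <- merge_config(base[[key]], override[[key]], here)
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

#' Build (or load) a pipeline configuration
#'
#' Starts from the package defaults and overlays, in order, the contents of
#' a YAML file and any settings given directly; unknown keys are rejected
#' by name.  The configuration has one block per stage (`simulate`,
#' `sexchrom`, `normalize`, `dosage`, `sexbias`), a `paths` block for
#' external inputs (when `paths$counts` is set the simulate stage is
#' skipped), a global `seed` and an `out_dir`.
#'
#' @param yaml_path Optional YAML file with overrides.
#' @param ... Named overrides, e.g. `out_dir = "run1"`, `seed = 7`,
#'   `sexchrom = list(min_depth = 10)`.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(yaml_path = NULL, ...) {
  cfg <- default_pipeline_config()
  if (!is.null(yaml_path)) {
    if (!file.exists(yaml_path)) stop("config file not found: ", yaml_path, call. = FALSE)
    cfg <- merge_config(cfg, yaml::read_yaml(yaml_path))
  }
  dots <- list(...)
  if (length(dots) > 0) cfg <- merge_config(cfg, dots)
  if (is.null(cfg$out_dir)) stop("configuration requires `out_dir`", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

#' @noRd
log_line <- function(log_path, msg) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg)
  message(line)
  cat(line, "\n", file = log_path, append = TRUE, sep = "")
}

#' @noRd
sim_config_from <- function(cfg) {
  s <- cfg$simulate
  sim_config(n_autosomes = s$n_autosomes,
             n_genes_per_chrom = s$n_genes_per_chrom,
             gene_spacing = s$gene_spacing, window_size = s$window_size,
             depth_female = s$depth_female, regime = s$regime,
             bias_fraction_female = s$bias_fraction_female,
             bias_fraction_male = s$bias_fraction_male,
             bias_fold = s$bias_fold, bias_female_on_x = s$bias_female_on_x,
             dispersion = s$dispersion, libsize = s$libsize, seed = cfg$seed)
}

#' @noRd
plan_from <- function(cfg) {
  ts <- cfg$simulate$tissues
  do.call(rbind, lapply(ts, function(t) {
    tissue_plan(t$tissue, n_replicates = t$n_replicates %||% 2L,
                sexes = t$sexes %||% "F,M",
                regime = if (is.null(t$regime) || is.na(t$regime)) NA_character_
                         else t$regime)
  }))
}

#' Run the full dosage-compensation pipeline
#'
#' Executes the stages in order, writing each stage's tables under
#' `out_dir` and finally a combined `report.json` assembled from the
#' on-disk stage TSVs.  With `from_stage`, earlier stages are loaded from
#' their existing artifacts instead of recomputed, so downstream stages
#' can be re-run after a parameter change.
#'
#' Per-tissue test design is taken from `sexbias$designs`
#' (tissue -> "replicated"/"unreplicated") and otherwise auto-detected
#' from the replicate structure of the metadata.
#'
#' @param config A `pipeline_config`, or a path to a YAML config.
#' @param from_stage Optional stage name to resume from (one of simulate,
#'   sexchrom, normalize, dosage, sexbias, report).
#' @return Invisibly, the report list (also written as `report.json`).
#' @export
run_pipeline <- function(config, from_stage = NULL) {
  if (is.character(config)) config <- pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "run.log")
  start_at <- 1L
  if (!is.null(from_stage)) {
    if (!from_stage %in% PIPELINE_STAGES)
      stop("unknown stage: ", from_stage, "; expected one of ",
           paste(PIPELINE_STAGES, collapse = ", "), call. = FALSE)
    start_at <- match(from_stage, PIPELINE_STAGES)
  }
  log_line(log_path, sprintf("xodosage %s | seed %d | starting at stage '%s'",
                             as.character(utils::packageVersion("xodosage")),
                             config$seed, PIPELINE_STAGES[start_at]))

  paths <- config$paths
  simulated <- is.null(paths$counts)
  fix_dir <- file.path(out, "fixtures")

  ## stage 1: simulate (skipped when external inputs are provided)
  if (simulated) {
    if (start_at <= 1L) {
      scfg <- sim_config_from(config)
      genome <- simulate_genome(scfg)
      coverage <- simulate_dna_coverage(genome, scfg)
      expr_sim <- simulate_expression(genome, scfg, plan_from(config))
      write_fixture_set(genome, coverage, expr_sim, fix_dir)
      log_line(log_path, sprintf(
        "simulate: %d chromosomes, %d genes, %d windows, %d samples",
        nrow(genome$chromosomes), nrow(genome$genes), nrow(coverage),
        nrow(expr_sim$samples)))
    }
    paths <- list(gene_table = file.path(fix_dir, "genes.tsv"),
                  coverage = file.path(fix_dir, "coverage.tsv"),
                  counts = file.path(fix_dir, "counts.tsv"),
                  metadata = file.path(fix_dir, "samples.tsv"))
  }
  for (p in c("gene_table", "coverage", "counts", "metadata")) {
    if (is.null(paths[[p]]) || !file.exists(paths[[p]]))
      stop("input file for `", p, "` not found: ",
           paths[[p]] %||% "<unset>", call. = FALSE)
  }
  gene_table <- read_gene_table(paths$gene_table)

  ## stage 2: X-chromosome identification
  classes_path <- file.path(out, "chrom_classes.tsv")
  if (start_at <= 2L) {
    sc <- config$sexchrom
    track <- compute_window_ratios(read_coverage(paths$coverage),
                                   min_depth = sc$min_depth,
                                   normalize_libsize = sc$normalize_libsize)
    track <- loess_smooth(track)
    classes <- classify_chromosomes(track, x_band = unlist(sc$x_band),
                                    auto_band = unlist(sc$auto_band),
                                    min_windows = sc$min_windows)
    utils::write.table(track, file.path(out, "window_ratios.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(classes, classes_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    log_line(log_path, sprintf(
      "sexchrom: %d windows retained (%d dropped); labels: %s",
      nrow(track), attr(track, "n_dropped"),
      paste(sprintf("%s=%d", names(table(classes$label)),
                    as.integer(table(classes$label))), collapse = ", ")))
  } else {
    classes <- utils::read.delim(classes_path, stringsAsFactors = FALSE)
  }

  ## stage 3: normalisation and per-tissue expression
  cm <- read_counts(paths$counts, paths$metadata)
  gene_lengths <- stats::setNames(gene_table$exonic_length, gene_table$gene_id)
  tissue_files <- function(tis) file.path(out, sprintf("tissue_%s.tsv", tis))
  if (start_at <= 3L) {
    nz <- config$normalize
    expr <- compute_fpkm(cm, gene_lengths, tmm = nz$tmm)
    tes <- average_replicates(expr, gene_table)
    tes <- lapply(tes, filter_expressed, threshold = nz$filter_threshold,
                  rule = nz$filter_rule)
    utils::write.table(
      data.frame(sample_id = names(expr$tmm_factors),
                 tmm_factor = expr$tmm_factors,
                 eff_libsize = expr$eff_libsize, row.names = NULL),
      file.path(out, "tmm_factors.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    qc <- suppressWarnings(spearman_replicates(cm))
    utils::write.table(qc, file.path(out, "spearman_replicates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (tis in names(tes)) {
      utils::write.table(tes[[tis]], tissue_files(tis), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    log_line(log_path, sprintf(
      "normalize: %d genes x %d samples; tissues with both sexes: %s; retained per tissue: %s",
      nrow(expr$fpkm), ncol(expr$fpkm), paste(names(tes), collapse = ", "),
      paste(vapply(tes, function(t) sum(t$retained), 1L), collapse = ", ")))
  } else {
    tissues <- unique(cm$samples$tissue)
    tes <- list()
    for (tis in tissues) {
      f <- tissue_files(tis)
      if (file.exists(f)) {
        te <- utils::read.delim(f, stringsAsFactors = FALSE)
        attr(te, "tissue") <- tis
        class(te) <- c("tissue_expression", "data.frame")
        tes[[tis]] <- te
      }
    }
  }

  ## stage 4: dosage statistics
  dosage_path <- file.path(out, "dosage_report.tsv")
  if (start_at <= 4L) {
    dz <- config$dosage
    dreport <- dosage_report(tes, classes, delta = dz$delta,
                             epsilon = dz$epsilon, floor = dz$floor)
    utils::write.table(dreport, dosage_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    log_line(log_path, sprintf(
      "dosage: %s", paste(sprintf("%s=%s", dreport$tissue, dreport$status),
                          collapse = ", ")))
  }

  ## stage 5: sex-biased genes and enrichment
  if (start_at <= 5L) {
    sb <- config$sexbias
    enr_rows <- list(); summary_rows <- list()
    for (tis in names(tes)) {
      meta_t <- cm$samples[cm$samples$tissue == tis, , drop = FALSE]
      if (!all(c("F", "M") %in% meta_t$sex)) next
      reps <- tapply(meta_t$replicate, meta_t$sex, length)
      design <- sb$designs[[tis]] %||%
        if (all(reps >= 2)) "replicated" else "unreplicated"
      res <- sex_bias_analysis(cm$counts[, meta_t$sample_id, drop = FALSE],
                               meta_t, gene_table, classes, design = design,
                               bcv = sb$bcv, cpm_threshold = sb$cpm_threshold,
                               lfc_threshold = sb$lfc_threshold,
                               fdr_threshold = sb$fdr_threshold,
                               prior_count = sb$prior_count)
      utils::write.table(res$bias_table,
                         file.path(out, sprintf("bias_%s.tsv", tis)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      for (dir in c("female", "male")) {
        e <- res$enrichment[[dir]]
        enr_rows[[paste(tis, dir)]] <- data.frame(
          tissue = tis, direction = dir,
          biased_x = e$table[1, 1], biased_auto = e$table[1, 2],
          unbiased_x = e$table[2, 1], unbiased_auto = e$table[2, 2],
          odds_ratio = e$odds_ratio, p = e$p.value,
          enriched_on = e$enriched_on %||% NA_character_,
          stringsAsFactors = FALSE)
      }
      lab <- table(factor(res$bias_table$label,
                          levels = c("female_biased", "male_biased",
                                     "unbiased", "filtered")))
      summary_rows[[tis]] <- data.frame(
        tissue = tis, design = design, n_retained = res$n_retained,
        n_female_biased = as.integer(lab["female_biased"]),
        n_male_biased = as.integer(lab["male_biased"]),
        n_unbiased = as.integer(lab["unbiased"]),
        n_filtered = as.integer(lab["filtered"]), stringsAsFactors = FALSE)
      log_line(log_path, sprintf(
        "sexbias[%s, %s]: %d retained, %d female-biased, %d male-biased",
        tis, design, res$n_retained, lab["female_biased"], lab["male_biased"]))
    }
    utils::write.table(do.call(rbind, enr_rows), file.path(out, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(do.call(rbind, summary_rows),
                       file.path(out, "bias_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## stage 6: combined report, assembled from the stage TSVs on disk
  read_tsv0 <- function(p) if (file.exists(p))
    utils::read.delim(p, stringsAsFactors = FALSE) else NULL
  dreport_disk <- read_tsv0(dosage_path)
  report <- list(
    schema = 1L,
    seed = config$seed,
    inputs = lapply(paths, basename),
    chromosome_classes = read_tsv0(classes_path),
    tissues = if (is.null(dreport_disk)) character(0) else dreport_disk$tissue,
    dosage = dreport_disk,
    bias_summary = read_tsv0(file.path(out, "bias_summary.tsv")),
    enrichment = read_tsv0(file.path(out, "enrichment.tsv"))
  )
  write_report(report, out)
  log_line(log_path, "report: written report.json")
  invisible(report)
}

#' Generate a ready-to-run demo dataset and configuration
#'
#' Simulates a compact XX/XO experiment mirroring the qualitative pattern
#' the package targets: two somatic tissues (single replicate per sex)
#' under complete compensation and one gonad tissue (two replicates per
#' sex) lacking compensation, with 30% of female-biased genes placed on
#' the X.  The sex-biased fraction is kept small (2% per direction) so the
#' X-enrichment signal is present without distorting the F:M-on-X median
#' that drives the dosage call.  Fixtures are written under
#' `out_dir/fixtures` next to a `demo.yaml` configuration consuming them.
#'
#' @param out_dir Output directory.
#' @param seed Simulation seed (default 7).
#' @return Path of the YAML config, invisibly.
#' @export
make_demo <- function(out_dir, seed = 7L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scfg <- sim_config(n_genes_per_chrom = 300L, libsize = 1e6,
                     bias_fraction_female = 0.02, bias_fraction_male = 0.02,
                     bias_female_on_x = 0.3, seed = seed)
  plan <- tissue_plan(c("head", "leg", "gonad"),
                      n_replicates = c(1L, 1L, 2L),
                      regime = c("complete_compensation",
                                 "complete_compensation", "no_compensation"))
  genome <- simulate_genome(scfg)
  coverage <- simulate_dna_coverage(genome, scfg)
  expr <- simulate_expression(genome, scfg, plan)
  fix_dir <- file.path(out_dir, "fixtures")
  write_fixture_set(genome, coverage, expr, fix_dir)
  cfg <- list(out_dir = file.path(out_dir, "results"), seed = as.integer(seed),
              paths = list(gene_table = file.path(fix_dir, "genes.tsv"),
                           coverage = file.path(fix_dir, "coverage.tsv"),
                           counts = file.path(fix_dir, "counts.tsv"),
                           metadata = file.path(fix_dir, "samples.tsv")))
  cfg_path <- file.path(out_dir, "demo.yaml")
  yaml::write_yaml(cfg, cfg_path)
  invisible(cfg_path)
}
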