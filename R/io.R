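# Readers and writers for gene tables (GFF3/TSV), BED-like coverage,
# count matrices with sample metadata, and the JSON/TSV result bundle.
# Gene tables are 1-based inclusive (GFF3 convention); coverage windows are
# 0-based half-open (BED convention); conversion happens only here.

#' @noRd
read_tsv_strict <- function(path, required, colClasses = NA) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = colClasses)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop(sprintf("%s: missing required column(s): %s", basename(path),
                 paste(missing, collapse = ", ")), call. = FALSE)
  df
}

#' @noRd
validate_gene_table <- function(genes) {
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup) > 0)
    stop("duplicate gene ID(s): ", paste(unique(dup), collapse = ", "), call. = FALSE)
  if (any(genes$start < 1) || any(genes$end < genes$start))
    stop("gene spans must satisfy 1 <= start <= end", call. = FALSE)
  if (any(genes$exonic_length < 1))
    stop("exonic_length must be >= 1", call. = FALSE)
  genes[, c("gene_id", "chrom", "start", "end", "exonic_length")]
}

#' Read a gene table from GFF3 or flat TSV
#'
#' The TSV dialect expects columns gene_id, chrom, start, end,
#' exonic_length.  The GFF3 dialect takes `type == "gene"` features keyed by
#' their `ID` attribute and sums exon features (matched through `Parent`)
#' into the exonic length; genes without exon features fall back to the span
#' length with a warning.  Coordinates are 1-based inclusive throughout.
#'
#' @param path File path.
#' @param dialect `"auto"` (by extension), `"tsv"` or `"gff3"`.
#' @return A data frame: gene_id, chrom, start, end, exonic_length.
#' @export
read_gene_table <- function(path, dialect = c("auto", "tsv", "gff3")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  }
  if (dialect == "tsv") {
    df <- read_tsv_strict(path, c("gene_id", "chrom", "start", "end", "exonic_length"))
    df$start <- as.integer(df$start); df$end <- as.integer(df$end)
    df$exonic_length <- as.integer(df$exonic_length)
    return(validate_gene_table(df))
  }
  # Structural pre-check so malformed lines are reported with their number;
  # parsing itself is delegated to rtracklayer.
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9))
    stop(sprintf("malformed GFF3 line %d: expected 9 tab-separated fields, found %d",
                 body[which(nf != 9)[1]], nf[nf != 9][1]), call. = FALSE)
  gff <- rtracklayer::readGFF(path)
  gff <- as.data.frame(gff, stringsAsFactors = FALSE)
  genes <- gff[gff$type == "gene", , drop = FALSE]
  if (nrow(genes) == 0) stop("no `gene` features in ", path, call. = FALSE)
  ids <- as.character(genes$ID)
  if (anyNA(ids) || any(!nzchar(ids)))
    stop("GFF3 gene feature without an ID attribute", call. = FALSE)
  exonic <- stats::setNames(rep(NA_real_, nrow(genes)), ids)
  exons <- gff[gff$type == "exon", , drop = FALSE]
  if (nrow(exons) > 0) {
    parent <- vapply(exons$Parent, function(p) as.character(p)[1], character(1))
    len <- exons$end - exons$start + 1
    agg <- tapply(len, parent, sum)
    exonic[names(agg)[names(agg) %in% ids]] <- agg[names(agg) %in% ids]
  }
  span <- genes$end - genes$start + 1
  no_exon <- is.na(exonic)
  if (any(no_exon)) {
    warning(sum(no_exon), " gene(s) without exon features; using span length",
            call. = FALSE)
    exonic[no_exon] <- span[no_exon]
  }
  validate_gene_table(data.frame(
    gene_id = ids, chrom = as.character(genes$seqid),
    start = as.integer(genes$start), end = as.integer(genes$end),
    exonic_length = as.integer(exonic), stringsAsFactors = FALSE))
}

#' Write a gene table as TSV or GFF3
#'
#' The GFF3 dialect writes one `gene` feature per row plus a single `exon`
#' child of the recorded exonic length, so exonic lengths survive a
#' round-trip through [read_gene_table()].
#'
#' @param genes Gene table data frame.
#' @param path Output path.
#' @param dialect `"tsv"` or `"gff3"`.
#' @param chrom_lengths Optional named vector for `##sequence-region` headers.
#' @export
write_gene_table <- function(genes, path, dialect = c("tsv", "gff3"),
                             chrom_lengths = NULL) {
  dialect <- match.arg(dialect)
  genes <- validate_gene_table(genes)
  if (dialect == "tsv") {
    utils::write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  hdr <- "##gff-version 3"
  if (!is.null(chrom_lengths)) {
    hdr <- c(hdr, sprintf("##sequence-region %s 1 %d", names(chrom_lengths),
                          as.integer(chrom_lengths)))
  }
  gene_lines <- sprintf("%s\txodosage\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                        genes$chrom, genes$start, genes$end, genes$gene_id)
  exon_lines <- sprintf("%s\txodosage\texon\t%d\t%d\t.\t+\t.\tID=%s.exon1;Parent=%s",
                        genes$chrom, genes$start,
                        genes$start + genes$exonic_length - 1L,
                        genes$gene_id, genes$gene_id)
  body <- as.vector(rbind(gene_lines, exon_lines))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @noRd
validate_coverage <- function(cov) {
  need <- c("chrom", "start", "end", "depth_male", "depth_female")
  missing <- setdiff(need, names(cov))
  if (length(missing) > 0)
    stop("coverage table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  cov <- cov[, need]
  if (any(cov$start >= cov$end))
    stop("coverage windows must satisfy start < end (0-based half-open)",
         call. = FALSE)
  if (any(cov$depth_male < 0) || any(cov$depth_female < 0))
    stop("window depths must be >= 0", call. = FALSE)
  cov <- cov[order(cov$chrom, cov$start), , drop = FALSE]
  by_chrom <- split(cov, cov$chrom)
  for (b in by_chrom) {
    if (nrow(b) > 1 && any(b$start[-1] < b$end[-nrow(b)]))
      stop("overlapping coverage windows on ", b$chrom[1], call. = FALSE)
  }
  rownames(cov) <- NULL
  class(cov) <- c("coverage_windows", "data.frame")
  cov
}

#' Read a BED-like male/female coverage table
#'
#' Five tab-separated columns: chrom, start (0-based), end (exclusive),
#' depth_male, depth_female.  Windows are sorted and validated; overlaps,
#' empty windows and negative depths are rejected.  Depths may be
#' fractional (mean depth per window).
#'
#' @param path File path.
#' @return A `coverage_windows` data frame.
#' @export
read_coverage <- function(path) {
  df <- read_tsv_strict(path, c("chrom", "start", "end", "depth_male", "depth_female"))
  df$start <- as.numeric(df$start); df$end <- as.numeric(df$end)
  df$depth_male <- as.numeric(df$depth_male)
  df$depth_female <- as.numeric(df$depth_female)
  validate_coverage(df)
}

#' Write a coverage table
#' @param cov A `coverage_windows` data frame.
#' @param path Output path.
#' @export
write_coverage <- function(cov, path) {
  cov <- validate_coverage(cov)
  utils::write.table(cov, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a raw count matrix with its sample metadata
#'
#' The matrix TSV has a `gene_id` column followed by one integer column per
#' sample; metadata has columns sample_id, tissue, sex (F/M), replicate.
#' Non-integer counts and matrix columns without metadata are errors; extra
#' metadata rows are dropped with a warning.
#'
#' @param path Count matrix TSV.
#' @param metadata_path Sample metadata TSV.
#' @return A `count_matrix`: list with integer `counts` (genes x samples)
#'   and `samples` metadata aligned to the columns.
#' @export
read_counts <- function(path, metadata_path) {
  df <- read_tsv_strict(path, "gene_id")
  # metadata read as character: a sex column holding only "F" would
  # otherwise be parsed as logical FALSE
  meta <- read_tsv_strict(metadata_path,
                          c("sample_id", "tissue", "sex", "replicate"),
                          colClasses = "character")
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in metadata", call. = FALSE)
  if (!all(meta$sex %in% c("F", "M")))
    stop("metadata sex must be 'F' or 'M'", call. = FALSE)
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene ID(s): ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "),
         call. = FALSE)
  sample_cols <- setdiff(names(df), "gene_id")
  no_meta <- setdiff(sample_cols, meta$sample_id)
  if (length(no_meta) > 0)
    stop("count column(s) without metadata: ", paste(no_meta, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(meta$sample_id, sample_cols)
  if (length(extra) > 0) {
    warning("metadata sample(s) absent from count matrix, ignored: ",
            paste(extra, collapse = ", "), call. = FALSE)
    meta <- meta[meta$sample_id %in% sample_cols, , drop = FALSE]
  }
  m <- as.matrix(df[, sample_cols, drop = FALSE])
  if (nrow(m) == 0) storage.mode(m) <- "integer"
  if (!is.numeric(m)) stop("count matrix contains non-numeric values", call. = FALSE)
  bad <- which(m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-integer or negative count at gene '%s', sample '%s': %s",
                 df$gene_id[bad[1, 1]], sample_cols[bad[1, 2]],
                 format(m[bad[1, , drop = FALSE]])), call. = FALSE)
  storage.mode(m) <- "integer"
  rownames(m) <- df$gene_id
  meta <- meta[match(sample_cols, meta$sample_id), , drop = FALSE]
  meta$replicate <- as.integer(meta$replicate)
  rownames(meta) <- NULL
  structure(list(counts = m, samples = meta), class = "count_matrix")
}

#' Write a count matrix and its sample metadata
#' @param counts Integer matrix, genes x samples, with dimnames.
#' @param samples Sample metadata data frame.
#' @param path,metadata_path Output paths.
#' @export
write_counts <- function(counts, samples, path, metadata_path) {
  df <- data.frame(gene_id = rownames(counts) %||% character(nrow(counts)),
                   counts, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(samples[, c("sample_id", "tissue", "sex", "replicate")],
                     metadata_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the combined result bundle
#'
#' Serialises the report list to `report.json` (stable key order, full
#' numeric precision, so identical inputs give byte-identical output) and
#' writes each data-frame component as a TSV alongside it.
#'
#' @param report A named list; data-frame elements become `<name>.tsv`.
#' @param out_dir Output directory (created if absent).
#' @return Path of the JSON file, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report)) {
    if (is.data.frame(report[[nm]])) {
      utils::write.table(report[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  json_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", dataframe = "rows")
  invisible(json_path)
}
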