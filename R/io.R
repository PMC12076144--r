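#' Read and write site count matrices as tab-separated text
#'
#' On-disk layout: a header line `chrom  pos  <sample...>`, one row per site.
#' Validation is strict: duplicated sites, negative or non-integer counts and
#' empty sample sets are rejected with a message naming the first offending
#' record. Write-then-read is lossless.
#'
#' @param x a [site_count_matrix()].
#' @param path file path.
#' @return `read_count_matrix` returns a `site_count_matrix`;
#'   `write_count_matrix` returns `path` invisibly.
#' @export
write_count_matrix <- function(x, path) {
  stopifnot(inherits(x, "site_count_matrix"))
  df <- cbind(x$sites, as.data.frame(x$counts, check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  if (!file.exists(path)) stop_msg("no such file: %s", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("chrom", "pos") %in% names(df)))
    stop_msg("count matrix header must start with 'chrom' and 'pos'")
  sample_cols <- setdiff(names(df), c("chrom", "pos"))
  if (!length(sample_cols)) stop_msg("no samples in %s", path)
  key <- site_key(df$chrom, df$pos)
  if (anyDuplicated(key)) stop_msg("duplicate site %s in %s", key[duplicated(key)][1], path)
  counts <- as.matrix(df[, sample_cols, drop = FALSE])
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    bad <- which(is.na(counts) | counts < 0 | counts != round(counts), arr.ind = TRUE)[1, ]
    stop_msg("invalid count at %s, sample %s", key[bad[1]], sample_cols[bad[2]])
  }
  site_count_matrix(df[, c("chrom", "pos")], counts)
}

#' Read and write sample sheets
#'
#' A sample sheet is tab-separated with columns `sample_id`, `group` (e.g.
#' `cfDNA_t1`, `cfDNA_nonpregnant`, `placenta_term`, `buffy`), `tissue` and
#' `ga_days` (gestational age in days; empty/NA for non-pregnant donors).
#'
#' @param sheet data frame with the columns above.
#' @param path file path.
#' @return `read_sample_sheet` returns the validated data frame;
#'   `write_sample_sheet` returns `path` invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  validate_sample_sheet(sheet)
  write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop_msg("no such file: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  validate_sample_sheet(df)
}

validate_sample_sheet <- function(sheet) {
  need <- c("sample_id", "group", "tissue", "ga_days")
  missing_cols <- setdiff(need, names(sheet))
  if (length(missing_cols))
    stop_msg("sample sheet lacks column(s): %s", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    stop_msg("duplicate sample id '%s'", sheet$sample_id[duplicated(sheet$sample_id)][1])
  if (any(!is.na(sheet$ga_days) & sheet$ga_days < 0))
    stop_msg("gestational age must be >= 0 days")
  sheet
}

#' Check that a count matrix and sample sheet describe the same samples
#' @param counts a `site_count_matrix`.
#' @param sheet a sample sheet data frame.
#' @return invisibly TRUE; errors name the first mismatched sample.
#' @export
validate_samples <- function(counts, sheet) {
  missing_s <- setdiff(sample_ids(counts), sheet$sample_id)
  if (length(missing_s)) stop_msg("sample '%s' in counts but not in sheet", missing_s[1])
  invisible(TRUE)
}

#' Read and write DMR tables as BED6+
#'
#' Columns 1-6 follow BED (0-based half-open, score = -log10 adjusted p capped
#' at 1000, strand "."); extra columns carry `direction`, `fold_change`,
#' `n_sites`, `p_adjusted` and the comma-joined `annotation` labels, making the
#' round trip lossless for those fields.
#'
#' @param dmrs a DMR data frame as returned by [call_dmrs()].
#' @param path file path.
#' @return `read_dmr_bed` returns the DMR data frame; `write_dmr_bed` returns
#'   `path` invisibly.
#' @export
write_dmr_bed <- function(dmrs, path) {
  if (anyDuplicated(dmrs$id)) stop_msg("duplicate DMR id '%s'", dmrs$id[duplicated(dmrs$id)][1])
  score <- pmin(1000, -log10(dmrs$p_adjusted))
  score[!is.finite(score)] <- 1000
  ann <- dmrs$annotation %||% rep(NA_character_, nrow(dmrs))
  ann[is.na(ann) | ann == ""] <- "."
  bed <- data.frame(chrom = dmrs$chrom, start = dmrs$start, end = dmrs$end,
                    name = dmrs$id, score = round(score, 4), strand = ".",
                    direction = dmrs$direction, fold_change = dmrs$fold_change,
                    n_sites = dmrs$n_sites, p_adjusted = dmrs$p_adjusted,
                    annotation = ann, stringsAsFactors = FALSE)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_dmr_bed
#' @export
read_dmr_bed <- function(path) {
  if (!file.exists(path)) stop_msg("no such file: %s", path)
  cols <- c("chrom", "start", "end", "id", "score", "strand",
            "direction", "fold_change", "n_sites", "p_adjusted", "annotation")
  df <- read.delim(path, header = FALSE, col.names = cols, stringsAsFactors = FALSE)
  if (anyDuplicated(df$id)) stop_msg("duplicate DMR id '%s'", df$id[duplicated(df$id)][1])
  df$annotation[df$annotation == "."] <- ""
  df[, c("id", "chrom", "start", "end", "n_sites", "direction",
         "fold_change", "p_adjusted", "annotation")]
}

#' Read and write the toy genome annotation
#'
#' Genes go to a 6-column tab-separated table (`name`, `chrom`, `tss`, `tes`,
#' `strand`, `length`); CpG islands to BED3. All coordinates 0-based half-open.
#'
#' @param annotation an `annotation_set` (or `toy_genome`, whose genes/islands
#'   are used).
#' @param genes_path,islands_path file paths.
#' @return `read_annotation` returns an `annotation_set`: list with `genes` and
#'   `cpg_islands`.
#' @export
write_annotation <- function(annotation, genes_path, islands_path) {
  genes <- annotation$genes
  isl <- annotation$cpg_islands
  gdf <- data.frame(name = genes$name, chrom = genes$chrom, tss = genes$tss,
                    tes = genes$tes, strand = genes$strand,
                    length = abs(genes$tes - genes$tss), stringsAsFactors = FALSE)
  write.table(gdf, genes_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(isl[, c("chrom", "start", "end")], islands_path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(genes_path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(genes_path, islands_path) {
  genes <- read.delim(genes_path, stringsAsFactors = FALSE)
  isl <- read.delim(islands_path, header = FALSE,
                    col.names = c("chrom", "start", "end"), stringsAsFactors = FALSE)
  annotation_set(genes[, c("name", "chrom", "tss", "tes", "strand")], isl)
}

#' Construct a validated annotation set
#' @param genes data frame: `name`, `chrom`, `tss`, `tes`, `strand`.
#' @param cpg_islands data frame: `chrom`, `start`, `end` (half-open).
#' @return object of class `annotation_set`.
#' @export
annotation_set <- function(genes, cpg_islands) {
  if (nrow(genes) && !all(genes$strand %in% c("+", "-")))
    stop_msg("gene strand must be '+' or '-'")
  if (nrow(cpg_islands) && any(cpg_islands$start >= cpg_islands$end))
    stop_msg("CpG island intervals must satisfy start < end")
  structure(list(genes = genes, cpg_islands = cpg_islands), class = "annotation_set")
}

#' Save and load the synthetic ground truth sidecar (JSON)
#'
#' @param truth a `synthetic_truth` object.
#' @param path file path (JSON).
#' @return `read_truth` returns the `synthetic_truth`; `write_truth` returns
#'   `path` invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  obj <- unclass(truth)
  if (!is.null(obj$placental_fractions))
    obj$placental_fractions <- as.list(obj$placental_fractions)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pf <- obj$placental_fractions
  structure(list(
    planted_dmrs = as.data.frame(obj$planted_dmrs),
    placental_fractions = if (is.null(pf)) NULL else unlist(pf),
    seed = obj$seed), class = "synthetic_truth")
}
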