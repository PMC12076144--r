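#' Site-by-sample count matrix container
#'
#' The pipeline's primary substrate: non-negative integer read counts at
#' genomic enzyme/CpG sites (rows) for a set of samples (columns). Sites are
#' kept sorted by (chrom, pos); library sizes are the column totals.
#'
#' @param sites data frame with columns `chrom`, `pos` (0-based site
#'   coordinates); no duplicates allowed.
#' @param counts integer matrix, `nrow(sites)` x n_samples, with sample ids as
#'   column names.
#' @return object of class `site_count_matrix`: list with `sites`, `counts`
#'   (rownames `chrom:pos`) and `lib_sizes` (named column totals).
#' @export
site_count_matrix <- function(sites, counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(colnames(counts)) || ncol(counts) == 0)
    stop_msg("no samples: count matrix needs named sample columns")
  if (nrow(sites) != nrow(counts))
    stop_msg("sites (%d) and count rows (%d) disagree", nrow(sites), nrow(counts))
  if (anyDuplicated(colnames(counts))) stop_msg("duplicate sample ids")
  key <- site_key(sites$chrom, sites$pos)
  if (anyDuplicated(key))
    stop_msg("duplicate site %s", key[duplicated(key)][1])
  if (any(is.na(counts)) || any(counts < 0))
    stop_msg("counts must be non-negative and complete")
  if (any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1, ]
    stop_msg("non-integer count at row %d, sample %s", bad[1], colnames(counts)[bad[2]])
  }
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, c("chrom", "pos"), drop = FALSE]
  rownames(sites) <- NULL
  counts <- counts[ord, , drop = FALSE]
  storage.mode(counts) <- "integer"
  rownames(counts) <- site_key(sites$chrom, sites$pos)
  structure(list(sites = sites, counts = counts, lib_sizes = colSums(counts)),
            class = "site_count_matrix")
}

#' @export
print.site_count_matrix <- function(x, ...) {
  cat(sprintf("site_count_matrix: %d sites x %d samples (median library %.0f)\n",
              nrow(x$counts), ncol(x$counts), stats::median(x$lib_sizes)))
  invisible(x)
}

#' @export
dim.site_count_matrix <- function(x) dim(x$counts)

#' Sample ids of a count matrix
#' @param x a `site_count_matrix`.
#' @return character vector of sample ids.
#' @export
sample_ids <- function(x) colnames(x$counts)
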