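#' Reads-per-million normalization
#'
#' Divides each sample's site counts by its library size (column total) and
#' scales to one million, so per-sample coverage differences cancel. Columns of
#' the result sum to 1e6 exactly (up to floating-point error).
#'
#' @param counts a [site_count_matrix()].
#' @return object of class `rpm_matrix`: list with `sites`, `rpm` (numeric
#'   matrix) and `lib_sizes`.
#' @examples
#' scm <- site_count_matrix(data.frame(chrom = "chr1", pos = c(10, 20, 30)),
#'                          matrix(c(10L, 30L, 60L), 3, 1,
#'                                 dimnames = list(NULL, "s1")))
#' normalize_rpm(scm)$rpm[, 1]  # 1e5, 3e5, 6e5
#' @export
normalize_rpm <- function(counts) {
  stopifnot(inherits(counts, "site_count_matrix"))
  zero <- counts$lib_sizes == 0
  if (any(zero))
    stop_msg("sample '%s' has zero total count; cannot normalize", names(which(zero))[1])
  rpm <- sweep(counts$counts, 2, counts$lib_sizes, "/") * 1e6
  structure(list(sites = counts$sites, rpm = rpm, lib_sizes = counts$lib_sizes),
            class = "rpm_matrix")
}

# Pearson chi-squared for 2x2 tables [[a, n1 - a], [b, n2 - b]], vectorized
# over sites; 1 df, no continuity correction
pearson_chi2 <- function(a, n1, b, n2) {
  a <- as.numeric(a); n1 <- as.numeric(n1)
  b <- as.numeric(b); n2 <- as.numeric(n2)
  x12 <- n1 - a
  x22 <- n2 - b
  num <- (n1 + n2) * (a * x22 - x12 * b)^2
  den <- n1 * n2 * (a + b) * (x12 + x22)
  stat <- ifelse(den > 0, num / den, 0)
  list(stat = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Per-site chi-squared test between two pooled sample groups
#'
#' Counts are summed across the samples of each group; the 2x2 table
#' `[[a, N1 - a], [b, N2 - b]]` (site count vs rest of the pooled library)
#' is tested with the Pearson chi-squared statistic, 1 degree of freedom, no
#' continuity correction. Direction is the sign of the pooled RPM difference
#' (group 1 minus group 2). Sites with zero pooled count in both groups are
#' flagged untestable and carry no hypothesis (they are excluded from the
#' Bonferroni denominator by [call_dmrs()]).
#'
#' @param counts a [site_count_matrix()].
#' @param group1,group2 character vectors of sample ids.
#' @param site site row index, or a `"chrom:pos"` key.
#' @param n_tests Bonferroni denominator used for the adjusted p (default 1).
#' @return list with `site`, `a`, `b`, `n1`, `n2`, `stat`, `p`, `p_adjusted`,
#'   `direction` (+1/-1/0) and `testable`.
#' @export
site_chi_squared <- function(counts, group1, group2, site, n_tests = 1L) {
  stopifnot(inherits(counts, "site_count_matrix"))
  if (is.character(site)) site <- match(site, rownames(counts$counts))
  if (is.na(site) || site < 1 || site > nrow(counts$counts))
    stop_msg("site not found on the grid")
  if (!length(group1) || !length(group2)) stop_msg("both groups must be non-empty")
  missing_s <- setdiff(c(group1, group2), sample_ids(counts))
  if (length(missing_s)) stop_msg("unknown sample '%s'", missing_s[1])
  a <- sum(counts$counts[site, group1])
  b <- sum(counts$counts[site, group2])
  n1 <- sum(counts$lib_sizes[group1])
  n2 <- sum(counts$lib_sizes[group2])
  if (n1 == 0 || n2 == 0) stop_msg("a group has zero pooled library size")
  testable <- (a + b) > 0
  cs <- pearson_chi2(a, n1, b, n2)
  list(site = rownames(counts$counts)[site], a = a, b = b, n1 = n1, n2 = n2,
       stat = if (testable) cs$stat else NA_real_,
       p = if (testable) cs$p else NA_real_,
       p_adjusted = if (testable) min(1, cs$p * n_tests) else NA_real_,
       direction = sign(a / n1 - b / n2), testable = testable)
}

#' Call differentially methylated regions between two sample groups
#'
#' The genome-wide sliding window is realized as per-site testing followed by
#' run-merging: every testable site is compared between the pooled groups with
#' the Pearson chi-squared test ([site_chi_squared()]), p-values are
#' Bonferroni-corrected over the testable sites, sites with adjusted p <=
#' `alpha` are marked, and maximal runs of marked sites that are consecutive on
#' the site grid (up to `max_gap_sites - 1` intervening unmarked sites) and
#' share a direction are merged into candidate regions. A region is reported
#' when it has at least `min_sites` member sites and its fold change — the
#' ratio of the two group means of per-sample region RPM, larger over smaller —
#' reaches `fc_min`. When one group mean is zero, half the smallest nonzero
#' per-sample region value is used as a pseudo-value to avoid division by zero.
#'
#' @param counts a [site_count_matrix()].
#' @param sheet a sample sheet (see [read_sample_sheet()]).
#' @param group1,group2 group labels resolved against `sheet$group`.
#' @param alpha Bonferroni-adjusted significance level (adjusted p equal to
#'   `alpha` counts as significant).
#' @param fc_min minimal region fold change (>= 1).
#' @param min_sites minimal number of member sites per region.
#' @param max_gap_sites run-merging gap: a marked site extends the current run
#'   when it is at most this many grid steps after the previous member
#'   (1 = strictly consecutive).
#' @param autosomal_only drop regions on `sex_chroms`.
#' @param sex_chroms chromosome names treated as non-autosomal.
#' @return data frame of class `dmr_table`, one row per DMR, sorted by
#'   coordinate: `id`, `chrom`, `start`, `end` (half-open, last site + 1),
#'   `n_sites`, `direction` (`"hyper"` = higher in `group1`), `mean_rpm_1`,
#'   `mean_rpm_2`, `fold_change`, `p_adjusted` (minimum over member sites),
#'   `annotation` (empty until [annotate_dmrs()]), `autosomal`. Attributes
#'   `n_tested`, `n_significant`, `groups`.
#' @export
call_dmrs <- function(counts, sheet, group1, group2, alpha = 0.05, fc_min = 2,
                      min_sites = 2L, max_gap_sites = 1L,
                      autosomal_only = FALSE,
                      sex_chroms = c("chrX", "chrY", "X", "Y")) {
  stopifnot(inherits(counts, "site_count_matrix"))
  g1 <- intersect(sheet$sample_id[sheet$group == group1], sample_ids(counts))
  g2 <- intersect(sheet$sample_id[sheet$group == group2], sample_ids(counts))
  if (!length(g1)) stop_msg("group '%s' resolves to no samples", group1)
  if (!length(g2)) stop_msg("group '%s' resolves to no samples", group2)

  a <- rowSums(counts$counts[, g1, drop = FALSE])
  b <- rowSums(counts$counts[, g2, drop = FALSE])
  n1 <- sum(counts$lib_sizes[g1])
  n2 <- sum(counts$lib_sizes[g2])
  if (n1 == 0 || n2 == 0)
    stop_msg("group '%s' has zero pooled library size", if (n1 == 0) group1 else group2)

  testable <- (a + b) > 0
  m <- sum(testable)
  cs <- pearson_chi2(a, n1, b, n2)
  p_adj <- pmin(1, cs$p * m)
  dir <- sign(a / n1 - b / n2)
  sig <- testable & p_adj <= alpha & dir != 0

  norm <- normalize_rpm(counts)
  sites <- counts$sites
  regions <- list()
  for (cn in unique(sites$chrom)) {
    idx <- which(sites$chrom == cn)
    runs <- merge_runs(sig[idx], dir[idx], max_gap_sites)
    for (r in runs) {
      member <- idx[r]
      if (length(member) < min_sites) next
      start <- sites$pos[member[1]]
      end <- sites$pos[member[length(member)]] + 1L
      vals <- colSums(norm$rpm[member, , drop = FALSE])
      m1 <- mean(vals[g1]); m2 <- mean(vals[g2])
      if (m1 == 0 || m2 == 0) {
        nz <- vals[vals > 0]
        pseudo <- if (length(nz)) min(nz) / 2 else NA_real_
        if (is.na(pseudo)) next  # all-zero region cannot have been significant
        if (m1 == 0) m1 <- pseudo
        if (m2 == 0) m2 <- pseudo
      }
      fc <- max(m1, m2) / min(m1, m2)
      if (fc < fc_min) next
      regions[[length(regions) + 1]] <- data.frame(
        chrom = cn, start = start, end = end, n_sites = length(member),
        direction = if (dir[member[1]] > 0) "hyper" else "hypo",
        mean_rpm_1 = mean(vals[g1]), mean_rpm_2 = mean(vals[g2]),
        fold_change = fc, p_adjusted = min(p_adj[member]),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(regions)) do.call(rbind, regions)
         else data.frame(chrom = character(0), start = integer(0), end = integer(0),
                         n_sites = integer(0), direction = character(0),
                         mean_rpm_1 = numeric(0), mean_rpm_2 = numeric(0),
                         fold_change = numeric(0), p_adjusted = numeric(0),
                         stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$id <- if (nrow(out)) sprintf("dmr_%03d", seq_len(nrow(out))) else character(0)
  out$annotation <- rep("", nrow(out))
  out$autosomal <- !(out$chrom %in% sex_chroms)
  if (autosomal_only) out <- out[out$autosomal, , drop = FALSE]
  rownames(out) <- NULL
  out <- out[, c("id", "chrom", "start", "end", "n_sites", "direction",
                 "mean_rpm_1", "mean_rpm_2", "fold_change", "p_adjusted",
                 "annotation", "autosomal")]
  structure(out, class = c("dmr_table", "data.frame"),
            n_tested = m, n_significant = sum(sig),
            groups = c(group1, group2))
}

# split a logical significance vector (with per-site directions) into runs of
# same-direction marked sites; gap = allowed grid-step distance between
# consecutive members (1 = adjacent)
merge_runs <- function(sig, dir, max_gap_sites) {
  runs <- list()
  cur <- integer(0)
  cur_dir <- 0
  last <- -Inf
  for (i in seq_along(sig)) {
    if (!sig[i]) next
    if (length(cur) && dir[i] == cur_dir && (i - last) <= max_gap_sites) {
      cur <- c(cur, i)
    } else {
      if (length(cur)) runs[[length(runs) + 1]] <- cur
      cur <- i
      cur_dir <- dir[i]
    }
    last <- i
  }
  if (length(cur)) runs[[length(runs) + 1]] <- cur
  runs
}

#' Annotate DMRs with TSS, gene-body and CpG-island overlap
#'
#' A DMR is labelled `TSS` when it overlaps the window from `tss_flank` bp
#' before to `tss_flank` bp after a gene's transcription start site;
#' `gene_body` when it overlaps the interval from `tss_flank` bp after the TSS
#' to the TES (strand-aware, mirrored on the minus strand); `CpG_island` when
#' it overlaps any island. Labels are non-exclusive and stored comma-joined in
#' the `annotation` column.
#'
#' @param dmrs a `dmr_table`.
#' @param annotation an [annotation_set()].
#' @param tss_flank flank size in bp (default 1000).
#' @return the `dmr_table` with its `annotation` column filled in.
#' @export
annotate_dmrs <- function(dmrs, annotation, tss_flank = 1000L) {
  stopifnot(inherits(annotation, "annotation_set"))
  genes <- annotation$genes
  isl <- annotation$cpg_islands
  labels <- vapply(seq_len(nrow(dmrs)), function(i) {
    d <- dmrs[i, ]
    lab <- character(0)
    g <- genes[genes$chrom == d$chrom, , drop = FALSE]
    if (nrow(g)) {
      if (any(overlaps(d$start, d$end, g$tss - tss_flank, g$tss + tss_flank)))
        lab <- c(lab, "TSS")
      body_start <- ifelse(g$strand == "+", g$tss + tss_flank, g$tes)
      body_end <- ifelse(g$strand == "+", g$tes, g$tss - tss_flank)
      valid <- body_start < body_end
      if (any(valid & overlaps(d$start, d$end, body_start, body_end)))
        lab <- c(lab, "gene_body")
    }
    ii <- isl[isl$chrom == d$chrom, , drop = FALSE]
    if (nrow(ii) && any(overlaps(d$start, d$end, ii$start, ii$end)))
      lab <- c(lab, "CpG_island")
    paste(lab, collapse = ",")
  }, "")
  dmrs$annotation <- labels
  dmrs
}

#' Per-sample region methylation value
#'
#' Sums RPM-normalized counts over the sites of a region, giving the region's
#' methylation value per sample on the RPM scale (the value all downstream
#' ROC thresholds, marker comparisons and correlations operate on).
#'
#' @param normalized an `rpm_matrix` from [normalize_rpm()].
#' @param region list or single-row data frame with `chrom`, `start`, `end`
#'   (half-open).
#' @param stat `"sum"` (default) or `"mean"` over member sites.
#' @return named numeric vector, one value per sample.
#' @export
region_rpm <- function(normalized, region, stat = c("sum", "mean")) {
  stopifnot(inherits(normalized, "rpm_matrix"))
  stat <- match.arg(stat)
  sel <- normalized$sites$chrom == region$chrom &
    normalized$sites$pos >= region$start & normalized$sites$pos < region$end
  if (!any(sel)) stop_msg("region %s:%d-%d covers no sites on the grid",
                          region$chrom, region$start, region$end)
  v <- normalized$rpm[sel, , drop = FALSE]
  if (stat == "sum") colSums(v) else colMeans(v)
}

#' Region-by-sample methylation matrix for a DMR table
#'
#' @param normalized an `rpm_matrix`.
#' @param dmrs a `dmr_table` (or any data frame with `id`, `chrom`, `start`,
#'   `end`).
#' @param stat passed to [region_rpm()].
#' @return numeric matrix, one row per DMR (rownames = DMR ids), one column
#'   per sample.
#' @export
region_rpm_matrix <- function(normalized, dmrs, stat = "sum") {
  stopifnot(nrow(dmrs) >= 1)
  out <- t(vapply(seq_len(nrow(dmrs)),
                  function(i) region_rpm(normalized, dmrs[i, ], stat = stat),
                  numeric(ncol(normalized$rpm))))
  rownames(out) <- dmrs$id
  out
}
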