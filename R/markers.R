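#' Convert gestational age from weeks+days notation to days
#'
#' Obstetric records write gestational age as completed weeks plus days,
#' e.g. `"39+2"`; correlation analyses need a single numeric scale, so ages
#' are encoded in days (`39 * 7 + 2 = 275`).
#'
#' @param x character vector like `"39+2"` (or `"39"` for exact weeks), or a
#'   numeric vector already in days (returned unchanged).
#' @return numeric vector of days.
#' @examples
#' ga_days("39+2")  # 275
#' @export
ga_days <- function(x) {
  if (is.numeric(x)) return(x)
  parts <- strsplit(as.character(x), "\\+")
  vapply(parts, function(p) {
    p <- suppressWarnings(as.numeric(trimws(p)))
    if (any(is.na(p)) || length(p) > 2) return(NA_real_)
    if (length(p) == 1) p * 7 else p[1] * 7 + p[2]
  }, 0)
}

#' Compare a marker region between two sample groups
#'
#' Welch's unequal-variance two-sided t-test on per-sample region methylation
#' (RPM scale), with the fold change of group means. Used for
#' placenta-specific markers (a RASSF1-promoter-style region) across cfDNA
#' collection periods.
#'
#' Degenerate inputs: when both groups are constant and equal the test is
#' vacuous and p = 1 by convention; constant but different groups give p = 0
#' with a warning; a zero denominator mean yields an infinite fold change with
#' a warning.
#'
#' @param region list/row with `chrom`, `start`, `end` (and optionally `id`).
#' @param normalized an `rpm_matrix`.
#' @param sheet sample sheet.
#' @param groupA,groupB group labels (>= 2 samples each).
#' @return list: `id`, `groupA`, `groupB`, `mean_a`, `mean_b`, `fold_change`
#'   (= mean_a / mean_b), `p_value`, `n_a`, `n_b`.
#' @export
compare_marker <- function(region, normalized, sheet, groupA, groupB) {
  vals <- region_rpm(normalized, region)
  ga <- vals[intersect(sheet$sample_id[sheet$group == groupA], names(vals))]
  gb <- vals[intersect(sheet$sample_id[sheet$group == groupB], names(vals))]
  if (length(ga) < 2 || length(gb) < 2)
    stop_msg("both groups need >= 2 samples (got %d and %d)", length(ga), length(gb))
  ma <- mean(ga); mb <- mean(gb)
  if (mb == 0) {
    warning("zero denominator mean; fold change reported as Inf")
    fc <- Inf
  } else fc <- ma / mb
  if (sd(ga) == 0 && sd(gb) == 0) {
    p <- if (ma == mb) 1 else {
      warning("both groups constant with different means; p = 0 by convention")
      0
    }
  } else {
    p <- t.test(ga, gb, var.equal = FALSE)$p.value
  }
  list(id = region$id %||% sprintf("%s:%d-%d", region$chrom, region$start, region$end),
       groupA = groupA, groupB = groupB, mean_a = ma, mean_b = mb,
       fold_change = fc, p_value = p, n_a = length(ga), n_b = length(gb))
}

#' Pearson correlation of a region's methylation with gestational age
#'
#' Correlates per-sample region methylation (RPM scale) with gestational age
#' in days over the included cfDNA samples; samples without a gestational age
#' (non-pregnant donors) are excluded. A correlation of at least `r_min`
#' (signed, i.e. a positive association) selects the region as a
#' gestational-age marker; `use_abs = TRUE` switches to `|r| >= r_min` to also
#' capture declining (first-trimester-hyper) markers.
#'
#' @param region list/row with `chrom`, `start`, `end` (and optionally `id`).
#' @param normalized an `rpm_matrix`.
#' @param sheet sample sheet with `ga_days`.
#' @param include_groups group labels of the samples to correlate (e.g. all
#'   cfDNA periods).
#' @param r_min selection cutoff on r (default 0.7).
#' @param use_abs select on `|r|` instead of signed r.
#' @return list: `id`, `r`, `n`, `selected`, `reason` (non-`NA` when r is
#'   undefined, e.g. zero variance).
#' @export
correlate_with_ga <- function(region, normalized, sheet, include_groups,
                              r_min = 0.7, use_abs = FALSE) {
  vals <- region_rpm(normalized, region)
  keep <- sheet$group %in% include_groups & !is.na(sheet$ga_days)
  ids <- intersect(sheet$sample_id[keep], names(vals))
  if (length(ids) < 3) stop_msg("need >= 3 samples with gestational age (got %d)", length(ids))
  x <- vals[ids]
  y <- sheet$ga_days[match(ids, sheet$sample_id)]
  id <- region$id %||% sprintf("%s:%d-%d", region$chrom, region$start, region$end)
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(id = id, r = NA_real_, n = length(ids), selected = FALSE,
                reason = "zero variance"))
  }
  r <- cor(x, y)
  list(id = id, r = r, n = length(ids),
       selected = if (use_abs) abs(r) >= r_min else r >= r_min,
       reason = NA_character_)
}

#' Buffy-coat hypomethylation filter
#'
#' Placental DMRs that are highly methylated in hematopoietic cells are masked
#' in cfDNA, which is dominated by blood-cell fragments. This filter keeps a
#' DMR when at least `min_fraction` of buffy-coat samples score 0 (below the
#' DMR's binary threshold); the comparison is inclusive, so exactly 80% of
#' samples passes at the default cutoff.
#'
#' @param dmrs a `dmr_table` (its `id` and `direction` columns are used).
#' @param buffy_scores integer 0/1 matrix, DMR x buffy samples (rownames =
#'   DMR ids), e.g. `binary_score()` applied to buffy region values.
#' @param min_fraction minimal fraction of buffy samples scoring 0.
#' @return data frame: `id`, `fraction_zero`, `passes`, `direction`.
#' @export
buffycoat_filter <- function(dmrs, buffy_scores, min_fraction = 0.8) {
  if (is.null(dim(buffy_scores)) || ncol(buffy_scores) == 0)
    stop_msg("no buffy-coat samples supplied")
  miss <- setdiff(dmrs$id, rownames(buffy_scores))
  if (length(miss)) stop_msg("no buffy scores for DMR '%s'", miss[1])
  frac <- rowMeans(buffy_scores[dmrs$id, , drop = FALSE] == 0L)
  data.frame(id = dmrs$id, fraction_zero = unname(frac),
             passes = unname(frac >= min_fraction),
             direction = dmrs$direction, stringsAsFactors = FALSE)
}

#' Summed methylation of a marker panel per sample
#'
#' Adds the region methylation values (RPM scale) of a panel of marker regions
#' per sample — the combined-marker readout used to track the placental cfDNA
#' fraction across gestation.
#'
#' @param regions data frame with `chrom`, `start`, `end` (one row per marker).
#' @param normalized an `rpm_matrix`.
#' @return named numeric vector, one value per sample.
#' @export
marker_panel_score <- function(regions, normalized) {
  if (!nrow(regions)) stop_msg("empty marker panel")
  vals <- matrix(0, ncol(normalized$rpm), nrow(regions),
                 dimnames = list(colnames(normalized$rpm), NULL))
  for (i in seq_len(nrow(regions))) vals[, i] <- region_rpm(normalized, regions[i, ])
  rowSums(vals)
}
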