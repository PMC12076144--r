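#' Fit the optimal binary-methylation threshold for one DMR
#'
#' Mimics an ROC analysis of two reference sample sets: candidate thresholds
#' are the midpoints between consecutive sorted distinct pooled values, and the
#' returned threshold maximizes Youden's J = sensitivity + specificity - 1 for
#' classifying `values_high` above / `values_low` below. Ties on J are broken
#' in favour of higher specificity (the score should claim presence of the
#' reference signature conservatively), remaining ties in favour of the larger
#' threshold. When the `values_high` set actually lies below `values_low`, the
#' orientation is inverted and recorded in the `inverted` flag.
#'
#' @param values_high region methylation values of reference set A (expected
#'   hyper side).
#' @param values_low region methylation values of reference set B.
#' @return list with `threshold`, `youden` (J in \[0, 1\]) and `inverted`.
#' @examples
#' fit_threshold(c(0.8, 0.9), c(0.1, 0.2))  # threshold 0.5, J = 1
#' @export
fit_threshold <- function(values_high, values_low) {
  if (!length(values_high) || !length(values_low))
    stop_msg("both reference sets need at least one value")
  pooled <- sort(unique(c(values_high, values_low)))
  if (length(pooled) < 2) stop_msg("degenerate reference distributions: all values identical")
  cand <- (head(pooled, -1) + tail(pooled, -1)) / 2

  pick <- function(A, B) {
    j <- vapply(cand, function(t) mean(A > t) + mean(B <= t) - 1, 0)
    spec <- vapply(cand, function(t) mean(B <= t), 0)
    best <- which(j == max(j))
    best <- best[spec[best] == max(spec[best])]
    best <- best[length(best)]
    list(threshold = cand[best], youden = j[best])
  }
  fwd <- pick(values_high, values_low)
  rev_ <- pick(values_low, values_high)
  if (rev_$youden > fwd$youden)
    list(threshold = rev_$threshold, youden = rev_$youden, inverted = TRUE)
  else
    list(threshold = fwd$threshold, youden = fwd$youden, inverted = FALSE)
}

#' Binary methylation score for one region value
#'
#' A sample scores 1 when its region methylation exceeds the DMR's fitted
#' threshold and 0 otherwise. Thresholds are midpoints between observed
#' values, so exact equality is measure-zero; equality scores 0 by convention.
#'
#' @param value region methylation value (region RPM scale).
#' @param model a fitted model from [fit_threshold()] (or any list with a
#'   `threshold` element).
#' @return integer 0 or 1 (vectorized over `value`).
#' @export
binary_score <- function(value, model) {
  as.integer(value > model$threshold)
}

#' Fit per-DMR threshold models from two reference groups
#'
#' For every DMR, extracts the per-sample region methylation of the two
#' reference groups and fits the ROC-midpoint threshold. The hyper side of
#' each DMR is taken from its calling direction (`"hyper"` = higher in
#' `group1`), flipped when the threshold fit inverts.
#'
#' @param dmrs a `dmr_table`.
#' @param normalized an `rpm_matrix` covering the reference samples.
#' @param sheet sample sheet.
#' @param group1,group2 the two reference group labels (normally the groups
#'   that defined the DMRs).
#' @param stat region summary passed to [region_rpm()].
#' @return data frame of class `binary_score_model`: `id`, `threshold`,
#'   `youden`, `hyper_group` (which reference label is the hyper side),
#'   `group1`, `group2`.
#' @export
fit_binary_models <- function(dmrs, normalized, sheet, group1, group2,
                              stat = "sum") {
  if (!nrow(dmrs)) stop_msg("empty DMR table")
  g1 <- sheet$sample_id[sheet$group == group1]
  g2 <- sheet$sample_id[sheet$group == group2]
  if (!length(g1) || !length(g2)) stop_msg("reference group resolves to no samples")
  vals <- region_rpm_matrix(normalized, dmrs, stat = stat)
  rows <- lapply(seq_len(nrow(dmrs)), function(i) {
    hyper_first <- dmrs$direction[i] == "hyper"
    hi <- if (hyper_first) g1 else g2
    lo <- if (hyper_first) g2 else g1
    fit <- fit_threshold(vals[i, hi], vals[i, lo])
    hyper_group <- if (xor(hyper_first, fit$inverted)) group1 else group2
    data.frame(id = dmrs$id[i], threshold = fit$threshold, youden = fit$youden,
               hyper_group = hyper_group, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$group1 <- group1
  out$group2 <- group2
  structure(out, class = c("binary_score_model", "data.frame"))
}

#' Cumulative methylation score of samples against a DMR signature
#'
#' For each sample, counts the signature DMRs whose binary score matches the
#' reference of interest: score 1 on DMRs hypermethylated in the reference,
#' score 0 on DMRs hypomethylated in it. The overlap proportion is the total
#' number of matching DMRs divided by the number of signature DMRs.
#'
#' @param values region-by-sample methylation matrix (rownames = DMR ids), as
#'   from [region_rpm_matrix()].
#' @param models a `binary_score_model` table covering every DMR in `values`.
#' @param reference the reference group label of interest (must be one of the
#'   two labels the models were fitted on).
#' @return data frame, one row per sample: `sample_id`, `n_hyper_matched`,
#'   `n_hypo_matched`, `n_hyper`, `n_hypo`, `total`, `proportion`.
#' @export
cumulative_score <- function(values, models, reference) {
  ids <- rownames(values)
  miss <- setdiff(ids, models$id)
  if (length(miss)) stop_msg("no fitted model for DMR '%s'", miss[1])
  models <- models[match(ids, models$id), ]
  if (!reference %in% c(models$group1[1], models$group2[1]))
    stop_msg("reference '%s' is not one of the model's groups", reference)
  ref_hyper <- models$hyper_group == reference
  scores <- sweep(values, 1, models$threshold, ">") * 1L  # 1 iff value > threshold
  hyper_match <- colSums(scores[ref_hyper, , drop = FALSE] == 1L)
  hypo_match <- colSums(scores[!ref_hyper, , drop = FALSE] == 0L)
  total <- length(ids)
  data.frame(sample_id = colnames(values),
             n_hyper_matched = as.integer(hyper_match),
             n_hypo_matched = as.integer(hypo_match),
             n_hyper = sum(ref_hyper), n_hypo = sum(!ref_hyper),
             total = total,
             proportion = (hyper_match + hypo_match) / total,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Group-wise overlap of target samples with a DMR signature
#'
#' Applies [cumulative_score()] to every sample of each target group and
#' summarizes the overlap proportions per group (mean and SD; SD is 0 for a
#' single-sample group).
#'
#' @param dmrs signature `dmr_table` (non-empty).
#' @param models fitted `binary_score_model` table for these DMRs.
#' @param normalized `rpm_matrix` covering the target samples.
#' @param sheet sample sheet.
#' @param target_groups character vector of group labels to score.
#' @param reference reference group of interest (see [cumulative_score()]).
#' @param stat region summary statistic.
#' @return data frame: `group`, `n`, `mean_proportion`, `sd_proportion`.
#' @export
overlap_profile <- function(dmrs, models, normalized, sheet, target_groups,
                            reference, stat = "sum") {
  if (!nrow(dmrs)) stop_msg("empty DMR signature")
  vals <- region_rpm_matrix(normalized, dmrs, stat = stat)
  rows <- lapply(target_groups, function(g) {
    ids <- intersect(sheet$sample_id[sheet$group == g], colnames(vals))
    if (!length(ids)) stop_msg("target group '%s' resolves to no samples", g)
    cs <- cumulative_score(vals[, ids, drop = FALSE], models, reference)
    data.frame(group = g, n = length(ids),
               mean_proportion = mean(cs$proportion),
               sd_proportion = if (length(ids) > 1) sd(cs$proportion) else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
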