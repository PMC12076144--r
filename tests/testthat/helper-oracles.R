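# independent brute-force oracles used across tests

# textbook Pearson chi-squared: sum (O - E)^2 / E over the 4 cells of
# [[a, n1 - a], [b, n2 - b]]
oracle_chi2 <- function(a, n1, b, n2) {
  obs <- c(a, n1 - a, b, n2 - b)
  rs <- c(n1, n2)
  cs <- c(a + b, n1 + n2 - a - b)
  expd <- outer(rs, cs) / (n1 + n2)
  stat <- sum((matrix(obs, 2, byrow = TRUE) - expd)^2 / expd)
  list(stat = stat, p = pchisq(stat, 1, lower.tail = FALSE))
}

# exhaustive Youden scan over midpoint candidates, both orientations
oracle_youden <- function(A, B) {
  pooled <- sort(unique(c(A, B)))
  cand <- (head(pooled, -1) + tail(pooled, -1)) / 2
  best <- -Inf
  for (t in cand) {
    j1 <- mean(A > t) + mean(B <= t) - 1
    j2 <- mean(B > t) + mean(A <= t) - 1
    best <- max(best, j1, j2)
  }
  best
}

# covariance-formula Pearson correlation
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sqrt(sum((x - mean(x))^2) / (n - 1))
  sy <- sqrt(sum((y - mean(y))^2) / (n - 1))
  sum((x - mean(x)) * (y - mean(y))) / ((n - 1) * sx * sy)
}

# two-tissue methylome pair with planted regions, flat baseline by default
flat_pair <- function(genome, planted = NULL, baseline = 0.2, seed = 1) {
  cfg <- methylome_config(c("a", "b"), planted = planted,
                          baseline_range = c(baseline, baseline), noise_sd = 0)
  generate_methylomes(genome, cfg, seed = seed)
}

# design for n pure samples per tissue
pure_design <- function(n_per, depth, tissues = c("a", "b")) {
  do.call(rbind, lapply(tissues, function(t)
    data.frame(sample_id = sprintf("%s%02d", t, seq_len(n_per)), source = t,
               depth = depth, stringsAsFactors = FALSE)))
}

sheet_from_design <- function(design, group_map = NULL) {
  grp <- if (is.null(group_map)) design$source else group_map[design$source]
  data.frame(sample_id = design$sample_id, group = unname(grp),
             tissue = unname(grp), ga_days = NA_real_, stringsAsFactors = FALSE)
}

# 32-base fragment with the given motif planted at a 0-based offset over an
# all-A background (motif occurs nowhere else)
planted_fragment <- function(offset, motif = "CCGG") {
  stopifnot(offset >= 0, offset + nchar(motif) <= 32)
  paste0(strrep("A", offset), motif, strrep("A", 32 - offset - nchar(motif)))
}

# rpm_matrix whose rows are single-site regions at chr1:100, chr1:200, ...
marker_norm <- function(values) {
  # single-site regions, one per row of `values`; library sizes equalized
  n <- ncol(values)
  sites <- data.frame(chrom = "chr1", pos = seq_len(nrow(values)) * 100L)
  structure(list(sites = sites,
                 rpm = matrix(values, nrow(values), n,
                              dimnames = list(paste0(sites$chrom, ":", sites$pos),
                                              colnames(values))),
                 lib_sizes = rep(1e6, n)), class = "rpm_matrix")
}

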