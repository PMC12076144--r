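#' Describe a tissue design with planted differentially methylated regions
#'
#' Assembles the configuration consumed by [generate_methylomes()]: which
#' tissues exist, the shared baseline methylation propensity law, per-tissue
#' background noise, and a table of planted DMRs. Each planted DMR names a
#' low/high tissue pair; the high tissue's propensity over the region is the
#' shared baseline times `multiplier` (clipped to \[0, 1\]). Optional `gradient`
#' tissues are placed linearly between the pair, emulating the gradual
#' first-trimester-to-term drift of the placental methylome, and `leuk_level`
#' overrides the leukocyte propensity over the region (used to plant markers
#' that are hypomethylated in buffy coat and hence visible in cfDNA).
#'
#' @param tissues character vector of tissue labels.
#' @param planted data frame with columns `chrom`, `start_site` (1-based site
#'   index within the chromosome), `n_sites` (>= 2), `tissue_low`,
#'   `tissue_high` (each a tissue label or comma-separated list; every listed
#'   tissue gets the low/high propensity), `multiplier` (> 0, != 1); optional
#'   `gradient` (comma-separated `tissue` or `tissue:weight` entries placed at
#'   weight w between low and high, default w = 0.5) and `leuk_level`.
#'   `NULL` plants nothing.
#' @param baseline_range range of the per-site baseline propensity (uniform).
#' @param noise_sd per-tissue Gaussian background noise outside planted
#'   regions; 0 makes all tissues identical there.
#' @param leukocyte label of the leukocyte tissue targeted by `leuk_level`.
#' @return a list of class `methylome_config`.
#' @export
methylome_config <- function(tissues, planted = NULL,
                             baseline_range = c(0.1, 0.35),
                             noise_sd = 0.01, leukocyte = "leukocyte") {
  stopifnot(is.character(tissues), length(tissues) >= 1, !anyDuplicated(tissues))
  if (!is.null(planted)) {
    need <- c("chrom", "start_site", "n_sites", "tissue_low", "tissue_high", "multiplier")
    missing_cols <- setdiff(need, names(planted))
    if (length(missing_cols))
      stop_msg("planted table lacks column(s): %s", paste(missing_cols, collapse = ", "))
    if (is.null(planted$gradient)) planted$gradient <- NA_character_
    if (is.null(planted$leuk_level)) planted$leuk_level <- NA_real_
    if (any(planted$n_sites < 2))
      stop_msg("every planted DMR must cover >= 2 consecutive sites")
    if (any(planted$multiplier <= 0 | planted$multiplier == 1))
      stop_msg("effect multiplier must be > 0 and != 1")
    tset <- unique(c(unlist(strsplit(planted$tissue_low, ",")),
                     unlist(strsplit(planted$tissue_high, ",")),
                     sub(":.*$", "", unlist(strsplit(
                       planted$gradient[!is.na(planted$gradient)], ",")))))
    unknown <- setdiff(trimws(tset), tissues)
    if (length(unknown)) stop_msg("planted DMR references unknown tissue(s): %s",
                                  paste(unknown, collapse = ", "))
  }
  structure(list(tissues = tissues, planted = planted,
                 baseline_range = baseline_range, noise_sd = noise_sd,
                 leukocyte = leukocyte),
            class = "methylome_config")
}

#' Generate tissue methylomes with planted DMRs and return the ground truth
#'
#' Draws a shared per-site baseline methylation propensity, perturbs it with
#' tissue-specific background noise, then imposes the planted DMRs from the
#' config: within each planted region the low tissue keeps the baseline
#' exactly, the high tissue gets baseline times the effect multiplier (clipped
#' to \[0, 1\], with a message when clipping occurs), gradient tissues are
#' linearly interpolated, and the leukocyte propensity may be pinned to a
#' stated hypo- or hypermethylated level.
#'
#' @param genome a `toy_genome`.
#' @param config a [methylome_config()].
#' @param seed integer seed.
#' @return list with `methylomes` (named list of per-site propensity vectors,
#'   one per tissue, values in \[0, 1\]) and `truth` (class `synthetic_truth`:
#'   `planted_dmrs` data frame with bp coordinates, direction and multiplier;
#'   `placental_fractions`, filled in by the mixture generator; `seed`).
#' @examples
#' g <- generate_genome(1, 50, 3, 2, seed = 1)
#' cfg <- methylome_config(c("a", "b"), noise_sd = 0)
#' m <- generate_methylomes(g, cfg, seed = 2)
#' identical(m$methylomes$a, m$methylomes$b)  # TRUE: null design
#' @export
generate_methylomes <- function(genome, config, seed) {
  stopifnot(inherits(genome, "toy_genome"), inherits(config, "methylome_config"))
  n_sites <- nrow(genome$sites)
  with_seed(seed, {
    base <- runif(n_sites, config$baseline_range[1], config$baseline_range[2])
    meth <- lapply(config$tissues, function(t) {
      if (config$noise_sd > 0) clip01(base + rnorm(n_sites, 0, config$noise_sd)) else base
    })
    names(meth) <- config$tissues

    planted <- config$planted
    truth_rows <- list()
    if (!is.null(planted) && nrow(planted)) {
      for (i in seq_len(nrow(planted))) {
        pl <- planted[i, ]
        chrom_idx <- which(genome$sites$chrom == pl$chrom)
        if (!length(chrom_idx)) stop_msg("planted region on unknown chromosome '%s'", pl$chrom)
        if (pl$start_site + pl$n_sites - 1 > length(chrom_idx))
          stop_msg("planted region %d: sites %d..%d fall off the site grid of %s",
                   i, pl$start_site, pl$start_site + pl$n_sites - 1, pl$chrom)
        idx <- chrom_idx[pl$start_site:(pl$start_site + pl$n_sites - 1)]
        p_low <- base[idx]
        p_high_raw <- base[idx] * pl$multiplier
        if (any(p_high_raw > 1))
          message(sprintf("planted region %d: multiplier %.2f clips propensity to 1 at %d site(s)",
                          i, pl$multiplier, sum(p_high_raw > 1)))
        p_high <- clip01(p_high_raw)
        for (t in trimws(strsplit(pl$tissue_low, ",")[[1]])) meth[[t]][idx] <- p_low
        for (t in trimws(strsplit(pl$tissue_high, ",")[[1]])) meth[[t]][idx] <- p_high
        if (!is.na(pl$gradient)) {
          for (entry in trimws(strsplit(pl$gradient, ",")[[1]])) {
            kv <- strsplit(entry, ":")[[1]]
            w <- if (length(kv) == 2) as.numeric(kv[2]) else 0.5
            meth[[kv[1]]][idx] <- (1 - w) * p_low + w * p_high
          }
        }
        if (!is.na(pl$leuk_level)) meth[[config$leukocyte]][idx] <- pl$leuk_level
        pos <- genome$sites$pos[idx]
        truth_rows[[i]] <- data.frame(
          id = sprintf("planted_%03d", i), chrom = pl$chrom,
          start = pos[1], end = pos[length(pos)] + 1L,
          start_site = pl$start_site, n_sites = pl$n_sites,
          tissue_low = pl$tissue_low, tissue_high = pl$tissue_high,
          direction = "hyper_in_high", multiplier = pl$multiplier,
          leuk_level = pl$leuk_level, stringsAsFactors = FALSE)
      }
    }
    truth <- structure(list(
      planted_dmrs = if (length(truth_rows)) do.call(rbind, truth_rows)
                     else data.frame(),
      placental_fractions = NULL, seed = as.integer(seed)),
      class = "synthetic_truth")
    list(methylomes = meth, truth = truth)
  })
}

# parse a mixture spec string: "placenta_term:0.35,leukocyte:0.65" or a bare
# tissue label (weight 1); returns a named weight vector
parse_mixture <- function(spec, tissues) {
  parts <- trimws(strsplit(spec, ",")[[1]])
  if (length(parts) == 1L && !grepl(":", parts)) {
    w <- setNames(1, parts)
  } else {
    kv <- strsplit(parts, ":")
    if (any(lengths(kv) != 2)) stop_msg("malformed mixture spec '%s'", spec)
    w <- setNames(as.numeric(vapply(kv, `[`, "", 2)), vapply(kv, `[`, "", 1))
  }
  unknown <- setdiff(names(w), tissues)
  if (length(unknown)) stop_msg("unknown tissue label '%s' in mixture spec", unknown[1])
  if (any(is.na(w) | w < 0 | w > 1)) stop_msg("mixture fractions must lie in [0, 1]: '%s'", spec)
  if (abs(sum(w) - 1) > 1e-8) stop_msg("mixture fractions must sum to 1: '%s'", spec)
  w
}

#' Simulate a site-by-sample count matrix from tissue methylomes
#'
#' Each sample is a pure tissue or a mixture (e.g. cfDNA as a
#' leukocyte/placenta mixture). The mixture propensity at a site is the
#' weighted sum of tissue propensities; per-site counts are drawn independently
#' from a Poisson law with mean `depth * mix(site) / sum(mix)`, so the expected
#' library size equals the requested depth. An optional Gamma-Poisson
#' overdispersion can be switched on for robustness checks; the default is
#' pure Poisson shot noise.
#'
#' @param methylomes named list of per-site propensity vectors (from
#'   [generate_methylomes()]).
#' @param design data frame with columns `sample_id`, `source` (tissue label or
#'   `"tissueA:f,tissueB:1-f"` mixture spec) and `depth` (> 0).
#' @param seed integer seed; counts are reproducible for a fixed seed.
#' @param overdispersion Gamma-Poisson dispersion phi (variance
#'   `mu + phi * mu^2`); 0 = Poisson.
#' @param genome optional `toy_genome` supplying site coordinates; otherwise
#'   sites are labelled `chrS:index`.
#' @return list with `counts` (a [site_count_matrix()]) and
#'   `placental_fractions`: per-sample summed weight of tissues whose label
#'   starts with `"placenta"` (the simulated placental cfDNA fraction).
#' @export
generate_count_matrix <- function(methylomes, design, seed, overdispersion = 0,
                                  genome = NULL) {
  stopifnot(is.list(methylomes), length(methylomes) >= 1)
  need <- c("sample_id", "source", "depth")
  if (!all(need %in% names(design))) stop_msg("design needs columns: %s", paste(need, collapse = ", "))
  if (anyDuplicated(design$sample_id)) stop_msg("duplicate sample_id in design")
  if (any(design$depth <= 0)) stop_msg("depth must be > 0")
  n_sites <- length(methylomes[[1]])
  P <- do.call(cbind, methylomes)

  sites <- if (!is.null(genome)) genome$sites
           else data.frame(chrom = "chrS", pos = seq_len(n_sites) * 100L,
                           stringsAsFactors = FALSE)

  with_seed(seed, {
    counts <- matrix(0L, n_sites, nrow(design),
                     dimnames = list(NULL, design$sample_id))
    frac <- numeric(nrow(design))
    for (j in seq_len(nrow(design))) {
      w <- parse_mixture(design$source[j], colnames(P))
      mix <- as.vector(P[, names(w), drop = FALSE] %*% w)
      if (sum(mix) <= 0) stop_msg("sample %s: mixture propensities sum to 0", design$sample_id[j])
      mu <- design$depth[j] * mix / sum(mix)
      counts[, j] <- if (overdispersion > 0)
        rnbinom(n_sites, mu = mu, size = 1 / overdispersion)
      else rpois(n_sites, mu)
      frac[j] <- sum(w[startsWith(names(w), "placenta")])
    }
    list(counts = site_count_matrix(sites, counts),
         placental_fractions = setNames(frac, design$sample_id))
  })
}
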