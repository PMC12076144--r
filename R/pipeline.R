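#' Default placental cfDNA fraction trajectory across gestation
#'
#' The placenta-derived share of maternal cfDNA rises across gestation,
#' steeply towards delivery. The package's default trajectory interpolates
#' linearly through anchor fractions 0.08, 0.12, 0.20 and 0.35 at
#' representative first/second/third-trimester and delivery ages, and is held
#' constant outside the anchor range.
#'
#' @param ga gestational age in days (vectorized).
#' @param anchors data frame with `ga_days` and `fraction` anchor points.
#' @return placental fraction in \[0, 1\].
#' @examples
#' placental_fraction(c(80, 280))
#' @export
placental_fraction <- function(ga, anchors = data.frame(
                                 ga_days = c(80, 140, 225, 280),
                                 fraction = c(0.08, 0.12, 0.20, 0.35))) {
  approx(anchors$ga_days, anchors$fraction, xout = ga, rule = 2)$y
}

# deterministic, non-overlapping planted-region start indices
spaced_starts <- function(n, every, offset, n_sites, width) {
  s <- offset + (seq_len(n) - 1L) * every
  if (any(s + width - 1L > n_sites))
    stop_msg("cannot place %d regions of %d sites on %d sites", n, width, n_sites)
  s
}

#' Build the packaged synthetic study: genome, methylomes, counts, sheet
#'
#' Emulates the study design at desk scale: a two-chromosome toy genome;
#' leukocyte, bulk placenta (three trimesters) and trophoblast methylomes;
#' longitudinal cfDNA as a leukocyte/placenta mixture whose placental fraction
#' follows [placental_fraction()] of each sample's gestational age; buffy-coat
#' and pure-tissue samples. Planted structure:
#' \itemize{
#'   \item 30 placenta-hyper + 10 placenta-hypo "pregnancy signature" regions
#'     (placental tissues vs leukocyte) on chr1 — these drive the
#'     cfDNA-vs-non-pregnant DMRs;
#'   \item 20 placental "aging" regions (first trimester vs term, second
#'     trimester midway) on chr2: 8 term-hyper and buffy-hypomethylated (the
#'     recoverable gestational-age markers), 6 first-trimester-hyper and
#'     buffy-hypomethylated, 6 term-hyper but masked by high leukocyte
#'     methylation.
#' }
#'
#' Placental and cfDNA-borne placental profiles mature continuously: each bulk
#' placenta sample sits at a gestational-age-determined position along the
#' first-trimester-to-term methylome gradient plus an inter-individual
#' maturation jitter (`maturation_sd`), and each cfDNA sample mixes leukocyte
#' with the placenta methylome at its own maturation stage. The default depth
#' of 5e4 reads over 2000 sites (~25 reads per site) mirrors the per-site
#' coverage scale of a genome-wide run that passes the assay's QC floor.
#'
#' @param seed integer seed.
#' @param sites_per_chrom sites per chromosome (default 1000).
#' @param depth mean library size per sample (default 5e4).
#' @param n_cfdna cfDNA samples per collection period.
#' @param n_placenta placental samples per trimester.
#' @param n_buffy,n_nonpregnant buffy-coat / non-pregnant cfDNA sample counts.
#' @param maturation_sd SD of the per-sample placental maturation jitter.
#' @return list: `genome`, `methylomes`, `truth` (with placental fractions
#'   filled in), `counts` (a `site_count_matrix`), `sheet`, `annotation`,
#'   `design`.
#' @export
demo_dataset <- function(seed = 1L, sites_per_chrom = 1000L, depth = 5e4,
                         n_cfdna = 10L, n_placenta = 10L, n_buffy = 10L,
                         n_nonpregnant = 6L, maturation_sd = 0.18) {
  genome <- generate_genome(2, sites_per_chrom, 40, 20, seed = child_seed(seed, 1))

  placental <- c("placenta_t1", "placenta_t2", "placenta_term",
                 "sct_ctb_t1", "sct_ctb_t2", "sct_ctb_term",
                 "evt_t1", "evt_t2", "sk_term")
  tissues <- c("leukocyte", placental)
  plac_all <- paste(placental, collapse = ",")
  t1_like <- "placenta_t1,sct_ctb_t1,evt_t1"
  term_like <- "placenta_term,sct_ctb_term,sk_term"
  grad_mid <- "placenta_t2:0.5,sct_ctb_t2:0.5,evt_t2:0.5"

  sig_starts <- spaced_starts(40, max(6L, (sites_per_chrom - 11L) %/% 40L),
                              11, sites_per_chrom, 4)
  aging_starts <- spaced_starts(20, max(7L, (sites_per_chrom - 21L) %/% 20L),
                                21, sites_per_chrom, 5)
  planted <- rbind(
    # pregnancy signature: placenta high, leukocyte pinned low (hyper in cfDNA)
    data.frame(chrom = "chr1", start_site = sig_starts[1:30], n_sites = 4L,
               tissue_low = "leukocyte", tissue_high = plac_all,
               multiplier = 3, gradient = NA_character_, leuk_level = 0.02),
    # minority signature: leukocyte high, placenta at baseline (hypo in cfDNA)
    data.frame(chrom = "chr1", start_site = sig_starts[31:40], n_sites = 4L,
               tissue_low = plac_all, tissue_high = "leukocyte",
               multiplier = 2.5, gradient = NA_character_,
               leuk_level = NA_real_),
    # gestational-age markers: term-hyper, buffy-hypomethylated
    data.frame(chrom = "chr2", start_site = aging_starts[1:8], n_sites = 5L,
               tissue_low = t1_like, tissue_high = term_like,
               multiplier = 7, gradient = grad_mid, leuk_level = 0.02),
    # declining markers: first-trimester-hyper, buffy-hypomethylated
    data.frame(chrom = "chr2", start_site = aging_starts[9:14], n_sites = 5L,
               tissue_low = term_like, tissue_high = t1_like,
               multiplier = 7, gradient = grad_mid, leuk_level = 0.02),
    # masked markers: term-hyper but leukocyte methylation is high
    data.frame(chrom = "chr2", start_site = aging_starts[15:20], n_sites = 5L,
               tissue_low = t1_like, tissue_high = term_like,
               multiplier = 7, gradient = grad_mid, leuk_level = 0.8))

  cfg <- methylome_config(tissues, planted, baseline_range = c(0.12, 0.22),
                          noise_sd = 0.005)
  mm <- generate_methylomes(genome, cfg, seed = child_seed(seed, 2))

  ga_ranges <- list(cfDNA_t1 = c(70, 90), cfDNA_t2 = c(112, 168),
                    cfDNA_t3 = c(196, 250), cfDNA_delivery = c(273, 287))
  # placental maturation: position along the first-trimester-to-term methylome
  # gradient as a function of gestational age
  maturation <- function(ga) approx(c(63, 119, 280), c(0.05, 0.5, 0.95),
                                    xout = ga, rule = 2)$y
  plac_mix <- function(w) sprintf("placenta_t1:%s,placenta_term:%s",
                                  round(1 - w, 4), round(w, 4))
  cf_mix <- function(f, w) {
    p2 <- round(f * w, 4)
    p1 <- round(f - p2, 4)
    sprintf("placenta_t1:%s,placenta_term:%s,leukocyte:%s", p1, p2, 1 - p1 - p2)
  }
  design <- with_seed(child_seed(seed, 3), {
    rows <- list()
    add <- function(ids, group, tissue, source, ga) {
      rows[[length(rows) + 1]] <<- data.frame(
        sample_id = ids, group = group, tissue = tissue, source = source,
        ga_days = ga, depth = depth, stringsAsFactors = FALSE)
    }
    add(sprintf("np_%02d", 1:n_nonpregnant), "cfDNA_nonpregnant", "cfDNA",
        "leukocyte", NA_real_)
    for (g in names(ga_ranges)) {
      ga <- round(runif(n_cfdna, ga_ranges[[g]][1], ga_ranges[[g]][2]))
      f <- round(placental_fraction(ga), 4)
      add(sprintf("%s_%02d", sub("cfDNA_", "cf", g), 1:n_cfdna), g, "cfDNA",
          cf_mix(f, maturation(ga)), ga)
    }
    for (tr in c("t1", "t2", "term")) {
      ga <- switch(tr, t1 = round(runif(n_placenta, 63, 84)),
                   t2 = round(runif(n_placenta, 112, 126)),
                   term = round(runif(n_placenta, 273, 287)))
      w <- clip01(maturation(ga) + rnorm(n_placenta, 0, maturation_sd))
      add(sprintf("pl_%s_%02d", tr, 1:n_placenta), paste0("placenta_", tr),
          "placenta", plac_mix(w), ga)
    }
    add(sprintf("bc_%02d", 1:n_buffy), "buffy", "buffy", "leukocyte", NA_real_)
    add(sprintf("sct_t1_%02d", 1:4), "sct_ctb_t1", "sct_ctb", "sct_ctb_t1",
        round(runif(4, 63, 84)))
    add(sprintf("sct_t2_%02d", 1:3), "sct_ctb_t2", "sct_ctb", "sct_ctb_t2",
        round(runif(3, 112, 126)))
    add(sprintf("sct_term_%02d", 1:3), "sct_ctb_term", "sct_ctb", "sct_ctb_term",
        round(runif(3, 273, 287)))
    add(sprintf("evt_t1_%02d", 1:4), "evt_t1", "evt", "evt_t1",
        round(runif(4, 63, 84)))
    add(sprintf("evt_t2_%02d", 1:3), "evt_t2", "evt", "evt_t2",
        round(runif(3, 112, 126)))
    add(sprintf("sk_%02d", 1:3), "sk_term", "sk", "sk_term",
        round(runif(3, 273, 287)))
    do.call(rbind, rows)
  })

  gen <- generate_count_matrix(mm$methylomes, design, seed = child_seed(seed, 4),
                               genome = genome)
  truth <- mm$truth
  truth$placental_fractions <- gen$placental_fractions
  sheet <- design[, c("sample_id", "group", "tissue", "ga_days")]
  list(genome = genome, methylomes = mm$methylomes, truth = truth,
       counts = gen$counts, sheet = sheet,
       annotation = annotation_set(genome$genes, genome$cpg_islands),
       design = design)
}

#' Write the packaged demo dataset to disk
#'
#' Materializes [demo_dataset()] under `dir`: `counts.tsv`, `samples.tsv`,
#' `genes.tsv`, `islands.bed`, `truth.json` and a ready-to-run pipeline
#' `config.yaml`.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @param ... passed to [demo_dataset()].
#' @return named list of written paths, invisibly; the dataset as attribute
#'   `dataset`.
#' @export
make_demo <- function(dir, seed = 1L, ...) {
  ds <- demo_dataset(seed = seed, ...)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(counts = file.path(dir, "counts.tsv"),
                samples = file.path(dir, "samples.tsv"),
                genes = file.path(dir, "genes.tsv"),
                islands = file.path(dir, "islands.bed"),
                truth = file.path(dir, "truth.json"),
                config = file.path(dir, "config.yaml"))
  write_count_matrix(ds$counts, paths$counts)
  write_sample_sheet(ds$sheet, paths$samples)
  write_annotation(ds$annotation, paths$genes, paths$islands)
  write_truth(ds$truth, paths$truth)
  cfg <- list(
    counts = paths$counts, samples = paths$samples, genes = paths$genes,
    islands = paths$islands, outdir = file.path(dir, "results"),
    seed = as.integer(seed),
    thresholds = list(alpha = 0.05, fc_min = 2, min_sites = 2,
                      max_gap_sites = 1, r_min = 0.7, buffy_fraction = 0.8),
    comparisons = list(
      list(name = "cfDNA_t1_vs_nonpregnant", group1 = "cfDNA_t1", group2 = "cfDNA_nonpregnant"),
      list(name = "cfDNA_t2_vs_nonpregnant", group1 = "cfDNA_t2", group2 = "cfDNA_nonpregnant"),
      list(name = "cfDNA_t3_vs_nonpregnant", group1 = "cfDNA_t3", group2 = "cfDNA_nonpregnant"),
      list(name = "cfDNA_delivery_vs_nonpregnant", group1 = "cfDNA_delivery", group2 = "cfDNA_nonpregnant"),
      list(name = "cfDNA_t1_vs_delivery", group1 = "cfDNA_t1", group2 = "cfDNA_delivery"),
      list(name = "placenta_t1_vs_term", group1 = "placenta_t1", group2 = "placenta_term"),
      list(name = "sct_ctb_t1_vs_term", group1 = "sct_ctb_t1", group2 = "sct_ctb_term")),
    scoring = list(
      list(comparison = "cfDNA_delivery_vs_nonpregnant",
           reference = "cfDNA_delivery",
           targets = list("cfDNA_t1", "cfDNA_t2", "cfDNA_t3", "cfDNA_delivery"))),
    markers = list(placental_comparison = "placenta_t1_vs_term",
                   cfdna_groups = list("cfDNA_t1", "cfDNA_t2", "cfDNA_t3",
                                       "cfDNA_delivery"),
                   buffy_group = "buffy"),
    clustering = list(
      list(comparison = "placenta_t1_vs_term",
           groups = list("placenta_t1", "placenta_t2", "placenta_term"))))
  yaml::write_yaml(cfg, paths$config)
  ret <- structure(paths, dataset = ds)
  invisible(ret)
}

#' Read and validate a pipeline configuration
#'
#' @param path YAML config file (see [make_demo()] for the schema).
#' @return validated config list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_msg("no such config: %s", path)
  cfg <- yaml::read_yaml(path)
  need <- c("counts", "samples", "outdir", "comparisons")
  missing_f <- setdiff(need, names(cfg))
  if (length(missing_f)) stop_msg("config lacks field(s): %s", paste(missing_f, collapse = ", "))
  th <- cfg$thresholds %||% list()
  defaults <- list(alpha = 0.05, fc_min = 2, min_sites = 2, max_gap_sites = 1,
                   r_min = 0.7, buffy_fraction = 0.8)
  cfg$thresholds <- modifyList(defaults, th)
  with(cfg$thresholds, {
    if (alpha <= 0 || alpha > 1) stop_msg("alpha must lie in (0, 1]")
    if (fc_min < 1) stop_msg("fc_min must be >= 1")
    if (r_min < -1 || r_min > 1) stop_msg("r_min must lie in [-1, 1]")
    if (buffy_fraction < 0 || buffy_fraction > 1) stop_msg("buffy_fraction must lie in [0, 1]")
  })
  cfg$seed <- cfg$seed %||% 1L
  structure(cfg, class = "pipeline_config")
}

#' Run the full MeD-seq analysis pipeline from a config
#'
#' Orchestrates: input reading and validation, RPM normalization, DMR calling
#' and annotation per configured comparison (BED output), ROC-threshold
#' fitting and cumulative-score overlap profiles, gestational-age marker
#' selection (buffy filter + Pearson correlation with gestational age) and
#' z-score hierarchical clustering. Every group referenced by the config is
#' validated against the sample sheet before any computation; stage failures
#' abort with the stage named. Outputs and per-stage timings are recorded in
#' `manifest.json`; reruns with the same config and seed are byte-identical.
#'
#' @param config path to a YAML config or a `pipeline_config` list.
#' @return the manifest, invisibly (list with `outputs`, `dmr_counts`,
#'   `timings_s`, `config_hash`, `seed`, `version`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stages <- list()
  timing <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop_msg("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    stages[[name]] <<- proc.time()[["elapsed"]] - t0
    res
  }

  counts <- timing("read_counts", read_count_matrix(config$counts))
  sheet <- timing("read_sheet", read_sample_sheet(config$samples))
  validate_samples(counts, sheet)
  annotation <- if (!is.null(config$genes) && !is.null(config$islands))
    timing("read_annotation", read_annotation(config$genes, config$islands))
  else NULL

  # validate all referenced groups before computing anything
  referenced <- unique(c(
    unlist(lapply(config$comparisons, function(x) c(x$group1, x$group2))),
    unlist(lapply(config$scoring, function(x) c(x$reference, unlist(x$targets)))),
    unlist(config$markers$cfdna_groups), config$markers$buffy_group,
    unlist(lapply(config$clustering, function(x) unlist(x$groups)))))
  unknown <- setdiff(referenced, sheet$group)
  if (length(unknown)) stop_msg("config references unknown group '%s'", unknown[1])

  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds
  norm <- timing("normalize", normalize_rpm(counts))

  outputs <- list()
  dmr_counts <- list()
  dmr_tables <- list()
  for (cmp in config$comparisons) {
    dmrs <- timing(paste0("call_dmrs:", cmp$name), {
      d <- call_dmrs(counts, sheet, cmp$group1, cmp$group2, alpha = th$alpha,
                     fc_min = th$fc_min, min_sites = th$min_sites,
                     max_gap_sites = th$max_gap_sites)
      if (!is.null(annotation)) d <- annotate_dmrs(d, annotation)
      d
    })
    dmr_tables[[cmp$name]] <- dmrs
    dmr_counts[[cmp$name]] <- nrow(dmrs)
    bed <- file.path(config$outdir, paste0("dmrs_", cmp$name, ".bed"))
    if (nrow(dmrs)) write_dmr_bed(dmrs, bed) else file.create(bed)
    outputs[[paste0("dmrs_", cmp$name)]] <- bed
    message(sprintf("[%s] tested %d sites, %d significant, %d DMRs",
                    cmp$name, attr(dmrs, "n_tested") %||% NA,
                    attr(dmrs, "n_significant") %||% NA, nrow(dmrs)))
  }

  for (sc in config$scoring %||% list()) {
    dmrs <- dmr_tables[[sc$comparison]]
    if (is.null(dmrs)) stop_msg("scoring references unknown comparison '%s'", sc$comparison)
    if (!nrow(dmrs)) next
    cmp <- Filter(function(x) x$name == sc$comparison, config$comparisons)[[1]]
    res <- timing(paste0("score:", sc$comparison), {
      models <- fit_binary_models(dmrs, norm, sheet, cmp$group1, cmp$group2)
      prof <- overlap_profile(dmrs, models, norm, sheet, unlist(sc$targets),
                              sc$reference)
      list(models = models, profile = prof)
    })
    mpath <- file.path(config$outdir, paste0("thresholds_", sc$comparison, ".tsv"))
    ppath <- file.path(config$outdir, paste0("overlap_", sc$comparison, ".tsv"))
    write.table(res$models, mpath, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(res$profile, ppath, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs[[paste0("thresholds_", sc$comparison)]] <- mpath
    outputs[[paste0("overlap_", sc$comparison)]] <- ppath
  }

  if (!is.null(config$markers)) {
    mk <- config$markers
    dmrs <- dmr_tables[[mk$placental_comparison]]
    if (is.null(dmrs)) stop_msg("markers reference unknown comparison '%s'",
                                mk$placental_comparison)
    if (nrow(dmrs)) {
      cmp <- Filter(function(x) x$name == mk$placental_comparison,
                    config$comparisons)[[1]]
      tab <- timing("markers", {
        models <- fit_binary_models(dmrs, norm, sheet, cmp$group1, cmp$group2)
        buffy_ids <- sheet$sample_id[sheet$group == mk$buffy_group]
        vals <- region_rpm_matrix(norm, dmrs)
        bscores <- sweep(vals[, buffy_ids, drop = FALSE], 1,
                         models$threshold[match(dmrs$id, models$id)], ">") * 1L
        bf <- buffycoat_filter(dmrs, bscores, min_fraction = th$buffy_fraction)
        corr <- lapply(seq_len(nrow(dmrs)), function(i)
          correlate_with_ga(dmrs[i, ], norm, sheet, unlist(mk$cfdna_groups),
                            r_min = th$r_min))
        data.frame(id = dmrs$id, direction = dmrs$direction,
                   fraction_buffy_zero = bf$fraction_zero,
                   passes_buffy = bf$passes,
                   pearson_r = vapply(corr, function(x) x$r, 0),
                   selected = bf$passes & vapply(corr, function(x) isTRUE(x$selected), NA),
                   stringsAsFactors = FALSE)
      })
      mpath <- file.path(config$outdir, "ga_markers.tsv")
      write.table(tab, mpath, sep = "\t", quote = FALSE, row.names = FALSE)
      outputs[["ga_markers"]] <- mpath
      message(sprintf("[markers] %d DMRs -> %d pass buffy filter -> %d selected",
                      nrow(tab), sum(tab$passes_buffy), sum(tab$selected)))
    }
  }

  for (cl in config$clustering %||% list()) {
    dmrs <- dmr_tables[[cl$comparison]]
    if (is.null(dmrs) || nrow(dmrs) < 2) next
    res <- timing(paste0("cluster:", cl$comparison), {
      ids <- sheet$sample_id[sheet$group %in% unlist(cl$groups)]
      vals <- region_rpm_matrix(norm, dmrs)[, ids, drop = FALSE]
      z <- zscore_transform(vals)
      hierarchical_order(z, axis = "samples")
    })
    zpath <- file.path(config$outdir, paste0("leaf_order_", cl$comparison, ".tsv"))
    write.table(data.frame(position = seq_along(res$labels), sample = res$labels),
                zpath, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs[[paste0("leaf_order_", cl$comparison)]] <- zpath
  }

  cfg_tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(config), cfg_tmp)
  cfg_hash <- unname(tools::md5sum(cfg_tmp))
  unlink(cfg_tmp)

  manifest <- list(
    version = as.character(utils::packageVersion("medseqr")),
    config_hash = cfg_hash, seed = config$seed,
    outputs = outputs, dmr_counts = dmr_counts,
    timings_s = lapply(stages, function(x) round(x, 3)))
  man_path <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  missing_out <- !vapply(unlist(outputs), file.exists, NA)
  if (any(missing_out))
    stop_msg("declared output missing: %s", unlist(outputs)[missing_out][1])
  invisible(manifest)
}
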