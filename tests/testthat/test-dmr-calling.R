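test_that("RPM normalization scales columns to one million", {
  scm <- site_count_matrix(data.frame(chrom = "chr1", pos = c(10L, 20L, 30L)),
                           matrix(c(10L, 30L, 60L, 5L, 5L, 5L), 3, 2,
                                  dimnames = list(NULL, c("s1", "s2"))))
  norm <- normalize_rpm(scm)
  expect_equal(norm$rpm[, "s1"], c("chr1:10" = 1e5, "chr1:20" = 3e5, "chr1:30" = 6e5))
  expect_equal(unname(norm$rpm[, "s2"]), rep(1e6 / 3, 3))  # uniform column
  expect_equal(unname(colSums(norm$rpm)), rep(1e6, 2))

  zero <- site_count_matrix(data.frame(chrom = "chr1", pos = 1:2 * 10L),
                            matrix(c(1L, 1L, 0L, 0L), 2, 2,
                                   dimnames = list(NULL, c("ok", "empty"))))
  expect_error(normalize_rpm(zero), "'empty'")
})

test_that("site chi-squared matches the textbook oracle on random tables", {
  set.seed(42)
  for (k in 1:200) {
    n1 <- sample(500:5000, 1); n2 <- sample(500:5000, 1)
    a <- sample(1:100, 1); b <- sample(1:100, 1)
    got <- pearson_chi2(a, n1, b, n2)
    want <- oracle_chi2(a, n1, b, n2)
    expect_lt(abs(got$stat - want$stat), 1e-10)
    expect_lt(abs(got$p - want$p), 1e-10)
  }
  # cross-check against stats::chisq.test without continuity correction
  ct <- chisq.test(matrix(c(30, 970, 10, 990), 2, byrow = TRUE), correct = FALSE)
  got <- pearson_chi2(30, 1000, 10, 1000)
  expect_equal(got$stat, unname(ct$statistic), tolerance = 1e-12)
  expect_equal(got$p, ct$p.value, tolerance = 1e-12)
})

test_that("site_chi_squared handles identical tables, symmetry, untestables", {
  scm <- site_count_matrix(
    data.frame(chrom = "chr1", pos = c(10L, 20L, 30L)),
    matrix(c(30L, 10L, 0L, 970L, 990L, 0L, 30L, 10L, 0L, 970L, 990L, 0L), 3, 4,
           dimnames = list(NULL, c("a1", "a2", "b1", "b2"))))
  res <- site_chi_squared(scm, c("a1", "a2"), c("b1", "b2"), 1)
  expect_equal(res$stat, 0)
  expect_equal(res$p, 1)
  expect_equal(res$direction, 0)

  swapped <- site_chi_squared(scm, c("b1", "b2"), c("a1", "a2"), "chr1:20")
  straight <- site_chi_squared(scm, c("a1", "a2"), c("b1", "b2"), "chr1:20")
  expect_equal(swapped$stat, straight$stat)
  expect_equal(swapped$direction, -straight$direction)

  res0 <- site_chi_squared(scm, c("a1", "a2"), c("b1", "b2"), 3)
  expect_false(res0$testable)
  expect_true(is.na(res0$p))
})

# shared fixture: one planted 5-site DMR, flat background, high depth
planted_fixture <- function(seed = 21, multiplier = 3, depth = 1e6) {
  g <- generate_genome(1, 100, 2, 1, seed = 13)
  planted <- data.frame(chrom = "chr1", start_site = 40, n_sites = 5,
                        tissue_low = "a", tissue_high = "b",
                        multiplier = multiplier)
  mm <- flat_pair(g, planted = planted)
  design <- pure_design(5, depth)
  gen <- generate_count_matrix(mm$methylomes, design, seed = seed, genome = g)
  list(genome = g, truth = mm$truth, counts = gen$counts,
       sheet = sheet_from_design(design))
}

test_that("a planted DMR is recovered exactly; the FC gate engages", {
  fx <- planted_fixture()
  dmrs <- call_dmrs(fx$counts, fx$sheet, "b", "a")
  expect_equal(nrow(dmrs), 1)
  expect_equal(dmrs$start, fx$truth$planted_dmrs$start)
  expect_equal(dmrs$end, fx$truth$planted_dmrs$end)
  expect_equal(dmrs$n_sites, 5)
  expect_equal(dmrs$direction, "hyper")  # hyper in tissue b

  # region fold change sits near the planted multiplier (background dilution
  # shifts it slightly below 3)
  expect_gt(dmrs$fold_change, 2.4)
  expect_lt(dmrs$fold_change, 3.1)
  # raising fc_min above the realized FC empties the call set
  expect_equal(nrow(call_dmrs(fx$counts, fx$sheet, "b", "a", fc_min = 4)), 0)
})

test_that("comparing a group against itself yields no DMRs", {
  fx <- planted_fixture()
  expect_equal(nrow(call_dmrs(fx$counts, fx$sheet, "a", "a")), 0)
})

test_that("call_dmrs is invariant to sample order within groups", {
  fx <- planted_fixture()
  perm <- fx$sheet[sample(nrow(fx$sheet)), ]
  d1 <- call_dmrs(fx$counts, fx$sheet, "b", "a")
  d2 <- call_dmrs(fx$counts, perm, "b", "a")
  expect_equal(as.data.frame(d1), as.data.frame(d2))
})

test_that("tightening alpha or fc_min never increases the number of calls", {
  fx <- planted_fixture(multiplier = 2.2, depth = 2e5)
  n_calls <- function(alpha, fc) nrow(call_dmrs(fx$counts, fx$sheet, "b", "a",
                                                alpha = alpha, fc_min = fc))
  alphas <- c(0.05, 0.01, 0.001, 1e-6)
  counts_alpha <- vapply(alphas, n_calls, fc = 1, 0L)
  expect_true(all(diff(counts_alpha) <= 0))
  fcs <- c(1, 1.5, 2, 3, 5)
  counts_fc <- vapply(fcs, n_calls, alpha = 0.05, 0L)
  expect_true(all(diff(counts_fc) <= 0))
})

test_that("group resolution and zero-library errors are explicit", {
  fx <- planted_fixture()
  expect_error(call_dmrs(fx$counts, fx$sheet, "nope", "a"), "resolves to no samples")
})

test_that("DMRs are annotated by TSS, gene body and CpG island overlap", {
  ann <- annotation_set(
    genes = data.frame(name = c("gp", "gm"), chrom = "chr1",
                       tss = c(10000L, 40000L), tes = c(15000L, 35000L),
                       strand = c("+", "-"), stringsAsFactors = FALSE),
    cpg_islands = data.frame(chrom = "chr1", start = 20000L, end = 20400L))
  mk <- function(start, end) data.frame(
    id = "d", chrom = "chr1", start = start, end = end, n_sites = 2L,
    direction = "hyper", mean_rpm_1 = 1, mean_rpm_2 = 2, fold_change = 2,
    p_adjusted = 0.01, annotation = "", autosomal = TRUE, stringsAsFactors = FALSE)

  expect_equal(annotate_dmrs(mk(20100, 20200), ann)$annotation, "CpG_island")
  expect_equal(annotate_dmrs(mk(10500, 10600), ann)$annotation, "TSS")   # tss + 500
  expect_equal(annotate_dmrs(mk(11500, 11600), ann)$annotation, "gene_body")  # tss + 1500
  # minus-strand gene body: between TES and tss - 1kb
  expect_equal(annotate_dmrs(mk(36000, 36100), ann)$annotation, "gene_body")
  expect_equal(annotate_dmrs(mk(39500, 39600), ann)$annotation, "TSS")
  expect_equal(annotate_dmrs(mk(70000, 70100), ann)$annotation, "")
})

test_that("region RPM is additive and invariant to library scaling", {
  scm <- site_count_matrix(data.frame(chrom = "chr1", pos = c(10L, 20L, 50L)),
                           matrix(c(10L, 20L, 70L), 3, 1,
                                  dimnames = list(NULL, "s")))
  norm <- normalize_rpm(scm)
  one <- region_rpm(norm, list(chrom = "chr1", start = 10, end = 11))
  expect_equal(unname(one), 1e5)
  both <- region_rpm(norm, list(chrom = "chr1", start = 10, end = 21))
  expect_equal(unname(both), 3e5)
  expect_equal(region_rpm(norm, list(chrom = "chr1", start = 10, end = 21),
                          stat = "mean"), both / 2)

  doubled <- site_count_matrix(scm$sites, scm$counts * 2L)
  expect_equal(region_rpm(normalize_rpm(doubled),
                          list(chrom = "chr1", start = 10, end = 21)), both)
  expect_error(region_rpm(norm, list(chrom = "chr1", start = 900, end = 950)),
               "no sites")
})
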