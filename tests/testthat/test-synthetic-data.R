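test_that("genome generation is seed-deterministic and respects preconditions", {
  g1 <- generate_genome(1, 100, 5, 3, seed = 7)
  g2 <- generate_genome(1, 100, 5, 3, seed = 7)
  expect_identical(serialize(g1, NULL), serialize(g2, NULL))
  g3 <- generate_genome(1, 100, 5, 3, seed = 8)
  expect_false(identical(g1$sites$pos, g3$sites$pos))

  expect_error(generate_genome(1, 0, 5, 3, seed = 1), "sites_per_chrom must be >= 1")
  expect_error(generate_genome(0, 10, 5, 3, seed = 1), "n_chrom must be >= 1")
  expect_error(generate_genome(1, 4, 10, 1, seed = 1), "infeasible placement")
})

test_that("multi-chromosome genomes have strictly increasing site grids", {
  g <- generate_genome(2, 50, 6, 4, seed = 3)
  expect_equal(nrow(g$sites), 100)
  for (cn in g$chromosomes$name) {
    p <- g$sites$pos[g$sites$chrom == cn]
    expect_length(p, 50)
    expect_true(all(diff(p) > 0))
  }
  expect_true(all(g$genes$strand %in% c("+", "-")))
  expect_true(all(g$cpg_islands$start < g$cpg_islands$end))
})

test_that("null methylome design yields identical tissues", {
  g <- generate_genome(1, 50, 3, 2, seed = 1)
  mm <- flat_pair(g)
  expect_identical(mm$methylomes$a, mm$methylomes$b)
  expect_equal(nrow(mm$truth$planted_dmrs), 0)

  # nonzero noise, no planting: tissues differ only by background noise
  cfg <- methylome_config(c("a", "b"), baseline_range = c(0.1, 0.3), noise_sd = 0.02)
  mm2 <- generate_methylomes(g, cfg, seed = 2)
  expect_false(identical(mm2$methylomes$a, mm2$methylomes$b))
  expect_lt(max(abs(mm2$methylomes$a - mm2$methylomes$b)), 0.2)
})

test_that("planted DMRs impose the exact multiplier and are fully booked", {
  g <- generate_genome(1, 100, 3, 2, seed = 1)
  planted <- data.frame(chrom = "chr1", start_site = 10, n_sites = 3,
                        tissue_low = "a", tissue_high = "b", multiplier = 3)
  mm <- flat_pair(g, planted = planted)
  idx <- 10:12
  expect_equal(mm$methylomes$b[idx], rep(0.6, 3))
  expect_equal(mm$methylomes$a[idx], rep(0.2, 3))
  expect_identical(mm$methylomes$a[-idx], mm$methylomes$b[-idx])
  expect_equal(mm$truth$planted_dmrs$start, g$sites$pos[10])
  expect_equal(mm$truth$planted_dmrs$end, g$sites$pos[12] + 1L)

  many <- data.frame(chrom = "chr1", start_site = seq(1, 96, by = 5), n_sites = 2,
                     tissue_low = "a", tissue_high = "b", multiplier = 2)
  mm2 <- flat_pair(g, planted = many)
  expect_equal(nrow(mm2$truth$planted_dmrs), 20)
  expect_true(all(mm2$truth$planted_dmrs$direction == "hyper_in_high"))
})

test_that("methylome config rejects invalid planted designs", {
  g <- generate_genome(1, 20, 2, 1, seed = 1)
  bad_sites <- data.frame(chrom = "chr1", start_site = 19, n_sites = 5,
                          tissue_low = "a", tissue_high = "b", multiplier = 2)
  expect_error(flat_pair(g, planted = bad_sites), "off the site grid")
  expect_error(methylome_config(c("a", "b"), planted = data.frame(
    chrom = "chr1", start_site = 1, n_sites = 1,
    tissue_low = "a", tissue_high = "b", multiplier = 2)), ">= 2 consecutive sites")
  expect_error(methylome_config(c("a", "b"), planted = data.frame(
    chrom = "chr1", start_site = 1, n_sites = 2,
    tissue_low = "a", tissue_high = "b", multiplier = 1)), "multiplier")
  expect_error(methylome_config(c("a", "b"), planted = data.frame(
    chrom = "chr1", start_site = 1, n_sites = 2,
    tissue_low = "a", tissue_high = "zz", multiplier = 2)), "unknown tissue")
  # multiplier overshooting 1 clips with a message
  over <- data.frame(chrom = "chr1", start_site = 1, n_sites = 2,
                     tissue_low = "a", tissue_high = "b", multiplier = 8)
  expect_message(mm <- flat_pair(g, planted = over), "clips propensity")
  expect_equal(max(mm$methylomes$b), 1)
})

test_that("pure-tissue mixtures reproduce the single-tissue expectation", {
  g <- generate_genome(1, 100, 3, 2, seed = 1)
  planted <- data.frame(chrom = "chr1", start_site = 30, n_sites = 4,
                        tissue_low = "a", tissue_high = "b", multiplier = 3)
  mm <- flat_pair(g, planted = planted)
  design <- data.frame(sample_id = c("s_f0", "s_f1", "s_mix"),
                       source = c("a", "b", "a:0.5,b:0.5"),
                       depth = 1e6, stringsAsFactors = FALSE)
  gen <- generate_count_matrix(mm$methylomes, design, seed = 11, genome = g)
  cm <- gen$counts$counts
  # f = 0 / f = 1: expected counts proportional to the single methylome
  for (col in c("s_f0", "s_f1")) {
    p <- if (col == "s_f0") mm$methylomes$a else mm$methylomes$b
    mu <- 1e6 * p / sum(p)
    expect_lt(max(abs(cm[, col] - mu) / sqrt(mu)), 5)  # within 5 SD everywhere
  }
  expect_equal(gen$placental_fractions[["s_mix"]], 0)  # no placenta tissues here
  expect_error(generate_count_matrix(mm$methylomes, within(design, source <- "zz"),
                                     seed = 1), "unknown tissue")
  expect_error(generate_count_matrix(mm$methylomes,
                                     within(design, source <- "a:1.2,b:-0.2"),
                                     seed = 1), "\\[0, 1\\]")
})

test_that("empirical mixture means match the analytic Poisson mean", {
  # 200 sites, depth 1e6, f = 0.5, flat baseline; 50 replicates
  g <- generate_genome(1, 200, 2, 1, seed = 5)
  planted <- data.frame(chrom = "chr1", start_site = 50, n_sites = 10,
                        tissue_low = "a", tissue_high = "b", multiplier = 3)
  mm <- flat_pair(g, planted = planted)
  f <- 0.5
  mix <- f * mm$methylomes$b + (1 - f) * mm$methylomes$a
  mu <- 1e6 * mix / sum(mix)
  design <- data.frame(sample_id = "m", source = "b:0.5,a:0.5", depth = 1e6)
  reps <- vapply(1:50, function(k)
    generate_count_matrix(mm$methylomes, design, seed = 100 + k, genome = g)$counts$counts[, 1],
    numeric(200))
  emp <- rowMeans(reps)
  se <- sqrt(mu / 50)
  expect_lt(max(abs(emp - mu) / se), 5)
  expect_lte(mean(abs(emp - mu) > 3 * se), 0.02)  # ~99.7% of sites within 3 SE
})

test_that("expected counts are linear in the mixture fraction", {
  g <- generate_genome(1, 100, 2, 1, seed = 2)
  planted <- data.frame(chrom = "chr1", start_site = 20, n_sites = 5,
                        tissue_low = "a", tissue_high = "b", multiplier = 4)
  mm <- flat_pair(g, planted = planted)
  fs <- c(0, 0.25, 0.5, 0.75, 1)
  site <- 22  # inside the planted region
  means <- vapply(seq_along(fs), function(i) {
    f <- fs[i]
    src <- if (f == 0) "a" else if (f == 1) "b" else sprintf("b:%s,a:%s", f, 1 - f)
    design <- data.frame(sample_id = sprintf("s%d", 1:20), source = src, depth = 1e6)
    mean(generate_count_matrix(mm$methylomes, design, seed = 40 + i,
                               genome = g)$counts$counts[site, ])
  }, 0)
  mix_site <- function(f) {
    m <- f * mm$methylomes$b + (1 - f) * mm$methylomes$a
    1e6 * m[site] / sum(m)
  }
  analytic <- vapply(fs, mix_site, 0)
  expect_lt(max(abs(means - analytic) / analytic), 0.02)
  fit <- lm(means ~ vapply(fs, function(f) {
    m <- f * mm$methylomes$b + (1 - f) * mm$methylomes$a
    m[site] / sum(m)
  }, 0))
  expect_gt(summary(fit)$r.squared, 0.999)
})

test_that("count generation is reproducible and supports overdispersion", {
  g <- generate_genome(1, 50, 2, 1, seed = 1)
  mm <- flat_pair(g)
  design <- pure_design(3, 1e4)
  g1 <- generate_count_matrix(mm$methylomes, design, seed = 9, genome = g)
  g2 <- generate_count_matrix(mm$methylomes, design, seed = 9, genome = g)
  expect_identical(g1$counts$counts, g2$counts$counts)
  g3 <- generate_count_matrix(mm$methylomes, design, seed = 9, genome = g,
                              overdispersion = 0.5)
  expect_false(identical(g1$counts$counts, g3$counts$counts))
  expect_gt(var(as.numeric(g3$counts$counts)), var(as.numeric(g1$counts$counts)))
})

test_that("fragment generation plants the motif at the requested offsets", {
  g <- generate_genome(1, 10, 2, 1, seed = 1)
  expect_equal(nrow(generate_fragments(g, 1, 0, seed = 1)), 0)
  fr <- generate_fragments(g, 1, 25, offsets = 14, seed = 2)
  expect_true(all(fr$offset == 14))
  expect_true(all(substr(fr$sequence, 15, 18) == "CCGG"))
  expect_true(all(nchar(fr$sequence) == 32))
  fr2 <- generate_fragments(g, 1, 25, offsets = 14, seed = 2)
  expect_identical(fr, fr2)
  expect_error(generate_fragments(g, 1, 5, offsets = 30, seed = 1),
               "inside a 32-base fragment")
})
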