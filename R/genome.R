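#' Generate a toy genome with enzyme sites, genes and CpG islands
#'
#' Builds a small genome used throughout the synthetic-data pipeline: one or
#' more chromosomes carrying an ordered grid of recognition sites (the
#' positions at which a methylation-dependent restriction enzyme releases
#' fragments), plus gene models (TSS/TES/strand) and CpG islands for annotation
#' overlap. All coordinates are 0-based, half-open.
#'
#' Sites are laid down with random gaps between `gap_range[1]` and
#' `gap_range[2]` bp. Genes are anchored at distinct sites (their TSS is placed
#' at a site position) and given random lengths in `gene_length_range`; CpG
#' islands span a window around randomly chosen sites. Feature counts are
#' per genome, spread round-robin across chromosomes.
#'
#' @param n_chrom number of chromosomes (>= 1).
#' @param sites_per_chrom number of enzyme sites per chromosome (>= 1).
#' @param n_genes total number of genes (>= 1).
#' @param n_islands total number of CpG islands (>= 1).
#' @param seed integer seed; identical seeds give byte-identical genomes.
#' @param gap_range inter-site gap range in bp.
#' @param gene_length_range gene length range in bp.
#' @param island_halfwidth island extent around its anchor site, in bp.
#'
#' @return An object of class `toy_genome`: a list with `chromosomes`
#'   (data frame: `name`, `length`), `sites` (`chrom`, `pos`, strictly
#'   increasing per chromosome), `genes` (`name`, `chrom`, `tss`, `tes`,
#'   `strand`) and `cpg_islands` (`chrom`, `start`, `end`).
#' @examples
#' g <- generate_genome(2, 50, 6, 4, seed = 1)
#' nrow(g$sites)  # 100
#' @export
generate_genome <- function(n_chrom, sites_per_chrom, n_genes, n_islands, seed,
                            gap_range = c(60L, 180L),
                            gene_length_range = c(2000L, 6000L),
                            island_halfwidth = 250L) {
  n_chrom <- assert_count(n_chrom, "n_chrom")
  sites_per_chrom <- assert_count(sites_per_chrom, "sites_per_chrom")
  n_genes <- assert_count(n_genes, "n_genes")
  n_islands <- assert_count(n_islands, "n_islands")
  n_sites <- n_chrom * sites_per_chrom
  if (n_genes > n_sites)
    stop_msg("infeasible placement: %d genes requested but only %d sites available as TSS anchors",
             n_genes, n_sites)
  if (n_islands > n_sites)
    stop_msg("infeasible placement: %d CpG islands requested but only %d anchor sites available",
             n_islands, n_sites)

  with_seed(seed, {
    chrom_names <- sprintf("chr%d", seq_len(n_chrom))
    sites <- do.call(rbind, lapply(chrom_names, function(cn) {
      gaps <- sample(gap_range[1]:gap_range[2], sites_per_chrom, replace = TRUE)
      data.frame(chrom = cn, pos = 1000L + cumsum(gaps), stringsAsFactors = FALSE)
    }))
    chrom_len <- vapply(chrom_names, function(cn) {
      max(sites$pos[sites$chrom == cn]) + max(gene_length_range) + 2L * island_halfwidth + 1000L
    }, integer(1))
    chromosomes <- data.frame(name = chrom_names, length = unname(chrom_len),
                              stringsAsFactors = FALSE)

    # genes: distinct site anchors so TSS annotation is exercised by construction
    anchor_idx <- sample.int(n_sites, n_genes)
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    glen <- sample(gene_length_range[1]:gene_length_range[2], n_genes, replace = TRUE)
    tss <- sites$pos[anchor_idx]
    gchrom <- sites$chrom[anchor_idx]
    gmax <- chrom_len[gchrom]
    tes <- ifelse(strand == "+", pmin(tss + glen, gmax - 1L), pmax(tss - glen, 0L))
    genes <- data.frame(name = sprintf("gene_%03d", seq_len(n_genes)),
                        chrom = gchrom, tss = tss, tes = as.integer(tes),
                        strand = strand, stringsAsFactors = FALSE)

    isl_idx <- sample.int(n_sites, n_islands)
    cpg_islands <- data.frame(
      chrom = sites$chrom[isl_idx],
      start = pmax(sites$pos[isl_idx] - island_halfwidth, 0L),
      end = sites$pos[isl_idx] + island_halfwidth,
      stringsAsFactors = FALSE)
    cpg_islands <- cpg_islands[order(cpg_islands$chrom, cpg_islands$start), ]
    rownames(cpg_islands) <- NULL

    genome <- structure(list(chromosomes = chromosomes, sites = sites,
                             genes = genes, cpg_islands = cpg_islands),
                        class = "toy_genome")
    validate_genome(genome)
    genome
  })
}

#' Validate a toy genome's structural invariants
#'
#' Checks strictly increasing site coordinates per chromosome, in-range gene
#' coordinates and non-degenerate CpG-island intervals.
#'
#' @param genome a `toy_genome`.
#' @return the genome, invisibly; errors describe the first violation.
#' @export
validate_genome <- function(genome) {
  stopifnot(inherits(genome, "toy_genome"))
  for (cn in genome$chromosomes$name) {
    p <- genome$sites$pos[genome$sites$chrom == cn]
    if (length(p) && any(diff(p) <= 0))
      stop_msg("site coordinates not strictly increasing on %s", cn)
  }
  len <- setNames(genome$chromosomes$length, genome$chromosomes$name)
  g <- genome$genes
  if (nrow(g)) {
    bad <- g$tss < 0 | g$tes < 0 | g$tss >= len[g$chrom] | g$tes >= len[g$chrom]
    if (any(bad)) stop_msg("gene %s out of chromosome range", g$name[which(bad)[1]])
    if (!all(g$strand %in% c("+", "-"))) stop_msg("gene strand must be '+' or '-'")
  }
  isl <- genome$cpg_islands
  if (nrow(isl) && any(isl$start >= isl$end))
    stop_msg("degenerate CpG island at %s:%d", isl$chrom[which(isl$start >= isl$end)[1]],
             isl$start[which(isl$start >= isl$end)[1]])
  invisible(genome)
}

#' @export
print.toy_genome <- function(x, ...) {
  cat(sprintf("toy_genome: %d chromosome(s), %d sites, %d genes, %d CpG islands\n",
              nrow(x$chromosomes), nrow(x$sites), nrow(x$genes), nrow(x$cpg_islands)))
  invisible(x)
}

#' Simulate 32 bp enzyme fragments with the recognition motif at known offsets
#'
#' MeD-seq digestion releases 32 bp fragments carrying the methylated CpG near
#' the middle; valid fragments carry the recognition motif at a characteristic
#' distance from the read end. This generator plants the motif at offsets drawn
#' from a configurable law and records the planted offset so the positional
#' read filter can be tested against ground truth.
#'
#' Background bases are drawn from \{A, G, T\} only; because the motif is the
#' sole source of adjacent cytosines, the planted occurrence is guaranteed to
#' be the fragment's unique match.
#'
#' @param genome a `toy_genome` (provenance metadata for the fragments).
#' @param site row index into `genome$sites` the fragments notionally came from.
#' @param n number of fragments (>= 0).
#' @param offsets candidate 0-based motif start offsets from the 5' end.
#' @param probs sampling probabilities over `offsets` (default uniform).
#' @param motif IUPAC motif to plant (ambiguity codes are instantiated
#'   per fragment).
#' @param seed integer seed.
#'
#' @return data frame with columns `sequence` (32-base string), `offset`
#'   (planted 0-based motif start), `chrom`, `pos`.
#' @examples
#' g <- generate_genome(1, 10, 2, 1, seed = 1)
#' fr <- generate_fragments(g, 1, 5, offsets = 14, seed = 2)
#' all(nchar(fr$sequence) == 32)
#' @export
generate_fragments <- function(genome, site, n, offsets = 13:17, probs = NULL,
                               motif = "CCGG", seed = 1L) {
  stopifnot(inherits(genome, "toy_genome"))
  n <- assert_count(n, "n", min = 0L)
  if (n == 0L) {
    return(data.frame(sequence = character(0), offset = integer(0),
                      chrom = character(0), pos = integer(0)))
  }
  k <- nchar(motif)
  if (any(offsets < 0 | offsets + k > 32))
    stop_msg("motif offsets must keep the %d-base motif inside a 32-base fragment", k)
  site <- assert_count(site, "site")
  if (site > nrow(genome$sites)) stop_msg("site index %d beyond the site grid", site)
  iupac <- strsplit(c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
                      S = "CG", W = "AT", K = "GT", M = "AC", B = "CGT",
                      D = "AGT", H = "ACT", V = "ACG", N = "ACGT"), "")
  motif_chars <- strsplit(toupper(motif), "")[[1]]
  if (!all(motif_chars %in% names(iupac))) stop_msg("invalid IUPAC code in motif '%s'", motif)

  with_seed(seed, {
    off <- if (length(offsets) == 1L) rep(as.integer(offsets), n)
           else sample(offsets, n, replace = TRUE, prob = probs)
    seqs <- vapply(seq_len(n), function(i) {
      bases <- sample(c("A", "G", "T"), 32, replace = TRUE)
      inst <- vapply(motif_chars, function(ch) sample(iupac[[ch]], 1), "")
      bases[(off[i] + 1):(off[i] + k)] <- inst
      paste(bases, collapse = "")
    }, "")
    data.frame(sequence = seqs, offset = off,
               chrom = genome$sites$chrom[site], pos = genome$sites$pos[site],
               stringsAsFactors = FALSE)
  })
}
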