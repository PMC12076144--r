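---
title: "Count-based DMR calling and tissue-of-origin scoring for MeD-seq cfDNA data"
author: "medseqr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Count-based DMR calling and tissue-of-origin scoring for MeD-seq cfDNA data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medseqr)
```

## The measurement model

MeD-seq reads out DNA methylation with a methylation-dependent restriction
enzyme (LpnPI) that cuts only at methylated recognition sites, releasing 32 bp
fragments centred on the methylated CpG. After sequencing, a read is accepted
as a genuine digestion product when the recognition motif starts 13–17 bp from
either read end (`filter_fragments()`); everything downstream then works on
**counts of accepted fragments per recognition site**: methylation is not a
per-molecule beta value (as in bisulfite data) but a rate — the more often a
site is methylated across input molecules, the more fragments it yields.

This count nature drives every statistical choice in the package:

* coverage differences between samples are removed by reads-per-million (RPM)
  scaling, `value = count × 1e6 / library size` (`normalize_rpm()`);
* two groups are compared per site with a Pearson chi-squared test on the
  pooled 2×2 table `[[a, N1−a], [b, N2−b]]`, where `a`, `b` are the pooled
  site counts and `N1`, `N2` the pooled library sizes (1 df, no continuity
  correction) — a natural test for a difference of two count rates;
* a region's methylation in one sample is the sum of its RPM values over the
  region's sites (`region_rpm()`), the quantity all downstream scoring uses.

In maternal plasma, cell-free DNA (cfDNA) is a mixture: mostly fragments of
hematopoietic origin (buffy-coat methylome) plus a placenta-derived fraction
that grows across gestation. Methylation differences between pregnant and
non-pregnant cfDNA therefore reflect (i) the placental methylome scaled by the
placental fraction and (ii) pregnancy-induced changes in blood cells.

## DMR calling

`call_dmrs()` realizes the genome-wide sliding window as per-site testing plus
run merging:

1. every site with a nonzero pooled count in at least one group is tested;
   sites with zero counts in both groups carry no hypothesis and are excluded
   from the multiple-testing denominator;
2. p-values are Bonferroni-corrected over the tested sites; adjusted `p ≤
   alpha` (default 0.05, boundary inclusive) marks a site, with direction the
   sign of the pooled RPM difference;
3. maximal runs of marked, same-direction sites that are consecutive on the
   site grid are merged into regions (`max_gap_sites` widens the allowed gap;
   the default of 1 demands strict consecutiveness, and "sequentially"
   differential sites motivates the default `min_sites = 2`);
4. a region is reported when its fold change — larger group mean of per-sample
   region RPM over smaller — reaches `fc_min` (default 2).

The conservative pairing of Bonferroni with a fold-change floor is deliberate:
at genome scale, pooled chi-squared tests on large libraries detect biologically
negligible rate differences (including compositional shifts that RPM scaling
induces at *unchanged* sites when other sites change), and the FC ≥ 2 gate is
what removes them. The pooling itself is a modelling choice: counts are summed
across samples within a group before testing, so between-sample dispersion is
not modelled — a known limitation shared with the assay's established analysis
practice. The null simulations in the test suite show the family-wise rate is
controlled under Poisson noise; overdispersed data would inflate it, which is
why the synthetic generator exposes an overdispersion knob for sensitivity
checks.

Fold changes on regions with a zero group mean use half the smallest nonzero
per-sample region value as a pseudo-value; ties at `p = alpha` count as
significant; regions are reported half-open (`[first site, last site + 1)`),
0-based, BED-compatible.

`annotate_dmrs()` labels regions by overlap with TSS windows (1 kb either side
of the TSS), gene bodies (1 kb after the TSS to the TES, strand-aware) and CpG
islands; labels are non-exclusive.

## Binary and cumulative methylation scores

To attribute a DMR signature to candidate source tissues, each DMR gets an
ROC-derived threshold on region methylation (`fit_threshold()`): candidate
thresholds are midpoints between consecutive distinct pooled reference values,
and the fit maximizes Youden's J = sensitivity + specificity − 1 for
classifying the two reference sets. Ties prefer higher specificity (claiming
signature presence conservatively), then the larger threshold. The reference
sets are the same two groups that defined the DMRs. A query sample scores 1
on a DMR when its region methylation exceeds the threshold (equality scores 0;
midpoint candidates make that a measure-zero case), and the cumulative score
counts DMRs whose binary score matches the reference of interest — score 1 on
reference-hyper DMRs, score 0 on reference-hypo DMRs — with the **overlap
proportion** the matched count over the signature size.

Two properties matter for interpretation. The scores are invariant to positive
rescaling of all values (so RPM-scale differences between runs cancel), and
with thresholds fitted between two reference sets, a query mixture crosses a
DMR's threshold roughly when its mixture fraction passes the midpoint of the
reference fractions. Scoring dilute cfDNA against *pure-tissue* references
therefore yields flat near-zero overlap until the placental fraction
approaches half the pure-tissue level — which is why tissue-of-origin profiles
in cfDNA are built from cfDNA-defined reference sets (e.g. delivery vs
non-pregnant cfDNA), where thresholds sit inside the physiological fraction
range. The package's simulations reproduce this: overlap with the
pregnancy-cfDNA signature rises strictly with the placental fraction while
overlap with the leukocyte side falls.

## Gestational-age marker selection

The marker funnel chains three steps on DMRs called between first-trimester
and term placentas:

1. **Buffy-coat hypomethylation filter** (`buffycoat_filter()`): keep a DMR
   when at least 80% of buffy-coat samples score 0 on its binary threshold
   (boundary inclusive). High hematopoietic methylation otherwise masks the
   placental signal, since blood cells dominate cfDNA.
2. **Pearson selection** (`correlate_with_ga()`): correlate region methylation
   with gestational age (in days; `ga_days()` converts `"39+2"` notation
   exactly) across cfDNA samples, excluding non-pregnant donors, and select
   signed `r ≥ 0.7`. Signed, because the biologically expected markers rise
   with gestation (term-hyper markers gain signal both from placental
   maturation and from the growing placental fraction; declining markers are
   fighting the fraction trend and are correspondingly less clear — an
   optional `use_abs` flag captures them).
3. Marker panels are summarized per sample by summed region RPM
   (`marker_panel_score()`), and single markers compared between collection
   periods with Welch's t-test (`compare_marker()`; Welch rather than pooled
   variance, since group variances differ across gestation and the safer
   default costs little; raw p-values, no multiplicity correction at panel
   scale).

## Clustering

For heatmap-style reporting, region-by-sample RPM is row-standardized to mean
0, SD 1 with the population SD (`zscore_transform()`; zero-variance rows are
dropped and recorded), then clustered agglomeratively (`hierarchical_order()`;
Euclidean distance and average linkage by default — both configurable and
recorded in the output, since the assay literature does not pin them down).
Cophenetic group distances (`cophenetic_group_distance()`) quantify ordering
claims such as "second-trimester placentas sit between first trimester and
term".

## The synthetic study

`demo_dataset()` builds the whole study in silico so every stage is testable
against planted truth. Its defaults *are* the package's study conditions:

* **Genome**: 2 chromosomes × 1000 sites, random 60–180 bp gaps; 40 genes and
  20 CpG islands anchored at sites. Coordinates are 0-based half-open
  throughout (BED convention).
* **Methylomes**: a shared per-site baseline propensity `U(0.12, 0.22)` plus
  tissue noise (SD 0.005). Propensities are recovery rates — the relative rate
  at which a methylated fragment is released from a site — not beta values.
* **Planted structure**: 30 pregnancy-signature regions (placental tissues at
  3× baseline, leukocyte pinned to 0.02) and 10 reversed ones; 20 placental
  "aging" regions (first trimester vs term at 7× baseline, clipped at 1 —
  near-binary switches, with second-trimester tissues midway), of which 8 are
  term-hyper with leukocyte at 0.02 (the recoverable markers), 6 decline
  toward term, and 6 are term-hyper but masked by leukocyte methylation of
  0.8.
* **Samples** mirror the study design: 6 non-pregnant cfDNA, 10 cfDNA per
  collection period (longitudinal), 10 placentas per trimester, 10 buffy
  coats, small trophoblast sets. cfDNA is a
  leukocyte/placenta Poisson mixture with placental fraction
  `placental_fraction(ga)` interpolating 0.08 → 0.12 → 0.20 → 0.35 across
  trimesters and delivery.
* **Maturation**: each placenta-containing sample sits at a
  gestational-age-determined position along the first-trimester→term methylome
  gradient, plus an inter-individual jitter (SD 0.18). This heterogeneity is
  load-bearing: it is what makes second-trimester samples interleave with
  both neighbours in the dendrogram (a tight, homogeneous middle group merges
  as a block and its mean cophenetic distance to the far side ties with the
  extreme-to-extreme distance exactly).
* **Depth**: 5 × 10⁴ expected reads per sample over 2000 sites (~25 per
  site), the per-site coverage scale of a genome-wide run passing the assay's
  QC floor. Counts are Poisson (variance = mean); an optional Gamma–Poisson
  overdispersion parameter exists for robustness checks but is off by
  default, matching the chi-squared caller's count-rate assumptions.

All randomness flows from one integer seed through derived child seeds; a
fixed seed reproduces the dataset byte for byte.

What the generator does **not** emulate: fragment-length biology of real
cfDNA, sequence-dependent digestion efficiency, per-individual copy-number or
genetic variation, batch effects, and between-sample biological dispersion
beyond the maturation axis. Passing tests therefore demonstrate correctness of
the pipeline's statistics and the qualitative behaviour of its scores under
the mixture model — not performance on real sequencing data.

## Numerical and design choices worth knowing

* The chi-squared is computed in closed form, vectorized over sites, in double
  precision (pooled library sizes overflow 32-bit integers); the test suite
  pins it to the textbook Σ(O−E)²/E oracle and to `chisq.test(correct =
  FALSE)` at 10⁻¹⁰.
* The read filter measures the offset to the **first base** of the motif,
  window inclusive on both ends, and checks both orientations
  (reverse-complement symmetric); a fragment matching in both orientations
  counts once. The default motif `CCDG` is a documented stand-in for an
  LpnPI-style site, not a claim about the enzyme's exact recognition
  sequence; both motif and window are configurable.
* Degenerate inputs have defined behaviour: all-identical reference values
  error out in `fit_threshold()`; constant-and-equal groups give p = 1 in
  `compare_marker()`; zero-variance regions report an undefined correlation
  with a reason; zero-variance rows are dropped before clustering.
* `run_pipeline()` validates every referenced group against the sample sheet
  before computing anything, and reruns with the same config and seed are
  byte-identical (the manifest records a config hash and per-stage timings).

## Limitations

The pooled chi-squared ignores biological replication within groups; with
strongly overdispersed real data the Bonferroni+FC gate is the only guard, and
a per-sample count model (negative binomial / beta-binomial) would be the
natural extension. The ROC threshold uses region RPM sums; a mean-based
variant is available but the per-region statistic used in the assay literature
is not specified. Marker selection reports raw p-values and signed
correlations; neither is corrected for the number of candidate regions, by
design, because the funnel's specificity comes from the buffy-coat filter and
the planted-truth tests quantify exactly that.
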