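---
title: "Bulked-segregant SNP-index mapping with simulated RIL populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bulked-segregant SNP-index mapping with simulated RIL populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(slafbsa)
```

## The problem this package addresses

Bulked segregant analysis (BSA) with reduced-representation sequencing
localizes major quantitative trait loci (QTL) without genotyping every line
of a mapping population. Two DNA bulks are formed from the phenotypic
extremes of a biparental population — here, recombinant inbred lines (RILs)
derived by repeated selfing — and sequenced alongside the parents as
fixed-length SLAF (specific-locus amplified fragment) tags. At a marker
tightly linked to the trait, the two bulks are enriched for opposite
parental alleles; at an unlinked marker, both bulks look like a random
draw of the population.

The package implements the full inference chain on tabular tag data:

1. **Simulation** of an F8 RIL population on a genetic map, trait values
   with a planted QTL, extreme bulks, and per-tag read depths.
2. **Tag processing**: depth and SNP-count filters, sequence clustering
   into loci, and parent-polarized marker calling.
3. **SNP-index association scan** with an empirical percentile threshold
   and consecutive-marker hot-region detection.
4. **Validation statistics**: single-marker ANOVA with variance explained,
   allele-frequency summaries, and relative expression by `2^-ddCt`.
5. **Diagnostic marker design**: restriction-site search, digest-fragment
   prediction, and InDel amplicon sizing.

## The association statistic

For each tag, reads in a pool are classified by parental origin. With `M`
and `P` the male- and female-parent allele read counts, the SNP index of a
pool is `M / (P + M)`; it is undefined at zero depth, and such tags are
excluded before any threshold computation. The scan statistic is

```
delta = SNP_index(high bulk) - SNP_index(low bulk)  in [-1, 1]
```

`delta` is near +1 where the high bulk is fixed for the male-parent allele
and the low bulk for the female-parent allele. The association threshold is
the empirical nearest-rank 99.99% percentile of all defined deltas: sort
ascending and take the element at rank `ceiling(q * N)`. This integer rule
guarantees that at most `floor((1 - q) * N)` markers *strictly* exceed the
threshold, and it reproduces exactly (no interpolation). Note that the
count of markers *at or above* the threshold is at least
`N - ceiling(q * N) + 1`, which for `q = 0.9999` and `N = 20000` is 3 of
20,000 (1.5e-4): only the strict-exceedance fraction is bounded by
`1 - q`.

A *hot region* is a maximal run of at least three markers with
`delta >= threshold` that are **consecutive in the per-chromosome marker
ordering** — not a centimorgan window. This reading is forced by observed
region geometry: regions with three markers and a genetic span of 0 cM can
only arise from adjacency in the marker list at a shared map position. The
scan is one-sided by default (the high-trait allele is assumed to come from
the male parent); a `two_sided` flag scans `|delta|` for traits whose
increasing allele comes from the female parent.

## The simulator and what it emulates

`simulate_ril_population()` builds lines by explicit generation-by-
generation selfing from a uniformly heterozygous F1 (single-seed descent),
rather than using the closed-form RIL map expansion. Each gamete picks a
random starting homolog and switches between homologs with the Haldane
(no-interference) recombination fraction `r = (1 - exp(-2d/100))/2` implied
by the inter-locus distance `d` in cM; chromosome boundaries switch with
probability 1/2 (independent assortment). Explicit selfing yields realistic
residual heterozygosity — at F8 the expected heterozygote fraction per
locus is `(1/2)^7 ~ 0.78%` — which the closed form would discard.

Phenotypes are additive: genotype codes P/H/M map to -1/0/+1 per QTL, and
`phenotype = mu + sum(effect * code) + Normal(0, sigma_e)`. A QTL not
coincident with a map locus is snapped to the nearest locus on its
chromosome so the genotype matrix remains the single source of genetic
state. The helper `effect_for_pve()` converts a target single-QTL variance
fraction `pve = a^2 / (a^2 + sigma_e^2)` into the additive effect `a`.

Bulks take the `bulk_size` largest and smallest phenotypes (default 30 of
150 lines, the reference design). Selection is a stable ascending sort by
(phenotype, line index): ties are resolved deterministically, and the low
and high bulks are always disjoint.

Read depths per tag and source are Poisson with a common mean (default
50x; the reference protocol does not publish a per-bulk mean depth, so
this is a configuration choice, stated openly here). Allele counts are
binomial draws at the bulk allele frequency (heterozygous lines contribute
1/2), perturbed by a symmetric allele-flip error
`f' = f(1 - e) + (1 - f)e` with default `e = 0.001`. There is no
base-quality model: raw-read quality filtering happens upstream of the tag
tables this package consumes. The number of SNPs per simulated tag is
`1 + Poisson(0.5)`, a one-time generator choice giving mostly 1-2 SNP tags
with a small tail beyond the 3-SNP filter boundary.

Features of real SLAF data the generator does **not** emulate: overdispersed
depths (PCR duplicates, GC bias), mapping and clustering artifacts from
repetitive genomes, segregation distortion, multi-QTL genetic architecture,
and linkage disequilibrium with population structure. Passing simulation
tests therefore demonstrates correctness of the inference chain under the
stated sampling model, not robustness to every artifact of a real
sequencing campaign.

## Tag filters and marker calls

Filters mirror the reference processing rules with inclusive boundaries:
a tag is kept iff *each* parent's total tag depth is at least 5x and the
tag has at most 3 SNPs. Clustering groups equal-length tag sequences whose
identity strictly exceeds 0.90 — "more than 90% similarity" is read
literally as a strict inequality — using greedy assignment in descending
depth order against cluster representatives, with Hamming identity
(`N` matches nothing). Alignment-based clustering is out of scope because
size-selected SLAF tags are fixed-length fragments.

Marker polarization ("same genotype as one parent") is quantified here as
a purity threshold: at least 95% of each parent's reads must carry that
parent's allele, near-fixed in opposite directions. The 0.95 default is a
package parameterization — the reference pipeline worked from genotype
calls and publishes no number — chosen to tolerate the simulated
sequencing error without misclassifying parents at 50x depth; it is
exposed as `purity` in `call_parent_markers()` and `bsa_config()`.

## Association validation statistics

`marker_anova()` is a two-class one-way ANOVA; variance explained is
eta-squared, `100 * SS_between / SS_total`. For a two-class layout this is
algebraically `100 * F / (F + n - 2)`, exposed as `pve_from_f()` so a
printed F statistic and population size suffice to recover a printed PVE.
Both routes are verified against each other and against hand-computed sums
of squares in the test suite. Missing genotypes are dropped with a count;
no multiple-testing correction is applied by default because validation
tables conventionally report per-environment significance.

## Numerical and design choices

- **Nearest-rank percentile, no interpolation**: reproducibility of the
  integer rule; a `round(q * N, 9)` guard prevents floating-point
  overshoot of exact integer ranks (e.g. `0.9999 * 10000`).
- **Coordinates for digestion are 0-based, half-open**; fragment lengths
  are first differences of `(0, cuts..., length)` and always sum to the
  amplicon length. Palindromic recognition sites are counted once, in
  forward orientation. Type IIS cut offsets may exceed the pattern length;
  cuts outside the amplicon are discarded.
- **Enzyme definitions** ship as an editable TSV (name, IUPAC pattern,
  top-strand cut offset) seeded with AluI, MluCI, BstNI, BsmAI and EcoRI
  from public catalogue conventions; tests use synthetic amplicons since
  no real amplicon sequences are required.
- **Tie and degeneracy rules** are deterministic everywhere: bulk
  selection by line index, clustering by input order, marker ordering by
  `(chrom, pos_cM, tag_id)`, zero-length digest fragments dropped.
- **Seeding**: every stochastic function takes an explicit seed;
  `run_pipeline()` derives per-stage seeds from the config seed, so
  identical configs give byte-identical artifacts.
- **Scan polarity**: bulk labels `aa`/`ab` in the SNP-index formulation
  are fixed here as high-trait/low-trait bulks respectively, and the
  default scan is one-sided on raw (not absolute) delta; both choices are
  flagged (`two_sided`).

## Problem sizes used in the automated checks

Simulation-based checks run at sizes chosen to make sampling error small
relative to the tested effect: 10,000 lines for heterozygosity decay and
independent assortment, 20,000 lines for two-locus recombination against
an exact transfer-matrix enumeration, 500 seeded replicates of a 150-line
population for variance-explained calibration, ten replicates of a
10-chromosome x 2,000-tag genome for null-threshold calibration, and 200
seeded replicates of a 3-chromosome x 2,000-tag genome (150 cM per
chromosome) for QTL recovery.

## Known limitations

- **Hot-region recovery at moderate QTL strength.** With a single QTL
  explaining 25% of trait variance in 150 lines, truncation selection of
  30-line bulks leaves the bulk allele frequencies near 0.9/0.15 — far
  from fixation. At 50x depth, `delta` then essentially never reaches 1,
  so the 99.99% nearest-rank threshold sits at (or within a rank or two
  of) the sample maximum and flags only one to three scattered markers:
  the three-consecutive-marker rule cannot fire, even though the top
  deltas localize tightly around the QTL. Hot-region detection under this
  rule is effectively a *fixation detector*: it requires bulks nearly
  fixed for opposite alleles, i.e. a very strong QTL (the shipped
  `bsa_demo_config()` plants PVE 0.8, where delta saturates at 1 and
  regions recover reliably), low sequencing depth (which saturates
  indexes by sampling), or a lower fixed threshold. The 200-replicate
  recovery check in the test suite documents this behaviour honestly
  rather than relaxing the scan rule.
- The simulator's Poisson depth model has no overdispersion; real tag
  depth distributions are heavier-tailed, which widens the null delta
  distribution and makes the empirical threshold *more* conservative.
- Composite interval mapping, sliding-window SNP-index smoothing, and
  confidence intervals on delta are out of scope; the association layer
  is single-marker by design.

## A worked demonstration

```{r demo, eval = FALSE}
run <- run_pipeline(bsa_demo_config(seed = 42))
run$counts
run$regions[, 1:5]
glance(run$assoc)
autoplot(run$scan)
```

The demo plants a strong QTL on `chr2` at 75 cM; the scan finds a hot
region overlapping it, and the single-marker ANOVA at the QTL locus
reports the planted effect with its variance explained.
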