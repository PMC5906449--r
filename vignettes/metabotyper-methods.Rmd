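---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabotyper)
```

This vignette documents the statistical models behind each analysis
stage, the parameters that matter (with units and defaults), what the
synthetic-data generators emulate — and deliberately do not — and the
numerical choices made where a design was genuinely open.

## The study design the package serves

A panel of fully sequenced, inbred fly lines is profiled for a small
metabolite panel (triacylglycerol, total protein, free glycerol,
lactate, glycogen, glucose, per animal) in three strata: late
third-instar larvae (mixed sex) and six-day-old adult females and males.
The same lines are genotyped at biallelic SNPs, some are sequenced for
gut 16S composition, and a diet-shift arm rears animals on a low sugar
diet (LSD) before maturing them on LSD, standard (SD) or high sugar
(HSD) food. The package implements the analysis chain over these four
data types; the wet-lab stages (rearing, assays chemistry, 16S library
preparation, read processing) and the external mixed-model association
tool are out of scope — the package post-processes association output
and offers only a deliberately naive single-marker scan for testing.

## Assay quantification

Plate assays are modelled as linear in concentration:
`reading = a·conc + b`. Curves are fitted by ordinary least squares
*with* an intercept: blanks are part of every standard series and the
intercept absorbs plate background; forcing the line through the origin
would push background into the slope. Quantification inverts the curve
and undoes dilution and pooling:

```
conc   = (reading − b) / a × dilution
amount = conc × volume / n_animals        # per animal
```

Dilutions are per assay × stage × sex (e.g. glycogen: larvae 1:2, males
1:3, females 1:6 basal and 1:10 in the diet-shift arm); homogenisation
volume is an explicit parameter because it differs between assays and is
not a universal constant. Readings that imply a concentration below the
blank are flagged below-detection and stored as missing, never negative.
Glycogen is the floored difference of the digested and undigested
glucose-oxidase readings. Citrate-synthase activity converts the DTNB
absorbance slope with reaction volume 0.22 mL, sample volume 0.02 mL,
path length 0.63 cm and ε(TNB²⁻) = 13.6 mM⁻¹cm⁻¹ as defaults; the
conversion is linear in ΔA and dilution and inversely linear in enzyme
volume, which the tests assert directly.

## Normalisation

Two normalisations serve different questions:

* **Column z-scores** (mean 0, SD 1 per metabolite) precede clustering
  and PCA, so metabolites with very different absolute scales weigh
  equally. Zero-variance columns are an error, named.
* **Percent-of-maximum** expresses each *line mean* (replicates averaged
  first) as a percent of the largest line mean in its
  metabolite × stage × sex group; the top line maps to exactly 100. An
  alternative reading of "percent normalised among lines" —
  percent-of-sum — was considered; percent-of-max was chosen because it
  preserves the interpretation "percent of the best-provisioned line"
  and makes the group maximum a checkable invariant. The choice is
  immaterial for diet-shift responses: the response
  `(shifted − baseline)/baseline × 100` cancels any scaling shared by
  the two arms, an invariance the suite tests explicitly.

Below-detection values (larval glucose, typically) are imputed as half
the smallest observed value of their column *before* z-scoring — the
standard left-censoring convention — so whole lines are not lost to one
censored metabolite.

## Metabotypes, PCA and virago calling

Metabotypes are k-means clusters of normalised profiles; the best of
`n_init = 50` random restarts by within-cluster sum of squares is kept
and the seed is required, so assignments are reproducible. Defaults:
k = 3 on a combined larva/female/male panel (the coarse stratum
structure) and k = 6 for larva-only prototypes; clustering operates on
line-level profiles or replicates as the caller chooses — the tests use
replicates, which is the stricter recovery problem. On tiny instances
the restart scheme provably reaches the global optimum; the suite checks
this against exhaustive enumeration of all 2-partitions.

PCA is the eigen-decomposition of the covariance of the z-scored
columns. Signs are fixed by making the largest-magnitude loading of each
component positive — a pure convention that makes scores comparable
across runs.

A *virago* line has adult females with a male-like profile. The printed
version of this call is visual (female points inside the male cluster of
a PCA); the package's reproducible analogue clusters the adult samples'
top-2 principal-component scores with 2-means, requires each cluster to
have a clear sex majority (otherwise the clustering is degenerate and an
error is raised), and flags every line whose mean female score is closer
to the male-cluster centroid than to the female one. Distances are
reported as evidence.

## Correlations and the fecundity comparison

Correlation matrices use Spearman's rank correlation on line means with
midrank ties and pairwise-complete observations (per-pair n is reported
so downstream can audit). P-values come from the AS89 algorithm as
implemented in `stats::cor.test`: the exact tail distribution for
tie-free n ≤ 9 and an Edgeworth series beyond; a t-approximation
variant is available (`method = "t"`) because figure legends and methods
sections in this literature differ on which was used. Two quirks are
handled explicitly: the Edgeworth tail can underflow to exactly zero, so
p-values are floored at `2/n!` (the smallest attainable two-sided
permutation p); and constant variables yield undefined coefficients,
emitted missing with a warning. The suite validates the exact path to
1e-12 against full permutation enumeration and the approximation path
against a 200 000-draw Monte-Carlo tail. Significance filtering is a raw
p < α mask (α = 0.05 by default) because that is the filter this kind of
study applies; a multiplicity correction across the matrix is
deliberately not applied by default.

The egg-laying comparison is a one-way ANOVA followed by two-sided
pooled-SD t-tests of every candidate line against every control line,
Bonferroni-multiplied by the number of comparisons and capped at 1.

## Allele sharing and group-unique alleles

For two inbred lines, sharing of an allele class is
`100 × #(both carry the class) / #(both called)` — the denominator is
jointly callable sites, which reproduces the characteristic magnitudes
of such data (alternative-allele sharing in single digits, reference
sharing around three quarters); heterozygous or multi-allelic calls are
treated as missing because the lines are inbred. The all-pairs values
form the empirical null distribution; its mode is the midpoint of the
fullest histogram bin (width 0.5 percentage points, ties to the lower
bin), and a line group's summary is the mean of its within-group pair
values. A site is group-unique for a class when every group member
carries that class (non-missing) and no non-group line does; both class
lists are returned. All of these operations are checked against
site-by-site enumeration oracles on small matrices.

## GWAS post-processing

Filtering is strict (`p < threshold`, conventionally 1e-5) and
idempotent. Per-trait counts partition unique variants into
gene-associated (non-empty symbol) and unclear. Condition overlap
intersects unique variant ids and unique gene symbols case-sensitively.
Manhattan preparation lays chromosomes end to end and emits −log10 p
with threshold lines at 1e-5 and 1e-7 by default. The bundled
`naive_association_scan` regresses trait line means on allele dosage per
site with a minor-carrier threshold (default 4 lines); it exists so
end-to-end tests have a scan whose type-I error and power can be
verified, and it makes no claim of equivalence to a mixed-model
association tool (no relatedness, inversion or symbiont covariates).

## Microbiome tables

The taxon filter retains a species if it lies in the minimal
cumulative-abundance prefix reaching 95% in at least one sample — the
stacked-bar-chart reading of "top 95% most abundant in at least one
sample"; a rank-percentile reading was considered and rejected because
it ignores "most abundant". Genus rollup sums member species and
commutes with closure to relative abundances. The correlation pipeline
excludes configured lines and taxa first — the usual rule drops the
Wolbachia genus and any Wolbachia-infected line, because Wolbachia is an
intracellular endosymbiont, not a gut resident — then log10-transforms
(pseudocount 1 on counts; rank statistics are unaffected by the
pseudocount choice) and applies the filtered Spearman analysis at
species and genus level. Hierarchical clustering defaults to
Bray–Curtis dissimilarity with average linkage, the standard pairing for
compositional 16S data; samples are pre-sorted by id so ties break
deterministically.

## The synthetic-data generators

The generators define the study conditions under which every recovery
claim is tested. Design choices:

* **Log-scale generation.** Amounts are drawn on the log scale and
  exponentiated: positivity is automatic and the data are right-skewed
  like real assay measurements. Effect sizes are dimensionless
  "SD units"; one unit maps to 0.2 log units, i.e. a ~20% replicate
  coefficient of variation, typical of plate assays. Censoring below a
  configurable detection floor stores values as missing.
* **Structure hierarchy.** Stage/sex offsets (default 12 SD units along
  fixed biological patterns: females store more TAG/glycogen, larvae
  less glycogen/glucose, larval lactate 20-fold above adults) dominate
  metabotype offsets (default separation 5 SD units), matching real
  panels where stage and sex move energy stores far more than
  line-to-line variation. Metabotype centroids are mutually orthogonal
  directions drawn in the orthogonal complement of the stage/sex offset
  subspace, so within-stratum cohort structure cannot leak into the axes
  separating the strata; without this, k-means on the combined panel
  occasionally splits the widest stratum instead of separating the
  sexes. The 12-unit default was chosen by verifying stratum recovery
  across a seed sweep, since only qualitative separability is specified
  for these offsets.
* **Viragos.** A virago line's female samples are drawn from the male
  distribution (male stratum offset and male cohort effect), which is
  the strongest version of "male-like profile" and makes
  precision/recall well-defined.
* **Genotypes.** Sites are independent Bernoulli draws at a
  Beta-distributed alternative-allele frequency (no linkage
  disequilibrium — a stated non-goal). Group-unique alleles are planted
  exactly; after the missing-call mask, background sites that became
  group-unique by chance are repaired, so the planted lists are exactly
  the discoverable sites except where a group member's own call was
  masked — the degradation mode the recovery tests measure.
* **Abundances.** One multinomial count profile per panel sample at a
  fixed depth (rows sum to the depth exactly), from log-scale weights:
  a community baseline dominated by Acetobacter and Lactobacillus, a
  per-line composition offset (so samples cluster by line, not diet),
  and per-sample noise. A Wolbachia-infected line receives half its
  reads from Wolbachia; all other samples have structurally zero
  Wolbachia counts. Planted metabolite–taxon links use a Gaussian
  copula whose mixing angle is calibrated against the closed relative
  abundance on the realised sample: an unconditional copula would leave
  the achieved Spearman a full sampling SD (~0.15 at n = 30) from
  target, defeating the stated ±0.15 tolerance, whereas calibration
  absorbs both the sampling error and compositional attenuation.
* **Seeding.** Each generator derives per-stream sub-seeds
  deterministically from the master seed, so enlarging one stream (more
  taxa, say) does not perturb another; identical configs reproduce
  byte-identical outputs.

What the generators do **not** emulate — and hence what green tests do
not show about real data: linkage disequilibrium and population
structure among lines, relatedness-driven confounding in association
scans, sequencing batch effects and compositional zero-inflation beyond
the multinomial, assay plate effects, and any nonlinear
metabolite–taxon relationship (planted links are monotone by
construction).

## Problem sizes and numerical choices

The default validation runs use 35 lines × 3 strata × 3 replicates
(315 samples), 500–2000 genotype sites, 10-line/≈60-sample microbiome
panels over 20 seeds, and 10 null traits × ~500 sites for scan
calibration — sizes at which every planted effect is recoverable and the
full suite runs in well under a minute. Ties in the sharing histogram
mode go to the lower bin; k-means uses 50 restarts with a required seed;
PCA signs follow the dominant-loading convention; percent responses at
zero or missing baselines are missing, not infinite; and the glycogen
difference is floored at zero with a flag rather than an error, because
a small negative difference is ordinary measurement noise.

## Known limitations

The naive association scan is a testing stand-in, not a GWAS method.
AS89 p-values beyond n = 9 inherit the accuracy of the Edgeworth
expansion (verified here to ~0.005 against Monte-Carlo permutation).
Reproducing the published shared-allele percentages requires the
external panel genotypes; the package ships the operations and verifies
them on planted synthetic matrices instead. Exact reproduction of
supplementary-table counts is demonstrated on synthetic association
tables that plant those counts, since the published sheets are not
redistributable inside the package.
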