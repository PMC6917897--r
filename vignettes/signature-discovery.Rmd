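---
title: "Methods: spatial gene-signature discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial gene-signature discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`brainsig` discovers gene signatures of a cognitive function by correlating
the spatial pattern of brain gene expression with a volumetric
functional-association map, characterizing the resulting ranking with
pre-ranked gene-set enrichment, and validating the candidate genes with
evidence-based statistics. This vignette is the package's account of the
method: the model at each stage, its assumptions, the parameters that
matter, the numerical conventions, and what the synthetic benchmark does
and does not establish.

## The statistical model, stage by stage

### Preprocessing

The input is probe-level microarray expression per donor, each sample a
point in a common stereotactic space with a compartment label (cortical or
subcortical) and a shared anatomical region label.

* **Background filter.** A probe is retained when its fraction of
  above-background samples is at least 0.5, computed over all of a donor's
  samples. The boundary is inclusive: exactly 50 % passes, since what is
  excluded is "fewer than half". A probe must pass in *every* donor to be
  kept, so all donors share one probe universe.
* **Differential stability (DS).** For each probe, expression is averaged
  within region labels per donor; DS is the mean over donor pairs of the
  Pearson correlation between the two donors' region-mean vectors,
  restricted to regions sampled by both. Pairs sharing fewer than two
  regions are excluded; a probe with no valid pair is flagged undefined
  and its gene is dropped if no sibling probe survives. Pearson
  correlation over matched region means is the established reading of
  differential stability and has trivially verifiable limits (identical
  profiles give 1, reversed profiles give −1), which is why the package
  uses it.
* **Probe selection.** Per gene, the surviving probe with maximal DS wins;
  ties go to the lexicographically smallest probe id so the choice is
  deterministic.
* **Normalization.** Gene rows are z-scored within each donor and
  compartment separately (cortex and subcortex have grossly different
  expression baselines, and donors have different scales). The sample
  standard deviation (n − 1 denominator) is used; zero-variance rows
  become all-zero and are flagged rather than propagating NaN. A
  donor-compartment with one sample cannot be normalized and is an error.
  Genes dropped in any donor are dropped globally: the downstream ranking
  is a single per-gene statistic across donors, so every donor must score
  the same universe.

### Co-registration

Samples are snapped to voxels by applying the inverse affine and rounding
half away from zero (a deterministic, platform-stable rule; R's default
round-half-to-even would make voxel assignment depend on parity at exact
boundaries). All spatial logic goes through the 4×4 affine, so anisotropic
or rotated grids work even though the simulator only emits diagonal
affines.

Samples whose voxel z score is not strictly positive are excluded —
negative z reflects association with *other* functions and z = 0 carries
no signal. Masking can leave a donor-compartment empty; such donors are
excluded from the correlation for that compartment and recorded, mirroring
the variable per-donor retention real data shows.

Expression is then smoothed: each retained sample's value is replaced, per
gene and donor, by the unweighted mean over all retained samples within a
6 mm Euclidean radius (including itself). Two deliberate choices:

* **Sample space, not voxel space.** The transcriptome is a sparse point
  set; averaging over the sample sphere is deterministic,
  resolution-independent, and needs no rasterization. This may differ from
  the internals of tools that smooth a rasterized volume.
* **Smoothing after masking.** Only retained samples contribute: excluded
  voxels carry no usable functional signal, so letting them leak into
  their neighbors' averages would dilute the comparison. The opposite
  order is defensible; this package's order is stated so results are
  interpretable.

Smoothing is a row-stochastic linear operator: outputs stay within the
per-gene range of the inputs, and radius 0 is the identity.

### Spatial correlation and the ranked list

Each donor's slope and intercept are fit individually (ordinary least
squares of expression on z), and the Pearson correlation *r* is the
statistic carried forward. Donors are combined by the *approximate random
effects* mean: the unweighted arithmetic mean of the valid per-donor *r*
values. No variance weighting and no Fisher transform are applied by
default — the plain average across donors is the combination rule the
method defines; `random_effects_mean(..., fisher = TRUE)` is available for
sensitivity analyses. Undefined per-donor *r* (zero variance, or fewer
than 3 retained points) leads to exclusion of that donor for that gene;
genes with fewer than two valid donors are excluded entirely, because a
one-donor "mean" is not a random-effects statistic. Genes are ranked
descending by mean *r*, ties broken by gene id.

### Pre-ranked enrichment

The enrichment score of a set with N_H members in a list of N genes is the
signed maximum deviation of a running sum that gains `|r̄|^p / N_R` at
members (N_R the sum of member weights) and loses `1/(N − N_H)` at
non-members. The weight exponent defaults to p = 1 (the "weighted"
statistic); p = 0 recovers the classic Kolmogorov–Smirnov form, a property
the test suite checks against a brute-force KS oracle. The implementation
evaluates the curve only at its breakpoints (closed form), which is exact
and linear in set size; the suite verifies equality with a full
running-sum walk to 1e−12 and with an independent GSEA implementation
(`fgsea`).

Because a pre-ranked analysis has no phenotype labels to permute, the null
is gene-tag permutation: ES values of random same-size sets drawn without
replacement from the universe (default 1000 permutations, cached per set
size). Normalization and significance follow the sign-stratified ratio
procedure: NES = ES / mean(|same-signed null ES|); the nominal p is the
fraction of same-signed null ES at least as extreme (floored at
1/(n_perm+1) and flagged when no null shares the sign); the FDR q of a set
is the fraction of pooled same-signed null NES at least as extreme as its
NES divided by the fraction of observed same-signed NES at least as
extreme, capped at 1. Significant sets (q < 0.05) split by ES sign into
S⁺ and S⁻; an empty S⁺ or S⁻ is a valid outcome that downstream stages
skip gracefully, not an error.

The leading edge of a positively enriched set is its members at ranks up
to the running-sum peak; for a negative ES, members at or after the
trough. Candidate lists count each gene's leading-edge memberships across
significant same-sign sets and rank by count, then by |mean r̄| (the more
extreme correlation first — the tie-break a count tie leaves is between
genes the ranking itself orders by magnitude), then by gene id, truncated
to 10.

### Overlap and over-representation

The cortical/subcortical comparison intersects the significant set ids and
the member-gene unions of the significant sets, reporting
`100 · shared / union` rounded half-up to one decimal. Partitioned gene
lists (shared, cortex-only, subcortex-only) can be tested for
over-representation against any library: upper-tail hypergeometric
probability of at least the observed overlap, Benjamini–Hochberg adjusted
across the tested sets.

### Validation statistics

* **Chance probability.** The probability that all N pool hits of a
  top-10 candidate list would occur by drawing without replacement from a
  pool of K known genes out of M analyzed is the product form
  `Π_{i=0..N−1} (K−i)/(M−i) = C(K,N)/C(M,N)`. The product form (all N
  draws land in the pool), rather than a hypergeometric tail over the
  list length, is the model that reproduces the published values across
  every configuration, and the suite cross-checks it against a
  binomial-coefficient oracle.
* **Precision scores.** Strong evidence counts 1, weak evidence ½, strong
  and weak being mutually exclusive per function; the memory and motor
  scores are each side's weighted count over their sum, so they add to 1
  whenever any evidence exists. A list with no evidence at all is flagged
  undefined rather than scored 0/0.
* **Correlation differences and bootstrap.** For member genes of each
  significant set, the difference between the target-analysis and
  control-analysis mean *r* is taken, multiplied by −1 for negative lists
  so that support for the method is always positive. The differences are
  subsampled without replacement (10,000 iterations by default) to a
  common size, and the mean is declared significantly different from zero
  when the central 95 % interval — the 2.5th and 97.5th percentiles of
  the iteration means, linear interpolation between order statistics
  (quantile type 7) — strictly excludes 0. An interval touching 0 exactly
  is *not* significant; "subsampling" is read as without replacement, with
  a `replace` flag for the alternative.

## The synthetic-data generator

`simulate_study()` generates every input the pipeline consumes under a
single master seed (per-stage seeds are derived by fixed offsets, so each
stage is independently reproducible; identical configurations give
byte-identical outputs).

What it emulates, and the defaults chosen as the benchmark's study
conditions:

* **Term map** — a volume (default 40³ voxels of 2 mm) with spherical
  positive-z foci (default 4 foci of 10 mm radius; peak z uniform in
  [2, 8], decaying linearly to a strictly positive floor at the boundary)
  over a zero background with ~2 % scattered negative-z voxels. Focus
  centers alternate between the cortical half (upper third axis) and the
  subcortical half so both compartments contain signal.
* **Samples** — per donor (default 4) and compartment, 100 points drawn
  without replacement from voxel centers, stratified so at least half lie
  in positive-z voxels (so the masked analysis keeps enough points); a
  4³ block partition of the volume provides shared region labels.
* **Expression** — a planted gene with sign s and target correlation ρ
  (default 0.8) has gene-level signal `s·ρ·z̃ + sqrt(1−ρ²)·ε` with
  `ε ~ N(0, 1)` and z̃ the map value standardized within
  donor-compartment, which makes the population per-donor correlation
  equal ρ analytically and enables parameter-recovery tests. Default 60
  positively and 60 negatively planted genes among 2000. Gene- and
  compartment-specific baselines give the compartments distinct raw
  levels, which the z-scoring must remove. Each gene has 3 probes: probe
  1 adds N(0, 0.1) measurement noise (the intended
  differential-stability winner), decoys add N(0, 2), and 30 % of decoys
  are flagged below background in well over half of every donor's samples
  so the background filter has a known correct action.
* **Gene sets** — default 50 sets, 5 planted (alternating sign, sizes
  40–60, 90 % of members from the planted pool of their sign, cycling
  through the pool so every planted gene is covered by at least one
  planted set); null sets are uniform draws with sizes 15–100. Set order,
  member order, and planted gene identities are shuffled/drawn at random,
  so nothing about planting is recoverable from file ordering.
* **Evidence and pools** — the known-memory pool is the planted genes
  plus 5 % of null genes; a disjoint motor pool is drawn at the same
  size. Planted genes receive memory evidence with probability 0.9,
  non-planted pool members 0.6, genes outside a pool never — so flag
  prevalence among planted genes exceeds the null prevalence several-fold
  and strong/weak exclusivity holds by construction.

What it does **not** emulate: anatomically realistic geometry, hemispheric
asymmetry, donor demographics, spatially autocorrelated noise fields,
probe cross-hybridization, or batch effects. Passing the planted-recovery
tests therefore shows that the pipeline's statistics behave as designed
under the assumed model — linear-Gaussian signal, independent noise — not
that the method overcomes the messier failure modes of real atlas data
(registration error, expression autocorrelation, incomplete sampling).
Results on real data additionally depend on the ontology library used.

With `planted_set_fraction = 1`, planted sets must be no larger than the
planted pool of their sign, or the generator cannot honor the fraction;
it checks coverage and stops with an explanatory error when the planted
sets cannot jointly cover the pool.

## Numerical conventions

* Voxel snapping rounds half away from zero; z = 0 voxels are excluded
  (strict positivity).
* Z-scoring uses the n − 1 standard deviation; zero-variance rows are
  zeroed and flagged.
* DS ties are broken by probe id; ranking ties by gene id; candidate ties
  by |mean r̄| then gene id — every ordering in the package is total and
  deterministic.
* The ES is the signed maximum-magnitude deviation; when the positive and
  negative extremes tie in magnitude to within 1e−12, the positive one is
  taken, so the result does not depend on floating-point summation order.
* Percentages are rounded half-up to one decimal; bootstrap percentiles
  use linear interpolation (quantile type 7); bootstrap significance
  requires strict exclusion of zero.
* All randomness (generator, permutation null, bootstrap) is seeded;
  per-stage child seeds are the master seed plus fixed offsets, kept
  within the 32-bit range.

## Problem sizes used by the test suite

The suite exercises the full default study (4 donors × 2 compartments ×
100 samples, 2000 genes × 3 probes, 50 sets, 1000 permutations) once for
the end-to-end recovery check, and smaller studies (3 donors, 300 genes,
12 sets) for the module-level integration tests; oracle-equivalence checks
run on 1000 random list/set instances of up to 50 genes, and the null
calibration uses 500 random sets over a 2000-gene null ranking with 500
permutations. These sizes were chosen to give the statistics enough
resolution (e.g. p-value granularity well below the 0.05 threshold) while
keeping the suite quick to run routinely.

## Known limitations

* The FDR procedure is the sign-stratified NES-ratio reconstruction of
  the published pre-ranked tool's method; minor numeric differences from
  that tool's outputs on real data are expected.
* The random-effects combination is the unweighted mean of per-donor
  correlations; it does not model between-donor variance explicitly, and
  no spatial-autocorrelation-preserving null is provided for the ranking
  itself.
* Evidence flags are inputs: the package scores them but does not mine
  literature.
* The candidate-list tie-break by correlation magnitude is an inference
  from the intended ranking behavior (count first, the ranking statistic
  second); printed candidate tables with rounded correlations cannot
  always be reproduced rank-exactly from rounded values.
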