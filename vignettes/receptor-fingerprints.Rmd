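---
title: "Methods: densitometry, laminar profiles and receptor fingerprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: densitometry, laminar profiles and receptor fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(receptarch)
```

## The measurement model

Quantitative in vitro receptor autoradiography labels transmitter
receptor binding sites in unfixed cryostat sections with tritiated
ligands and reads out their density from film. `receptarch` implements
the quantification chain in two stages.

**Film calibration.** Sections are co-exposed with standards of known,
step-wise increasing radioactivity concentrations. `fit_calibration()`
fits a monotone calibration curve through the standards' (radioactivity,
mean gray) pairs by non-linear least squares (Levenberg–Marquardt). The
default family is the saturating response

$$G(R) = \mathrm{offset} + G_{max}\,\bigl(1 - e^{-aR}\bigr),$$

which captures film saturation and inverts in closed form; a cubic
log-polynomial family is available for probing model mismatch. A fit is
refused unless it is strictly monotone, and gray values outside the
calibrated range are masked rather than extrapolated — saturated film
carries no density information and silently extrapolating it would bias
exactly the high-density laminae one cares about.

**Densitometry.** Radioactivity concentrations $R$ (cpm) become binding
site densities at ligand saturation via

$$C_b = \frac{R}{E \cdot B \cdot W_b \cdot S_a} \cdot
  \frac{K_D + L}{L} \quad [\text{fmol/mg protein}],$$

with counter efficiency $E$, decays per unit time and radioactivity $B$
(Ci/min), standard protein weight $W_b$ (mg), specific activity $S_a$
(Ci/mmol), dissociation constant $K_D$ (nM) and free ligand
concentration $L$ (nM). $C_b$ is linear in $R$ and in the saturation
factor $(K_D+L)/L$; these homogeneity properties are asserted in the
test suite over random parameter draws. All six constants travel in a
`ligand_params` object (YAML/JSON serializable per receptor) — nothing
is hard-coded.

Total binding is treated as representative of specific binding by
default, reflecting the experimental situation in which non-specific
binding is a small fraction of total binding; when a non-specific image
exists, `specific_binding()` subtracts it pixelwise, floors at zero and
reports how many pixels were floored.

## Laminar profiles and strata

`extract_traverses()` places anchors at equidistant arclength positions
along the pial contour and connects each to its minimum-length point on
the white-matter contour. Crossing connections are resolved by forcing
the white-matter arclength positions to be non-decreasing, so traverses
never intersect. Traverses longer than 1.5× the median length of their
area are excluded as obliquely sectioned cortex. Only this
minimum-length construction is implemented: the package's phantom
geometries (flat band and circular arc) are handled exactly by it, and a
second traverse engine (e.g. Laplace streamlines) would have no ground
truth here to be validated against. For strongly folded real cortex the
minimum-length rule is the method's known limitation.

`sample_profile()` samples the density image bilinearly at `n_bins`
equidistant points along a traverse (default 101), on a depth axis
normalized to 0 % (pial surface) – 100 % (layer VI / white matter
border). `partition_strata()` integrates the profile by the trapezoidal
rule over three depth sectors — supragranular $[0, f_1)$, granular
$[f_1, f_2)$, infragranular $[f_2, 1)$ — inserting the sector borders as
exact nodes, and divides by sector width. The all-layer mean is the sum
of the sector integrals, so the thickness-weighted identity

$$\bar d_{all} = f_1\,\bar d_{sg} + (f_2 - f_1)\,\bar d_{g} +
  (1 - f_2)\,\bar d_{ig}$$

holds by construction (and is tested to 1e-6 relative).

**Agranular areas.** Motor areas 4 and 6 and cingulate area 24 lack a
recognizable layer IV; their granular sector is defined as a stripe of
3 % of the total cortical depth directly below the lower border of
layer III. `cortical_geometry(agranular = TRUE, layerIII_lower_fraction
= f)` yields the sector $[f, f + 0.03)$.

**Guard band.** A laminar border appears in a sampled raster as a ramp
roughly one pixel wide, because pixels average tissue and bilinear
interpolation smooths the step. Integrating that ramp across the border
systematically misallocates density between neighboring sectors; for
the 3 % agranular stripe (≈4–5 px at typical resolutions) the bias
reaches the percent range, swamping the quantification error
everywhere else. `partition_strata()` therefore excludes a one-pixel
guard band on both sides of each interior border and bridges it by
extrapolating the adjacent plateau. For piecewise-constant laminae this
is exact regardless of how the border falls on the pixel grid; for
genuinely graded profiles it introduces an error of order (guard
width)² × slope, which is negligible at the default settings.
`guard_px = 0` restores the plain trapezoid.

## Fingerprints

A receptor fingerprint is the ordered vector of the densities of all
panel receptors in one area, for one stratum or the all-layer mean;
`build_fingerprints()` produces exactly four per area (all, sg, g, ig),
averaged over replicate brains, on one fixed receptor sequence (AMPA,
NMDA, kainate, GABAA, GABAA/BZ, GABAB, M1, M2, M3, a4b2, a1, a2,
5-HT1A, 5-HT2, D1) so that collections are mutually comparable.

Fingerprint *size* is computed two ways: the sum of the densities (the
headline measure used for cross-area comparisons) and the polygon area
of the polar plot, $\tfrac12 \sin(2\pi/k)\sum_i r_i r_{i+1 \bmod k}$.
Sizes are refused on z-normalized fingerprints, where negative spokes
make them meaningless.

Because ionotropic GABA/glutamate receptor densities exceed the
modulatory receptors by one to two orders of magnitude,
`normalize_z()` gives every receptor equal weight: per receptor,
subtract the mean and divide by the sample (n−1) standard deviation.
The scope matters and both options are explicit: `"per-stratum"`
normalizes each stratum over its areas (right for within-stratum
comparisons and clustering), while `"pooled-strata"` normalizes over
all area × stratum rows together — required whenever strata are to be
compared with one another, as in the strata-cluster MDS, since
per-stratum scoring would erase exactly the between-strata differences
of interest.

## Multivariate and univariate statistics

*Clustering.* `hcluster()` uses Euclidean distances (sensitive to both
size and shape of a fingerprint) with Ward linkage (`ward.D2`); the
cophenetic correlation against the input distances is reported, along
with the same score for alternative linkages, which documents the Ward
choice on the data at hand. One caveat is worth knowing: Ward merge
heights are cluster-update costs, not dissimilarities, so even on a
perfectly ultrametric input Ward's cophenetic correlation is slightly
below 1; the exact-representation value of 1 is attained by the average
linkage entry of the same comparison table. Ties in merges follow the
lowest-index-pair convention of `stats::hclust`, which is deterministic.

*Cluster count.* `choose_k()` runs seeded k-means with multiple
restarts for k = 2…12 and selects the k with maximal mean silhouette
width — an explicit operationalization of "the number of clusters was
defined by k-means".

*MDS.* `mds_kruskal()` embeds the Euclidean distances in two dimensions
by non-metric MDS minimizing Kruskal stress-1, initialized from the
classical solution plus 20 seeded random restarts (tolerance 1e-6); the
lowest-stress configuration is returned, and stress is reported as a
fraction.

*Discriminant tests.* With 15 receptors and 3 brains per area the
pooled within-group covariance is singular, so `discriminant_tests()`
shrinks it toward its diagonal with an analytically chosen intensity
and uses a Lawley–Hotelling-type trace statistic. p values come from
label permutations — exact at any shrinkage, at the price of a granular
p under tiny designs. Pairwise comparisons are post-hoc after a
significant omnibus test and deliberately uncorrected. The tests run on
absolute densities by default; pass z-scored fingerprints to weight
receptors equally.

*Univariate battery.* `anova_by_area()` runs a one-way fixed-effects
ANOVA per receptor (factor area, brains as replicates — a simplification
that ignores the shared brain of replicate measurements, documented as
such) and multiplies raw p values by the receptor count
(`bonferroni()`, unclipped by default so values above 1 occur).
`extrema_tests()` then tests, only for ANOVA-significant receptors, each
area's replicates against the across-area mean density treated as a
fixed expected value; receptors failing the gate are recorded as
not-tested, and zero-variance replicate sets are flagged degenerate
rather than given an infinite t.

## The synthetic phantom generator

Real human autoradiographs cannot ship with a package; the generator
replaces them with phantoms whose ground truth is known exactly, making
every downstream stage testable.

`generate_ground_truth()` plants the qualitative laminar and regional
structure of cortical receptor architecture: per receptor a laminar
pattern class with fixed stratum multipliers —

| class | sg | g | ig | receptors |
|---|---|---|---|---|
| canonical | 1.30 | 1.00 | 0.70 | AMPA, NMDA, GABAA, GABAA/BZ, GABAB, M1, M3, a2, 5-HT2, D1 |
| infragranular peak | 0.95 | 0.75 | 1.25 | kainate |
| granular minimum | 1.40 | 0.70 | 1.00 | a1, 5-HT1A |
| granular peak (primary sensory areas) | 1.05 | 1.60 | 0.70 | M2, a4b2 |

— applied to base densities in which ionotropic receptors exceed the
modulatory ones by one to two orders of magnitude. Regional
heterogeneity comes from multiplicative log-normal modulations shared
within functional groups (sd 0.10, log scale) plus per-area modulation
(sd 0.12); both scale all strata of an area equally so the planted
laminar ordering holds in every area. Brain replicates add independent
log-normal noise with coefficient of variation 0.05 (3 brains). These
values were fixed once as plausible magnitudes for this kind of data;
exact density ratios are free parameters of the model, not measured
quantities.

`render_phantom()` is the exact forward model: ground-truth densities
are inverted through the densitometry formula to radioactivity, passed
through the film response, and Gaussian gray noise (default sd 0.5 on
the 0–255 gray scale) is added; the standards strip is rendered through
the same film response. Densities that would land within 0.5 % of film
saturation are an error, never clipped. The ribbon is a constant-
thickness band (straight or circular arc) of equal-width area segments
with one padding row beyond each contour so samples taken exactly on a
contour stay unbiased. Gray values are continuous in memory; writing to
disk quantizes to 16-bit TIFF/PNG.

What the phantoms deliberately do **not** emulate: histological
texture, blood vessels, section artifacts, folded geometry beyond a
circular arc, myelin quenching (discussed in the literature but not
corrected here), or 3-D volumes. Passing the round-trip tests therefore
shows the *quantification chain* is correct, not that real tissue poses
no further problems (border placement, quenching and section quality
dominate there).

## Problem sizes and determinism

The default study design is a reduced 8 areas × 6 receptors × 3 brains
panel preserving every laminar pattern class and the agranular and
primary-sensory special cases; `study_config(full = TRUE)` switches to
the full 44 × 15 × 3 design, which the strata-cluster analyses use
(41 granular areas after excluding areas 4, 6 and 24). Validation runs
use phantoms of 150 px cortical thickness, 40 px area width, traverse
spacing 8 px and 201–301 profile bins — sizes at which the noiseless
round trip is exact to float precision and a full quantification pass
completes in well under a minute.

Every stochastic step takes an explicit integer seed, derived in the
pipeline from a single master seed; identical configurations reproduce
every non-plot artifact bit for bit, and each numeric output carries a
provenance line with the configuration hash and seed.

## Worked example

```{r, eval = FALSE}
cfg <- study_config(full = TRUE, replicate_cv = 0.05)
truth <- generate_ground_truth(cfg, seed = 1)
tab <- add_all_stratum(truth)
fps <- build_fingerprints(tab)
sf <- subset_fingerprints(fps, strata = c("sg", "g", "ig"),
                          exclude_areas = cfg$areas$area[cfg$areas$agranular])
z <- normalize_z(sf, scope = "pooled-strata")
m <- mds_kruskal(z, seed = 2)
kc <- choose_k(m$points, k_max = 12, seed = 3)
table(sub("^.*\\|", "", rownames(sf)), kc$cluster)
```

The analogous run through rendered phantoms — including calibration
fitting and profile extraction — is what `scripts/acceptance.R`
executes end to end.
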