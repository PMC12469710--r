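---
title: "Landmark-based craniofacial morphometrics with craniomorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark-based craniofacial morphometrics with craniomorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(craniomorph)
```

# The analysis problem

Mouse models of Down syndrome carry segmental duplications whose dosage
effects show up as localized craniofacial changes: midface hypoplasia,
lateral widening and anteroposterior shortening of the neurocranium
(brachycephaly), and altered mandible proportions. The standard
quantitative readout is a set of named 3D anatomical landmarks digitized
on micro-CT scans of each specimen — on the order of 39 cranium and 22
mandible landmarks, with roughly ten littermates per genotype.

craniomorph implements the two complementary analysis families used on
such data, plus the small-sample expression and proliferation statistics
that accompany them, and a synthetic cohort generator so every stage can
be calibrated and power-tested without access to the original scans
(which are typically not deposited).

# Euclidean Distance Matrix Analysis

EDMA is coordinate-system-free: each specimen is reduced to the vector of
all $K(K-1)/2$ inter-landmark distances (its *form matrix*,
`form_matrix()`). *Shape* is form standardized for size: each distance
vector is divided by its geometric mean (`scale_to_shape()`), so the shape
matrix has unit geometric mean. Centroid size is available as an
alternative divisor (`size_measure = "centroid"`); the geometric mean is
the default because it is defined purely on the distance vector and is
the classic EDMA scaling.

Two groups are compared by the ratio of their mean matrices
(`difference_matrix()`): per pair,
$\mathrm{RED}_{ij} = \bar d^{\,\mathrm{test}}_{ij} / \bar d^{\,\mathrm{ref}}_{ij}$,
the *relative Euclidean distance*. The form difference matrix (FDM) uses
raw distances; the shape difference matrix (SDM) scales each specimen
first. Ratios above 1 mean the distance is larger in the test (mutant)
group. The mean form estimator is the arithmetic per-pair mean of the
specimens' distances; moment-based estimators that subtract within-group
digitization variance exist, and results on noisy small samples can
differ slightly from software that uses them.

## Omnibus significance

`edma_test()` tests the global null of no form (or shape) difference with
the statistic $T = \max(\mathrm{RED}) / \min(\mathrm{RED})$. The null
distribution breaks group labels by pooling the specimens' distance
vectors and redrawing pseudo-groups of the original sizes, recomputing
$T$ each time; $p = (b + 1)/(n_\mathrm{boot} + 1)$, which cannot return an
exact zero at finite resamples. The default number of resamples is
10,000, the scale at which such bootstrap analyses are conventionally
run; calibration simulations in this package use 1,000 to keep runtimes
in seconds.

Two null constructions are provided:

* `null = "permutation"` (default): pseudo-groups are drawn *without*
  replacement — a label permutation. Under exchangeability this null is
  exact, and simulated null p-values are uniform (500 null cohorts at
  $K = 12$, $n = 10 + 10$: rejection 0.048 at $\alpha = 0.05$,
  Kolmogorov–Smirnov uniformity $p = 0.14$; these numbers are recomputed
  by the test suite and `scripts/acceptance.R`).
* `null = "bootstrap"`: both pseudo-groups are resampled *with*
  replacement from the pool, the classic two-sample pooled bootstrap. At
  these group sizes its null $T$ distribution is a few percent narrower
  than the sampling distribution, which leaves the rejection rate intact
  (0.054 measured) but makes the p-value distribution detectably
  non-uniform. It is kept as an option because "bootstrapping" is what
  analyses of this kind conventionally report.

$T$ is blind to a perfectly uniform size change (all REDs equal scale to
$T = 1$): a global doubling of the test group moves every RED to 2.0 but
leaves the omnibus statistic at its floor. The per-pair confidence
intervals and the RED band carry that signal instead, and the form/shape
duality makes it visible: a uniform scaling gives FDM $\equiv$ 2 and SDM
$\equiv$ 1.

Per-pair confidence intervals are percentile intervals from a separate
within-group bootstrap (each group resampled with replacement
independently) at level 0.978 — the level at which influence-landmark
bands are conventionally drawn; the flavor of interval (percentile) is a
package choice, as the original analyses do not state one.

## Influence landmarks

`influence_analysis()` localizes a difference: a pair is *out of band*
when its RED leaves $[0.95, 1.05]$, and each landmark is scored by the
fraction of its $K - 1$ incident pairs that are out of band. Landmarks
are ranked by this fraction with competition ranking (ties share the
lowest rank — the fraction takes only $K-1$ discrete values, so ties are
the norm, and an arbitrary tie-break would make rankings depend on
landmark names). The dominant direction is `increase` when out-of-band
pairs above the band outnumber those below at least 2:1 (`decrease`
symmetrically, `mixed` otherwise, `none` when no incident pair is out);
the 2:1 rule is a package convention — the analyses this mirrors report
direction qualitatively. When CIs are attached, a parallel count of pairs
whose interval excludes 1 is reported alongside the fixed band.

One geometric caveat worth knowing: a *local* contraction is applied (and
anatomically acts) about the affected region's own centroid, so a
landmark at the region's edge is displaced toward that centroid and its
distances to *other* regions can genuinely lengthen. Its dominant
direction will then be mixed or increase even though the region-level
effect is a contraction. This is a property of the geometry, not noise;
directionality checks in this package therefore compare against the
landmark-wise direction field computed from a noiseless application of
the same effect.

# Procrustes superimposition and shape PCA

`gpa()` implements Generalized Procrustes Analysis: every configuration
is centered, scaled to unit centroid size (full Procrustes; `scale =
FALSE` gives the partial variant), and rotated onto the running consensus
by the determinant-corrected orthogonal fit — reflections are disallowed
because anatomical landmark configurations are chiral. The consensus is
the coordinate-wise mean, renormalized, and iteration stops when its root
summed squared change drops below `tol` (default `1e-8`, typically 2–4
iterations). The first specimen seeds the consensus, which fixes the
overall orientation of the output; the fixed point is unique only up to
that global rotation, and all reported quantities (Procrustes distances,
PCA variance fractions) are invariant to it. Degenerate (collinear)
configurations are rejected rather than silently resolved.

`shape_pca()` eigendecomposes the covariance of the flattened aligned
coordinates about the consensus. Variance fractions sum to one over the
$\min(n-1, 3K)$ retained components; each loading's largest-magnitude
element is forced positive so signs are reproducible across platforms.

`group_permutation_test()` compares group mean shapes by the Procrustes
distance between group consensus configurations, with a within-pair label
permutation null and the same $(b+1)/(n+1)$ correction, defaulting to
1,000 permutations as such tests are conventionally run.

The integrative stage (`integrative_distance_pca()`) pools specimens from
several models into one PCA of shape-scaled distance vectors. Working in
distance space rather than a joint superimposition keeps the features
coordinate-free, so cohorts digitized in different poses combine without
a cross-cohort alignment step. A whitened canonical variate analysis is
deliberately *not* the default ordination: with ~10 specimens per group
and hundreds of features the within-group covariance is singular, and its
inversion would dominate the picture with noise.

# Expression and proliferation statistics

`select_and_test()` reproduces the small-sample comparison cascade:
Shapiro–Wilk normality on each group at $\alpha = 0.05$, then an F-test
for variance equality deciding between the two-tailed unpaired t-test and
Welch's t-test. When either group fails normality the package falls back
to the Mann–Whitney U test and flags it — a conventional nonparametric
replacement chosen here because the source procedure does not state one;
the cascade never silently defaults. All pre-test p-values are recorded
so the branch is replayable from the result object. Pre-test conditioning
can distort size, so the calibration is *checked*, not assumed: simulated
type-I error stays within [0.03, 0.08] at $\alpha = 0.05$ under both a
normal and a heavy-tailed (scaled $t_3$) null. No multiple-testing
correction is applied across genes by default (per-gene reporting, as is
conventional for two or three pre-specified dosage candidates); Holm is
available.

`proliferation_index()` is the percentage of EdU-positive (S-phase
labeled) cells among Hoechst-counted nuclei. The EdU/PH3 "mitotic index"
ratio orientation is ambiguous in common usage, so `mitotic_index()`
requires an explicit convention argument and has no default.

# The synthetic cohort generator

`build_template()` places landmarks on the upper half of a 12 × 8 × 6 mm
tri-axial ellipsoid — a stylized skull at adult-mouse scale — with region
tags on contiguous anteroposterior sectors. `effect_spec()` +
`apply_effect()` implant genotype effects as per-region affine maps about
the region centroid: isotropic factors model hypoplasia/hyperplasia,
per-axis factors model directional effects such as lateral widening.
Applying effects about the *region* centroid (not the global one) keeps
untouched regions bit-identical and mimics local bone-level change
without a global size confound. `sample_cohort()` adds iid isotropic
Gaussian noise per coordinate (the standard landmark-error model; no
error model is published for the data this emulates), optional rigid-pose
nuisance (random rotation/translation, which leaves all distances
invariant) and uniform size jitter (which form analysis should detect and
shape analysis should remove).

Default study conditions mirror the design this emulates: 10 specimens
per genotype, noise_sd 0.05 mm against a ~26 mm centroid-size template
(calibration studies use 0.02 mm, and effect-recovery studies scale noise
to 2% of the mean inter-landmark distance), desk-scale templates of
12–20 landmarks in 3 regions; the full 39/61-landmark inventory is
supported via `mouse_landmark_inventory()`, a synthetic stand-in
dictionary of plausible names and region tags. Per-specimen random
streams are derived from the master seed by counter-based splitting, so
enlarging a cohort never perturbs existing specimens. An option for
larger affected-group variance (`noise_sd_affected`) exists — increased
individual variability is part of the trisomic phenotype — but is off by
default.

What the generator does *not* emulate: correlated digitization error
along bone surfaces, allometry (size-dependent shape), sexual
dimorphism, missing landmarks, and measurement drift between scanning
sessions. Passing calibration and recovery tests on these cohorts
therefore demonstrates correctness of the statistical machinery under
the stated noise model, not robustness to every artifact of real
micro-CT data.

# The study pipeline

`study_config()` + `run_study()` reproduce the full analysis pattern:
per model, form and shape omnibus tests against the wild-type reference,
influence landmarks on the SDM, GPA + shape PCA on the pooled cohort;
then the integrative distance PCA and pairwise Procrustes-distance
permutation tests across all models (wild-types share one label and pool
together). Severity labels follow a stated quantitative rule — `NS` when
$p \ge \alpha$, otherwise `strong` when at least 25% of pairs are out of
the RED band and `mild` below that — because the qualitative
strong/mild/NS summaries this mirrors do not state a rule; both
thresholds surface in the report so users can re-threshold. Every
resampling stage derives its seed from the config's master seed, making
the whole report a pure function of (config, seed); the serialized
report is byte-identical across reruns, and per-dataset failures are
isolated into an `errors` field rather than aborting the study.

# Numerical choices and limitations

* Pair ordering is canonical (lexicographic by landmark index, the
  `dist()` convention); ratios are always test/reference with the
  wild-type as reference.
* Coincident landmarks (zero distance) and collinear configurations are
  hard errors, not warnings.
* Distances are interpreted in mm throughout; no unit conversion.
* GPA convergence tolerance `1e-8` on consensus change; the iteration cap
  (100) has never been approached on realistic data, and hitting it is an
  error carrying the change trace.
* p-values from resampling are bounded below by $1/(n+1)$; reported
  minima are that bound, not zero.
* Lele-style variance-corrected mean form estimation, two-sample EDMA
  variance testing, missing-landmark imputation, semilandmark sliding and
  thin-plate-spline visualization are out of scope.

## Calibration study sizes

The test suite and `scripts/acceptance.R` run the calibration studies at
fixed desk-scale sizes chosen to give stable rates in seconds-to-minutes:
500 null cohorts (1,000 resamples each) for omnibus calibration, 300 for
the permutation test (200 permutations), 100 simulations each for
influence recovery and directionality, and 1,000 replicates per null for
the cascade. All are computed fresh at run time from the seed.
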