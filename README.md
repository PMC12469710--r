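# craniomorph

Landmark-based craniofacial morphometrics in R: Euclidean Distance Matrix
Analysis (EDMA) with resampling significance tests and influence-landmark
detection, Generalized Procrustes superimposition with shape PCA,
Procrustes-distance permutation tests, small-sample expression and
cell-proliferation statistics, and a synthetic landmark-cohort generator.

## Who this is for

Groups phenotyping skeletal shape from named 3D anatomical landmarks —
the typical setting is mouse models of dosage disorders (e.g. Down
syndrome segmental duplications), where ~10 littermates per genotype are
micro-CT scanned and 39 cranium + 22 mandible landmarks digitized per
specimen, and the question is *whether*, *where* and *in which direction*
a genotype changes craniofacial form.

## The statistics at the core

A specimen with landmarks $x_1, \dots, x_K \in \mathbb{R}^3$ is reduced
to its **form matrix**, the vector of all $K(K-1)/2$ inter-landmark
distances $d_{ij} = \lVert x_i - x_j \rVert$; dividing by the geometric
mean of the $d_{ij}$ gives the **shape matrix**. Two groups are compared
pair by pair through the **relative Euclidean distance**

$$\mathrm{RED}_{ij} = \frac{\bar d^{\,\mathrm{mutant}}_{ij}}{\bar d^{\,\mathrm{wildtype}}_{ij}},$$

forming the form (FDM) or shape (SDM) difference matrix. Global
significance uses the omnibus statistic
$T = \max_{ij}\mathrm{RED}_{ij} / \min_{ij}\mathrm{RED}_{ij}$ against a
pooled label-resampling null with $p = (b+1)/(n_\mathrm{boot}+1)$
(default 10,000 resamples), plus per-pair 97.8% bootstrap confidence
intervals. **Influence landmarks** are those with many incident pairs
outside the RED band $[0.95, 1.05]$, each with a dominant direction
(increase/decrease/mixed). The complementary geometric-morphometrics
track superimposes specimens by **Generalized Procrustes Analysis**
(center, scale to unit centroid size, rotate — reflections disallowed),
runs **PCA** on the aligned coordinates, and compares groups by the
Procrustes distance between consensus shapes under a permutation null
(default 1,000 permutations).

## Worked example

Simulate a two-group cohort with a 10% midface contraction and 10%
lateral (y-axis) neurocranial expansion — the classic trisomic pattern —
then test and localize it:

```r
library(craniomorph)

tpl <- build_template(12, c(midface = 4, neurocranium = 4, base = 4), seed = 1)
eff <- effect_spec(c(midface = 0.9),
                   axis_scale = list(neurocranium = c(1, 1.1, 1)))
set <- sample_cohort(cohort_spec(tpl, eff, n_control = 10, n_affected = 10,
                                 noise_sd = 0.05, seed = 42))

fit <- edma_test(subset_group(set, "WT"), subset_group(set, "Mut"),
                 mode = "shape", n_boot = 10000, seed = 1)
summary(fit)
#> EDMA shape omnibus test (SDM difference matrix)
#>   groups: n = 10 (reference) vs n = 10 (test)
#>   observed T = max(RED)/min(RED) = 1.2188
#>   null: 10000 pooled permutation resamples, p = 9.999e-05
#>   RED quantiles: 0.899 0.986 0.998 1.026 1.096
#>   14 / 66 pairs outside RED band [0.95, 1.05]
```

The shape difference is significant (p is at the resampling floor
1/10001), with 14 of 66 relative distances out of band. Where is it?

```r
influence_analysis(fit$diff)
#> Influence landmarks (shape mode), RED band [0.95, 1.05]: 14 pairs out of band
#>        landmark region n_above n_below fraction_outside dominant_direction
#>       midface_3   <NA>       5       3       0.72727273              mixed
#>  neurocranium_3   <NA>       4       0       0.36363636           increase
#>       midface_1   <NA>       0       3       0.27272727           decrease
#>       midface_2   <NA>       0       3       0.27272727           decrease
#>       midface_4   <NA>       0       3       0.27272727           decrease
#>  ...
```

The implanted pattern is recovered: midface landmarks dominate the
ranking with *decreased* incident distances, the expanded neurocranial
landmark shows *increased* ones. (`midface_3` reads `mixed` because the
local contraction pulls this sector-edge landmark anteriorly, truly
lengthening its cross-region distances — see the methods vignette.) The
Procrustes track agrees:

```r
g <- gpa(set)
shape_pca(g)
#> Shape PCA: 20 specimens, 19 components
#>   variance fractions: PC1 80.6%, PC2 3.1%, PC3 2.4%, PC4 2.4%, PC5 2.0%
group_permutation_test(g, n_perm = 1000, seed = 1)
#> Procrustes-distance permutation tests (1000 permutations)
#> observed consensus distances:
#>         WT    Mut
#> WT  0.0000 0.0396
#> Mut 0.0396 0.0000
#> p-values:
#>        WT   Mut
#> WT     NA 0.001
#> Mut 0.001    NA
```

PC1 carries 80.6% of shape variance (the implanted group contrast), and
the two mean shapes differ at the permutation floor p = 1/1001.

Multi-model studies (each mutant vs wild-type, then an integrative
cross-model distance PCA and pairwise permutation tests, with
strong/mild/NS severity labels) run through `study_config()` +
`run_study()`; `write_study_report()` serializes every table plus a
machine-readable JSON. A thin command-line wrapper for simulation and
single analyses is in `inst/scripts/cranioform.R`.

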