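---
title: "Quantifying inter-operator landmark error: model, methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying inter-operator landmark error: model, methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(procerror)
```

## Scope

`procerror` quantifies how much of the variation in 3D landmark data is
measurement error — random digitizing noise plus systematic
operator-specific bias — relative to true biological variation. This
vignette documents the statistical model, the conventions behind every
numerical choice, the synthetic data generator and its calibration, and
the package's limitations. All problem sizes used in examples and tests
(15 landmarks split 10 bone / 5 nasal soft tissue, 20 individuals × 3
operators for replica designs, a 906-record partitioned study sample)
are the package's own canonical configuration, chosen to represent a
realistic multi-operator craniofacial study at desk scale.

## The measurement model

A record is one digitization of one individual by one operator: a
configuration $X \in \mathbb{R}^{p \times 3}$ of $p$ named landmarks in
mm. The generator, and implicitly the estimators, assume

$$X_{ior} = T_i + B_o + E_{ior},$$

where $T_i$ is the individual's true configuration (drawn around a
fixed anatomical template with individual shape variation, allometric
size variation and optional sexual size/shape dimorphism), $B_o$ is a
fixed per-operator bias field (the same systematic displacement applied
to every record that operator digitizes), and $E_{ior}$ is isotropic
Gaussian digitizing noise, independent across landmarks and records.
Each record is then given a random rigid motion — position and
orientation in the scanner are arbitrary, which is why all analyses
begin with superimposition.

## Generalized Procrustes analysis

`gpa_align()` implements partial Procrustes superimposition:

1. centre each configuration and scale it to unit centroid size
   $CS = \sqrt{\sum_i \lVert x_i - \bar{x} \rVert^2}$;
2. rotate each onto the current consensus using the SVD solution of the
   orthogonal Procrustes problem, restricted to proper rotations
   ($\det = +1$): reflections would silently swap left and right
   anatomy;
3. re-estimate the consensus as the mean of the aligned configurations,
   renormalised to unit size, and iterate until its displacement falls
   below `tol = 1e-10` (at most 100 iterations; non-convergence is an
   error, never silent).

The first record's orientation seeds the consensus, so results are
deterministic. The objective (total squared distance to the consensus)
is recorded after each iteration in `objective_trace`; it is provably
non-increasing, and the test suite asserts this on every fit it makes.

**Tangent projection.** By default aligned coordinates are Procrustes
*chord* coordinates: they live on the unit sphere, not in a linear
space. For the small shape variation typical of measurement-error
studies the difference is second order and chord distances are the
conventional choice, so `project_tangent = FALSE` is the default. The
quadratic unit-size constraint does, however, leave one second-order
"radial" principal component beyond the shape-space dimension $3p - 7$
(empirically $10^{-4}$–$10^{-3}$ of the leading eigenvalue for the
canonical panels). With `project_tangent = TRUE` the aligned shapes are
orthogonally projected onto the tangent plane at the consensus, the
covariance rank is exactly $\le 3p-7$, and PCA conserves the total
coordinate variance exactly; `shape_pca()` documents this interaction
and caps its component count at $3p-7$ either way.

## Variance partitioning

All ANOVA tables in the package are additive by construction (effect SS
sum exactly to the total; $R^2$ percentages sum to 100) and are
validated as such in the tests.

**Repeatability (replica designs).** For size, classical one-way ANOVA
of centroid size across individuals. For shape, the Procrustes ANOVA
convention: sums of squares are accumulated over all $3p$ aligned
coordinates jointly, and the classical degrees of freedom are
multiplied by the shape-space dimension $3p - 7$ (the dimensions lost
to translation, scale and rotation). With 20 individuals × 3 replicas
this yields individual df $19 \times 38 = 722$ and error df
$40 \times 38 = 1520$ for the full 15-landmark panel.

**ICC variant.** The intraclass correlation is computed from the mean
squares. The default variant is

$$\mathrm{ICC} = \frac{MS_a - MS_w}{MS_a + MS_w},$$

chosen because it exactly reproduces, at 2-decimal rounding, all six
published ICCs of the reference table from which this package's
acceptance targets derive, whereas the classical one-way form
$(MS_a - MS_w)/(MS_a + (k-1)MS_w)$ with $k = 3$ does not reproduce any
of them. The classical form remains available via
`icc_from_ms(..., variant = "oneway")`.

**Hierarchical (study designs).** `hierarchical_anova()` partitions
size or shape sequentially (Type I): sex first, then operator, then
residual. Sequential ordering is deliberate — the operator effect is
the *sex-adjusted* remainder, i.e. operator differences unrelated to an
uneven sex mix across operators. The factors are crossed, not nested,
because every operator measures both sexes. `balanced_subsample_r2()`
repeats the partition on a seeded, balanced draw (default 50 records
per sex × operator cell, 300 total) to show that unbalanced cell sizes
do not drive the estimates; note the balanced estimate is a single draw
with a sampling SD of roughly two $R^2$ points at that size.

**Permutation tests.** Parametric F/P values are always reported.
Optional permutation P values use 999 seeded rounds. For the grouping
ANOVAs, labels are permuted freely. For the repeatability ANOVA the
textbook scheme would permute replicas *within* individuals — but that
scheme is invariant for this statistic (the individual assignment of
each observation never changes), so the package permutes individual
labels freely across records and documents this deviation. Uniformity
of the null P distribution is verified in the tests.

## Absolute error: ODEV and AVEDEV

`compute_odev_avedev()` works on the **raw mm coordinates**, not the
superimposed ones: the operator deviation (ODEV) of a landmark is the
Euclidean distance between one operator's placement and the mean
placement of all operators for that individual and landmark, and
AVEDEV is the mean of the $k$ ODEVs. Superimposing first would spread
localised error over all landmarks; the raw-coordinate definition keeps
the metric interpretable in mm of digitizing displacement.
`error_profile()` summarises ODEVs with type-7 quantiles (the R
default; recorded in the output's `percentile_method` attribute).

## Concordance diagnostics

- `pairwise_size_correlation()`: Pearson correlations of per-operator
  centroid-size vectors over shared individuals.
- `distance_matrix_correlation()`: Pearson correlation over the
  $n(n-1)/2$ strictly-lower-triangle entries of two shape distance
  matrices. No permutation P by default — the statistic is a congruence
  diagnostic, not a test; a seeded Mantel P is available.
- `upgma_tree()`: average-linkage agglomeration via `stats::hclust`,
  with rows pre-sorted by label so that ties in the minimum distance
  break lexicographically and trees are identical across platforms. The
  tree exports to newick through `ape`; record identifiers use `_`
  separators because `:` is structural in newick.
- `replica_cluster_counts()`: an individual is a *triplet* if its
  replica leaves form an exclusive clade, *pair-or-better* if at least
  two do. With zero simulated error all individuals are triplets; the
  count degrades monotonically (up to one-step jitter) with noise.
- `relative_range()`: max/min ratio of per-record shape distances to
  the mean, with symmetric trimming (`ceiling(f/2·n)` from each tail,
  capped so at least two values remain).

## The synthetic generator and its calibration

`synthetic_spec()` fixes the generative parameters; two designs are
drawn from it:

- `generate_replica_study()`: every operator digitizes every individual
  once (default 20 × 3 = 60 records, single sex).
- `generate_study_sample()`: a large mixed-sex sample in which each
  record is digitized by exactly one operator, with deliberately
  unequal operator × sex cell counts (906 records by default).

Parameters (units mm unless noted), with their calibrated defaults:

| parameter | default | meaning |
|---|---|---|
| `mean_size` | 250 | template centroid size |
| `individual_shape_sd` | 2.0 bone / 2.8 soft | per-landmark SD of true individual shape variation (soft tissue varies more among individuals) |
| `individual_size_sd` | 6.5 | SD of true centroid-size variation |
| `sex_size_shift` | 15 | male−female centroid-size offset |
| `sex_shape_magnitude` | 0.7 | scale of a fixed sex shape-difference field |
| `operator_bias` | 1.25 | RMS of each operator's fixed bias field |
| `noise_sd_bone` / `noise_sd_soft` | 1.485 / 0.9 | digitizing noise SD per coordinate; bone landmarks are noisier (factor 1.65) because bone surfaces are harder to localise on MRI |

Operator bias fields are deterministic functions of the operator index
(drawn once from a private constant seed with RNG state save/restore,
so they never perturb the caller's stream), centred across operators,
and tissue-weighted with the same bone/soft ratio as the noise. Each
simulation returns a `truth` object carrying the true configurations,
the bias fields and `design_fractions` — the expected
individual/operator/noise variance shares — against which the tests
check parameter recovery (operator $R^2$ within ±0.05 of the designed
share over 20 seeds).

**Calibration.** The defaults were set in a single calibration pass to
place the pipeline's outputs in the regime reported by multi-operator
craniofacial MRI studies — shape error $R^2$ near 30% overall, higher
for bone than for nasal soft tissue, the reverse ordering for size
error, bone/soft absolute-error contrast near 0.65, and operator shape
effects exceeding sex effects in the study design — and then frozen.
They were not tuned against test outcomes afterwards. Known
imperfections are accepted rather than chased: for example, the
nasal-subset size dimorphism is weaker than in the emulating target.

**What the generator does not emulate**: landmark-specific error
anisotropy (noise is isotropic per landmark), operator-by-individual
interaction (bias fields are constant per operator), non-Gaussian
blunders/outliers, and missing landmarks.

## File formats and the command line

`read_landmark_table()` / `write_landmark_table()` support a long CSV
(one row per landmark observation; all metadata columns read as
character, so single-letter sex codes survive type inference) and a
Morphologika-style block format. Coordinates are written with 12
significant digits for lossless round trips. The CLI
(`inst/cli/procerror.R`) wraps simulation, alignment and the three
report levels; reports serialise to JSON via `write_study_report()`.

## Limitations

- Chord vs tangent coordinates differ at second order; for very large
  shape variation enable `project_tangent = TRUE` and interpret with
  care.
- ICC variants disagree when error variance is non-negligible; the
  default variant is tied to this package's acceptance arithmetic, not
  a universal recommendation.
- Sequential SS depend on entry order by design; swapping sex and
  operator answers a different question.
- The permutation scheme for repeatability deviates from the
  within-individual textbook scheme for the reason documented above.
- Synthetic regimes are calibrated summaries, not fitted to any real
  dataset; sample-dependent quantities (correlation tables, study-level
  $R^2$) should be treated as qualitative.
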