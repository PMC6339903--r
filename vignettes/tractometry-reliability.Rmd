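---
title: "Measuring test-retest reliability of tractometry with tractrel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring test-retest reliability of tractometry with tractrel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tractrel)
```

## The problem

Longitudinal diffusion-MRI studies follow white-matter fiber bundles —
here the four bilateral language bundles: arcuate (AF), inferior
longitudinal (ILF), inferior fronto-occipital (IFOF) and uncinate (UF)
fasciculi — across repeated scans, and interpret changes in tract
measures (FA, MD, AD, RD, NuFO, bundle volume, mean streamline length)
as biology. That interpretation is only safe if repeating the scan on
an unchanged subject reproduces both the bundle's shape and its
measures. `tractrel` quantifies that reproducibility for paired-session
cohorts with two complementary families of statistics: spatial overlap
of the reconstructions, and scalar agreement of the tract measures.

The package does not perform tractography. Its inputs are the products
of an upstream pipeline: streamline sets (TRK/TCK), optional streamline
density maps (NIfTI-1), per-bundle scalar measures (CSV), and one
linear transform per subject carrying Time-1 space into Time-2 space.

## Spatial overlap: the weighted Dice coefficient

Each session's bundle is rasterized into a streamline density map
$W_v$: the number of distinct streamlines visiting voxel $v$. For two
maps $W_i, W_j$ on a common grid,

$$
D(W_i, W_j) =
\frac{\sum_{v'} W_{i,v'} + \sum_{v'} W_{j,v'}}
     {\sum_{v} W_{i,v} + \sum_{v} W_{j,v}},
$$

where $v'$ ranges over voxels with positive weight in *both* maps.
Compared with the plain Dice coefficient on the binary supports, the
weighting emphasises the bundle core, where streamline density is
highest, and discounts the sparse fringe voxels that dominate
plain-support disagreement. $D = 1$ exactly when the two supports are
equal (the weights need not match), and for binary maps $D$ reduces to
the ordinary Dice coefficient. A mean wDSC of at least 0.70 — the
minimum reported by earlier test-retest tractography studies — is
taken as acceptable overlap; the boundary value itself passes.

Overlap is always computed after carrying the Time-1 bundle into
Time-2 space (`transform_streamlines()` with the subject's affine) and
rasterizing both sessions onto the Time-2 grid. No registration is
estimated here; the affine is an input.

### Density mapping: numerical choices

A voxel is visited by a streamline if the streamline's resampled trace
contains a point inside the voxel. Concretely each polyline is
resampled by arc length at its two endpoints plus the midpoints of
$\lceil L/h \rceil$ equal subdivisions, each sample is assigned to the
0-based voxel whose half-open cell contains it (floor of the
inverse-affine image), and the voxels are deduplicated per streamline.
The midpoint rule makes the sample-position set symmetric under
polyline reversal, so visitation does not depend on streamline
orientation. The default step is $h = 0.2 \times$ the smallest voxel
dimension — fine enough that for millimetre-scale voxels only
corner-clip traversals shorter than a fifth of a voxel can be missed;
`density_map(step =)` exposes the step for sensitivity checks, and the
test suite verifies the machinery against an independently coded
supersampling oracle at 0.01 mm resolution.

Bundle volume is (number of voxels with $W_v > 0$) $\times$ voxel
volume; the support threshold is strict positivity. Along-tract scalar
aggregation defaults to the density-weighted mean
$\sum_v W_v s_v / \sum_v W_v$ — consistent with the weighting rationale
of the wDSC — with the unweighted mask mean available
(`weighted = FALSE`); published pipelines are usually silent about
which of the two they use, and on synthetic data the difference is
small.

## Scalar agreement: ICC(A,1) and Bland-Altman

For one bundle and one measure, the paired-session data form an
$n \times k$ table ($k = 2$). From the two-way crossed decomposition
with row (subject) mean square $MS_R$, column (session) mean square
$MS_C$ and error mean square $MS_E$, the single-measure
absolute-agreement intraclass correlation is

$$
\mathrm{ICC}(A,1) =
\frac{MS_R - MS_E}{MS_R + (k-1)\,MS_E + \frac{k}{n}(MS_C - MS_E)},
$$

the population version of the ratio of between-subject variance to
total variance. The 95% confidence interval uses the F-distribution
construction with Satterthwaite-approximated denominator degrees of
freedom (McGraw & Wong 1996) — the interval SPSS prints — and
significance against ICC $= 0$ is the one-sided $F = MS_R/MS_E$ test on
$(n-1, (n-1)(k-1))$ degrees of freedom. Estimates are categorised with
the Cicchetti bins: excellent $\ge 0.75$, good $[0.60, 0.75)$, fair
$[0.40, 0.60)$, poor $< 0.40$. Two boundary conventions are the
package's own: the published bins leave $[0.74, 0.75]$ ambiguous, so
the bins are half-open with excellent starting at 0.75 exactly; and
negative estimates are reported as computed (category poor), not
clamped, which preserves the estimator's sampling distribution in
simulation studies.

Bland-Altman analysis summarises the per-subject differences
$d_i = y_{i1} - y_{i2}$ (Time 1 minus Time 2; the sign convention is
configurable) by their mean and the limits of agreement
$\bar d \pm m \cdot s_d$ with $m = 2$ by default (2.0 exactly, not
1.96, matching the convention the limits are usually drawn with; $s_d$
is the $n-1$ sample SD). The limits of agreement are not a confidence
interval of the mean difference — the two are easily conflated — so the
result object reports the limits, the fraction of pairs inside them,
and the integer count outside. The conventional "good agreement" call
requires 95% of points within the limits, which at $n = 18$ can only be
met by $18/18$ ($17/18 \approx 94.4\%$ already fails); the integer
count is therefore the more informative quantity at study scale.

Subjects missing either session of a bundle are dropped from that
bundle's tables only (pairwise-complete analysis); with the default
synthetic cohort the right UF is analysed with 17 of 18 subjects.
Analyses require at least 3 complete subjects. No multiple-comparison
correction is applied across the 56 bundle-measure combinations;
significance stars are reported at 0.05/0.01/0.001 as is conventional
for such reliability tables.

## The synthetic cohort

No per-subject imaging data accompanies the analyses, so the package
generates its own cohort with known ground truth
(`cohort_sim_spec()` + `simulate_cohort()`).

**Metric tables** follow the same two-way model the ICC assumes:
$y_{ij} = \mu + b_i + s_j + e_{ij}$ with independent normal effects of
SD $\sigma_b$ (between-subject), $\sigma_s$ (session) and $\sigma_e$
(residual). The session effect is drawn *random* rather than fixed so
that the population absolute-agreement ICC has the closed form
$\sigma_b^2 / (\sigma_b^2 + \sigma_s^2 + \sigma_e^2)$ (`true_icc()`),
giving an exact target for parameter-recovery studies. Defaults: 18
subjects, all tables generated at true ICC 0.85 with 10% of the
within-subject variance assigned to the session effect, and per-metric
scales chosen once as plausible tractometry values (FA $0.45 \pm
0.035$, MD $0.80 \pm 0.05\ \mu m^2/ms$, AD $1.20$, RD $0.60$, NuFO
$1.6$, volume $9000\ mm^3$, MLS $90\ mm$). These scales are
configuration values, not estimates of any study's data — the source
analyses publish only ICCs and CIs, not per-bundle means — and the ICC
is scale-invariant, so they only set the units of the report.

**Bundles** are tubes: a fixed per-bundle centerline curve inside a
40 mm isotropic grid (1 mm voxels), with each streamline a smooth
lateral offset of the centerline (constant plus half-sine components,
SD 1 mm). Session 2 redraws the tube around a centerline displaced by
`session_shift` (default 0.6 mm), which dials the expected wDSC; the
defaults land the per-bundle means in the low 0.8s, inside the range
typical of test-retest HARDI tractography. One subject's right UF is
absent in both sessions. All randomness derives from a master seed via
per-(subject, bundle, metric) hashed sub-seeds, so regeneration is
byte-identical and independent of call order.

What the generator does *not* emulate: anatomy (centerlines are
geometric arcs, not language-tract trajectories), raw DWI signal and
its noise floor, tracking failure modes (premature termination,
spurious branches), inter-subject morphological variability, and any
correlation between spatial overlap and metric agreement — metric
tables and bundle geometry are generated independently. Passing tests
therefore validate the *statistical machinery* under the assumed
two-way model and the *geometric machinery* on controlled shapes; they
say nothing about whether real tractography satisfies those
assumptions.

## Problem sizes and checks

The package's own validation (test suite plus `scripts/acceptance.R`)
runs at these scales, chosen to make Monte-Carlo error comfortably
smaller than the properties being asserted:

* ICC estimate/CI against a hand-coded ANOVA oracle and an independent
  reference implementation: 200 random tables, $n \in [3, 30]$,
  agreement to $10^{-8}$ (estimate) and $10^{-6}$ (CI).
* Parameter recovery at true ICC $\{0.2, 0.5, 0.75, 0.9\}$, $n = 18$:
  500 replicates per level (mean within $\pm 0.05$); CI coverage at
  0.75; F-test size over 2000 null tables.
* Density mapping against a 0.01 mm supersampling oracle on 20 random
  polylines; exact hand cases for lengths, volumes and Dice values.
* One full default cohort (18 x 2 x 8 x 7) through the pipeline:
  56 ICC rows, 8 wDSC rows, right UF at $n = 17$, byte-identical
  reruns; 100 replicate cohorts per generation regime (true ICC 0.9
  vs 0.3) for category separation.

## Known limitations

* Only two sessions are supported end-to-end ($k = 2$); the ANOVA and
  ICC code accepts $k > 2$ but the cohort layout and Bland-Altman
  analysis are strictly paired.
* The wDSC grid is whatever the Time-2 density map (or configured
  grid) uses; the package records voxel size but does not resample
  between grids.
* Degenerate tables (zero error variance) yield boundary results
  (ICC = 1, degenerate CI, p = 0) with warnings rather than errors, to
  keep simulation sweeps running.
* TRK support covers version-2 files with a valid `vox_to_ras` affine;
  pre-v2 files without one are rejected rather than guessed at.
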