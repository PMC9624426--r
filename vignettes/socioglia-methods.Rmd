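---
title: "Quantifying microbiota effects on zebrafish social circuits: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microbiota effects on zebrafish social circuits: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socioglia)
```

# Scope

`socioglia` implements, as one tested pipeline, the quantification chain
used to link microbiota status in larval zebrafish to (i) dyad social
behavior, (ii) single-neuron arbor morphology in the ventral
telencephalon, (iii) forebrain microglial distribution and morphology,
and (iv) microglial gene expression. Every stage consumes standard file
formats (trajectory CSV, SWC reconstructions, TIFF label masks +
centroid CSV, MatrixMarket count matrices) and every stage has a seeded
synthetic generator, so the full chain is testable without imaging data.
This vignette records the models, the parameter choices, the numerical
conventions, and the known limits of what the synthetic benchmarks can
show.

# Dyad social behavior

Pairs of sibling fish interact across a transparent divider in adjoining
50 × 50 mm arenas, imaged at 10 frames/s for 10 minutes. Three summary
statistics are computed per fish:

* **Relative proximity** $\frac{1}{T}\sum_t \left(1 - d_t/L\right)$,
  where $d_t$ is the perpendicular distance to the divider wall and $L$
  the arena extent perpendicular to it. 1 means "at the divider".
* **Percent orienting at 45–90°**: the fraction of heading-defined
  frames whose heading, folded against the divider line into
  $[0^\circ, 90^\circ]$, lies in $[45^\circ, 90^\circ]$. Folding counts
  both toward- and away-facing body angles, since only an angular band
  is defined. Under uniform headings the folded angle is uniform on
  $[0^\circ, 90^\circ]$, so the chance level is exactly 50%.
* **Swim speed**: mean per-frame displacement × fps (mm/s).

A fish is *in motion* in a frame when it moved at least one-third of its
body length since the previous frame; the first frame inherits the
second's state. Fish in motion for less than 10% of the assay are
excluded (strictly less: exactly 10% is retained). When no heading
channel is recorded, headings are taken from displacement vectors of
moving frames; stationary frames carry the last defined heading, and
frames before the first movement are dropped from the orienting
denominator, because a displacement heading is undefined at rest.
Whether the original assay used the body axis rather than the
displacement direction is not determinable from the assay description;
both are supported and displacement is the default.

The **optomotor** stage averages distance-to-center traces (30 frames/s)
over trials aligned on stimulus onset — 20 s of concentric rings
simulating motion toward the dish center, then a 20 s refractory period
— and reports the response as mean distance at onset minus mean distance
at offset. Trial counts per fish in the original design ranged from 46
to 59; the generator draws from that range when no count is given.

## What the dyad generator emulates

`gen_dyad()` produces bout-structured swimming: bout onsets are Poisson
(default 1 bout/s), each bout moves the fish for 0.5 s at per-frame
steps drawn around 25 mm/s, and the fish rests between bouts, so the
in-motion filter has non-trivial behavior (about 40–55% of frames in
motion, matching the range reported for real larvae). With probability
`sociality` a bout is social: the fish turns toward the divider-adjacent
strip (5 mm deep) and, inside it, draws a heading whose folded angle
against the divider is uniform on $[45^\circ, 90^\circ]$; otherwise the
heading is uniform. Walls reflect; reflection at axis-aligned walls
preserves the folded angle. The effective bout rate is
$\text{bout\_rate} \times (1 + 0.5\,\text{sociality})$: socially engaged
fish are also more active, which makes all four metrics — not only the
two geometric ones — increase with the planted sociality. At
`sociality = 0` orienting converges to the 50% chance level; at
`sociality = 1` orienting reaches ≈97% and proximity ≈0.88.

The generator does not emulate reciprocal interaction between the two
fish (each trajectory is independent given its parameters), burst-glide
kinematics within a bout, or wall-following behavior; passing tests
therefore show that the *metrics* behave correctly, not that the
generator is a behavioral model of real larvae.

# Arbor morphometry and 3D Sholl analysis

Neurons are rooted trees in SWC form (id, type, x, y, z, radius,
parent; soma type 1; coordinates in μm). Reading validates a single
root, no dangling parents and no cycles, with the offending line
reported.

## Sholl counting

`sholl_profile()` counts crossings of the piecewise-linear skeleton with
concentric spheres centered on the soma, by solving $|p(t)| = r$ exactly
on each segment (a quadratic in $t$; 0, 1 or 2 roots). Conventions:

* Roots are counted on the half-open parameter interval $(0, 1]$ of each
  edge, so a node lying exactly on a shell is counted once and
  attributed to its parent-side edge.
* A segment tangent to a shell (double root) counts once.
* The profile extends to the largest multiple of the step not exceeding
  the maximum soma-to-node distance; counts beyond are zero by
  construction.

Descriptions of this assay sometimes give the shell increment as a
diameter, which taken literally would be a 0.5 μm radius step; profile
axes and convention in the Sholl literature are radii, so the default
is a 1 μm *radius* step, configurable via `step`. Tests compare the analytic
counter against a dense-sampling oracle (points every 0.01 μm, counting
sign changes of $|p| - r$, with the same node-on-shell convention),
exactly, on 100 generated arbors per run.

## The 13-feature vector

Seven features follow the published analysis directly: total length,
mean branch length, arbor depth (the maximum number of bifurcations on
any soma-to-tip path), and the four Sholl summaries (total
intersections, maximum intersections, maximum radius with any
intersection, and the smallest radius attaining the maximum — the
tie-break is "smallest"). The published feature count is 13 without an
enumeration, so the remaining six are standard skeleton statistics:
branch-point, tip and branch counts, maximum soma-to-node Euclidean
distance, maximum soma-to-tip path distance, and axis-aligned bounding
box volume. This reconstruction is a documented deviation: the original
13 Imaris features are not identifiable from the text.

A *branch* is the path between consecutive topological nodes (root,
branch points, tips), so `mean_branch_length * n_branches =
total_length` identically. The soma counts as a bifurcation only when
its degree is ≥ 3. For microglial skeletons, endpoints are the terminal
tips per component, with the component root counted only when its
component is an unbranched path (a straight process has 2 endpoints, a
Y has 2) — the convention that matches endpoint counts from image
skeletons, where the "root" is not a biological soma. Time-series
variability of a per-cell measurement is the sample variance across
timepoints divided by the mean (variance/mean, not CV²; `"mean2"` is
available), so a constant series scores 0 and scaling the series by
$c$ scales the score by $c$.

## The arbor generator

`gen_arbors()` grows trees tip-by-tip in 1 μm steps: at each step a tip
terminates with probability `terminate_prob_per_um`, branches with
probability `branch_prob_per_um` (two daughters deflected 40° at random
azimuths), and otherwise elongates with a 15° per-step directional
jitter (tortuosity, persistence length ≈ 29 μm). Growth is confined to a
150 μm spherical territory around the soma — real arbors are confined to
their brain region, and the published Sholl profiles extend to at most
160 μm — and stops at a depth cap and a total-cable cap. An optional
guaranteed-outgrowth length (`min_total_um`) suppresses termination
early, modelling obligatory primary neurite extension. The defaults
(branch 0.04/μm, terminate 0.005/μm, 400 μm cap) give arbors of
realistic scale (tens to hundreds of μm of cable) spanning unbranched
paths to depth-10 trees.

# Morphotype clustering and factor analysis

Features are z-scored per column (sample SD; constant columns map to
zero with a warning). Hierarchical clustering uses squared Euclidean
distances with average linkage — "between-groups linkage" in SPSS
terminology is the same algorithm — and reports dendrogram heights on
the squared scale; flat labels come from cutting at a user-chosen `k`
(the published dendrograms are uncut, so `k` is always explicit).

Factor analysis is principal-axis factoring: squared multiple
correlations initialize the communalities, which are iterated on the
reduced correlation matrix; the number of factors is the number of
eigenvalues of the *original* correlation matrix above 1; retained
loadings get a varimax rotation with Kaiser normalization. Two numerical
choices matter:

* **Exact collinearity.** For strictly binary trees
  `n_branches = n_branch_points + n_tips` holds identically, so the
  13-feature correlation matrix is singular. The implementation warns,
  names the involved columns, and proceeds with pseudoinverses rather
  than failing — the analysis is well-defined on the non-null space.
* **Scores.** Regression (Thurstone) scores are the default for a
  well-conditioned correlation matrix. Under singularity the regression
  weights $R^{+}L$ amplify near-null noise directions (weights scale
  with $1/\lambda$), which measurably degrades downstream
  classification, so the `"auto"` method falls back to loading-weighted
  composites $ZL$. Both are available explicitly.

`classify_complex()` finds the factor loading most strongly on
`total_length`, orients it so larger means more complex, and thresholds
the score. The published complex/simple boundary is a line drawn by eye;
the default here is the 1-D two-class split minimizing within-class
variance, with a numeric override.

## The planted morphotype benchmark

`gen_morphotype_groups()` is the package's recovery benchmark: 60
"simple" (0.02 branches/μm) and 60 "complex" (0.10 branches/μm) arbors
under a shared regime — guaranteed outgrowth drawn per arbor from
750–850 μm (biological size heterogeneity), termination at 0.2/μm
afterwards, and a fixed trunk orientation, as for neurons registered to
a common reference. These choices are not arbitrary: average linkage on
squared distances cuts off *single outliers* before it separates groups,
so the benchmark needs every feature to be light-tailed within groups.
Guaranteed outgrowth removes early-extinction dwarf arbors (whose
branch-length ratios are extreme), confinement and tortuosity bound the
spatial-reach features, the shared size jitter gives the bounding-box
volume genuine variance so no single arbor is six standard deviations
out, and the common orientation removes the axis-alignment lottery in
the bounding box. Under this regime the k = 2 cut and the
complex/simple classification both recover the generating labels
perfectly across seeds; with heavy-tailed designs they fail not because
the groups overlap but because the last merge isolates one arbor.

# Volumetrics and affine registration

`density_metrics()` reports: neuropil density = neuropil voxels /
forebrain voxels; microglia per forebrain volume, in cells per
10⁶ μm³ (counts normalized to forebrain volume are conventionally
reported without units; a fixed reference volume makes them comparable);
the neuropil center of mass and the mean microglia z position, each
normalized per axis to the forebrain mask's bounding extent (0–1).
Bounding-box normalization is one reasonable reading of a position
normalized to forebrain size; it is invariant to padding and to voxel
size, which the tests assert. Voxels are cell-centered, 0-based, world =
index × voxel size.

Registration replaces the original intensity-based template step with
its downstream algebra: `fit_affine()` solves the least-squares
12-parameter affine from point correspondences (≥ 4 non-coplanar; QR
with a rank check; residual reported as the per-coordinate RMS), and
`apply_affine()` maps SWC coordinates while leaving ids, radii and
topology untouched. `decompose_affine()` factors the linear part as
$A = R\,\mathrm{Sh}\,\mathrm{diag}(s)$ via QR (rotation, unit
upper-triangular shears, scales), with intrinsic x-y-z Euler angles and
a reflection flag when $\det A < 0$ (the sign is carried by the first
scale); `compose_affine()` inverts the decomposition to 1e-9 or better.
Rigid transforms leave every morphometric feature except the bounding
box, and the entire Sholl profile, exactly invariant — this cross-check
runs in the test suite.

The volume generator builds an ellipsoidal forebrain on the voxel grid,
sizes a concentric neuropil ellipsoid by bisection to the target volume
fraction (within one voxel), and places microglia at voxel centers
(with sub-voxel jitter) sampled with weight $e^{\beta z_{\text{norm}}}$
— `dorsal_bias` $\beta = 0$ is uniform; positive values shift cells
dorsally, emulating the dorsoventral redistribution readout.

# Single-cell expression

The expression module mirrors the reclustering workflow applied to the
mpeg1⁺ immune-cell population: library-size normalization to 10,000
counts per cell, log1p, per-gene z-scaling; truncated SVD to 4
components; a k = 20 shared-nearest-neighbor graph (Jaccard weights of
the neighbor sets, pruned below 1/15); Louvain modularity at resolution
1.25 with a fixed seed. Dot statistics per (cluster, gene) are the
percent of cells with a nonzero count and the mean z-scaled expression.
A cluster's *fingerprint score* is the mean expressing fraction over
the 75 fingerprint genes; clusters scoring ≥ 0.5 are called microglia.
The qualitative rule — microglial clusters express most of the
fingerprint in a large majority of their cells — is formalized by the
score threshold, which is monotone by construction. Condition markers within a cluster are
two-sided Wilcoxon rank-sum tests on the log-normalized layer for genes
expressed in ≥ 10% of either condition's cells, Bonferroni-adjusted over
tested genes, with log2 fold changes of mean normalized expression
(pseudocount 1). Variable-gene selection before the SVD is deliberately
absent (all scaled genes enter), configurable upstream by subsetting.

The generator plants a 392-cell, 6-type mixture — ramified, amoeboid and
proliferative microglia plus three macrophage types, 50–75 cells each,
the same scale as the real subclustered population — with
negative-binomial counts (dispersion 0.5). Microglial types share the
75-gene fingerprint at mean 20; macrophages express a 10-gene subset of
it; each type carries its own 30-gene marker block; remaining genes are
near-silent background (mean 0.01, typical droplet sparsity). Condition
effects are planted per cell type as symmetric log2 fold changes; the
default plants the complement genes c1qa/c1qb higher in CVZ within
ramified microglia and higher in GF within amoeboid microglia, the
direction reported for those populations. Types of 50–75 cells matter
for a structural reason: modularity at resolution > 1 provably splits a
uniform community holding half the graph's weight, so very large
planted blobs fragment regardless of separation. With the default
mixture the subclustering recovers the planted types with ARI 1.0 and
flags exactly the microglial clusters.

What the generator does not emulate: ambient RNA, doublets, batch
structure, library-size gradients correlated with type, or the
continuum between ramified and amoeboid states; marker recovery on this
benchmark shows the testing machinery is correct, not that the defaults
are powered for any particular real effect size.

# The group-comparison harness

Every group comparison follows one decision rule. Gaussianity of each
sample is assessed by the D'Agostino–Pearson omnibus test: the sample
skewness and excess kurtosis are transformed to approximate normal
deviates (D'Agostino's skewness transformation; Anscombe–Glynn for
kurtosis) and $K^2 = z_1^2 + z_2^2$ is referred to $\chi^2_2$. The
implementation was validated against an independent implementation of
the same test, with reference statistics frozen in the test suite; it
requires n ≥ 8, below which the harness falls back to Mann–Whitney with
a warning. If both samples pass at α = 0.05, a Student t test is used
when an F-ratio test finds the variances comparable (at 0.05; what counts as unequal standard deviations is otherwise
unstated, and the F test is the conventional choice) and a Welch t test otherwise;
non-Gaussian samples get the Mann–Whitney U test. For ≥ 3 groups the
same gate selects one-way ANOVA with Tukey's HSD or Kruskal–Wallis with
Dunn's rank tests, the latter tie-corrected and Bonferroni-adjusted
over pairs. One consequence worth stating: with a 0.05 gate per sample,
about 14% of genuinely Gaussian pairs will be routed to Mann–Whitney —
this is a property of the published rule itself, and the calibration
checks are written against what the rule implies, not against a 100%
selection rate.

The size-versus-treatment confound is handled as published: ordinary
least squares of percent orienting on standard length with condition as
a covariate, two-sided per-coefficient tests, and an error on perfect
collinearity. Percentages are analyzed untransformed.

# Problem sizes, determinism and limits

The test suite and the acceptance script regenerate everything they
measure: 100 arbors per oracle-equivalence run, 20 rigid transforms, 20
dyads per sociality level at 5 minutes each, 60 + 60 planted arbors for
morphotype recovery, 100 seeded draws for the factor-count rule, the
392-cell mixture plus a 460-cell marker benchmark and a 500-gene null
run, and 60-draw simulations for the test-selection rule. These sizes
make the whole chain rerun in well under a minute of compute while
leaving the statistical checks decisively powered.

All generators are pure functions of their parameters including the
seed: sub-streams are derived deterministically per fish/arbor/cell, the
caller's RNG state is saved and restored, and community detection is
seeded explicitly. Identical seeds give bitwise-identical artifacts,
which the suite asserts.

Finally, the standing caveat: neurons are analyzed as independent units
even though several may come from one larva, replicating the published
analysis; a nested model is out of scope here and would be the first
extension worth adding for real data.
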