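---
title: "Panoramic maize ear phenotyping: models, measurements and their limits"
author: "EarPheno"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Panoramic maize ear phenotyping: models, measurements and their limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

A maize ear is, to good approximation, a tapered solid of revolution whose
surface carries kernels in longitudinal rows. Inspection-line systems image
the ear as it rotates on a roller conveyor, so no single frame sees the whole
surface and every frame foreshortens the limb of the ear. The measurement
strategy implemented here is the panoramic one: take the narrow band of rows
around each frame's central axis - where the cylindrical projection is
locally isometric and distortion is smallest - and stitch these central
strips over a full rotation into a flat panorama of the lateral surface.
All kernel-level traits are then read off that panorama.

EarPheno implements this pipeline end to end and, crucially, pairs it with a
parametric ear generator whose trait values are known analytically, so that
every stage is testable without access to a phenotyping line.

## The synthetic ear model

`buildEarModel()` resolves an `EarModel`: a revolution profile $r(y)$ on
$[0, L]$ (cm), a kernel lattice, and color/noise parameters.

* **Profiles.** The default `"spindle"` profile is a rounded elliptic butt
  over the first 15% of the length, a cylindrical body, and a cosine taper
  from 70% of the length to a point at the tip - a reasonable dent-maize ear
  silhouette. `"cylinder"`, `"sphere"` (a half-circle profile; a true sphere
  when $L = 2R$) and `"sine"` ($r = R\sin(\pi y/L)$) exist mainly as
  analytically convenient shapes for verification.
* **Lattice.** `nRows` rows are spaced evenly around the circumference
  (pitch $2\pi R/\mathrm{nRows}$ of unrolled arc); `kernelsPerRow` kernels
  fill the axial span $[0, (1-\mathrm{barrenTipFraction})L]$. Kernel
  centroids receive isotropic Gaussian jitter (sd `centroidJitterSd`, cm)
  clamped at 0.4 of the smaller lattice pitch, which preserves row order and
  hence the well-definedness of the true row count.
* **Appearance.** Kernels are drawn as ellipses (semi-axes 0.46 and 0.44 of
  the lattice pitches) with a brighter crown core and a darker rim. The
  crown/rim shading is constructed to be zero-mean over the ellipse, so the
  *mean* rendered kernel color equals the configured color exactly - this is
  what makes the color ground truth exact rather than approximate. The
  grooves between kernels expose cob and form the luminance valleys that the
  segmentation relies on.
* **Noise knobs.** Additive Gaussian pixel noise and an axial illumination
  gradient are available and off by default; the accuracy benchmark uses
  noise sd 5 (8-bit units).

Identical parameters and seed give bit-identical renders; all randomness is
drawn through seeded streams.

`trueTraits()` evaluates the twenty trait definitions on the *resolved*
model: surface area and volume by frustum quadrature of $r(y)$ at step
$10^{-4}L$ (verified in tests against a $10^6$-step trapezoid oracle and
against closed forms for the cylinder and sphere); the barren tip length
from the actual jittered lattice (the tip-most kernel of a jittered ear
protrudes beyond its nominal lattice position by the maximum of the row
jitters, which is measurable at benchmark scale); kernel thickness as the
mean consecutive centroid distance along the resolved rows.

The unrolled panorama uses one angular convention throughout: one full
circumference maps to the raster height at the scale of the maximum radius.
For a cylinder this equals the true isometric unroll, which is why the
stitching consistency test uses a constant-radius model.

## Imaging layer

* **Ear-state detection** declares an ear present when more than `tauArea`
  (2%) of pixels lie farther than `tauColor` (40 RGB units, Euclidean) from
  both the background and the roller reference colors.
  `estimateReference()` derives those two references from an ear-free frame
  by coarse color-histogram binning.
* **Segmentation** thresholds the same color distances, then applies
  morphological closing and opening with a disk of radius 3 px and keeps the
  largest connected component. The disk is the smallest brush that removes
  salt noise without erasing the 1-2 px grooves.
* **Orientation** is normalized from the mask's second moments; rotations
  below half a degree are skipped, near-circular masks (axis ratio < 1.1)
  are left unrotated with a warning, and the butt (the wider end, judged by
  the mean mask half-height over the outer 20% of columns) is flipped to
  x = 0.
* **Central strips** are the rows within `stripHalfWidth` (20 px) of the
  per-column mask midpoint, resampled straight.
* **Stitching** estimates each consecutive pair's circumferential offset by
  maximizing the normalized cross-correlation of strip luminance inside a
  search window around the expected offset (the expected offset is the
  maximum mask radius times the rotation per frame). The scan direction is
  fixed from the first pair. Strips are composited with linear ramp
  blending, and the canvas is folded at the cumulative offset of one full
  rotation, giving a circular (one-circumference) panorama. Pairs whose best
  correlation falls below 0.5 abort with an error naming the pair.

The ear-length trait supports an axial foreshortening correction
(chord-to-arc factor $\theta/\sin\theta$ for a known camera view angle);
the default is the identity, as the camera geometry is configuration the
package cannot infer.

## Kernel layer

Kernel segmentation separates kernel from cob by Otsu thresholding of the
raw luminance (raw, not smoothed - smoothing erodes the darker kernel rims
into the threshold), then floods a watershed on the Gaussian-smoothed
luminance restricted to the candidate mask: regions grow from the bright
crowns down to the groove valleys. Two practical details matter:

* **The seam.** The circumferential axis is periodic and kernels do cross
  the top/bottom raster edge. Segmentation therefore runs on a vertically
  doubled raster and keeps, for each kernel, the copy whose centroid falls
  in a one-circumference window opened at the groove line with the least
  kernel occupancy; the window origin (`wrapOrigin`) travels with the
  `KernelMap` so that graph construction can work in unwrapped coordinates.
* **Centroids** are intensity-weighted (by the squared smoothed luminance
  above threshold), anchoring them on the kernel crowns. When two heavily
  jittered kernels touch and the watershed boundary between them is
  arbitrary, the plain area centroids are pushed apart but the crown-
  weighted ones stay put.

Validity marking applies the area window (defaults: 0.25-4 times the median
region area) and, optionally, an axial border margin for real, clipped
panoramas; the generator's panoramas carry complete kernels to the borders,
so the margin defaults to 0.

Counting follows the graph recipe: Delaunay triangulation over the valid
kernel centroids plus start/end terminal groups placed one observed lattice
spacing beyond the kernel hull, Euclidean edge weights, and Bellman-Ford
shortest paths between the terminal groups; the kernel count of a path is
its number of non-terminal nodes. Bellman-Ford is retained even though the
weights are nonnegative; a textbook Dijkstra reimplementation serves as a
cross-check oracle in the tests, never as the implementation. Ties in path
weight resolve to fewer nodes, then lower predecessor ids, so results are
deterministic.

Three graph-hygiene rules were needed to make path counts equal lattice
counts, and all three are geometric rather than tuned:

* **Long-edge pruning** drops Delaunay edges longer than 3 times the median
  edge length (terminal edges exempt), stopping cross-row shortcuts on
  jittered lattices.
* **Bypass pruning** drops an edge whenever some third node gives a two-leg
  path within 12% of the edge's length. On strongly anisotropic lattices
  (few, widely spaced rows) the Delaunay triangulation legitimately contains
  edges that hop over an intermediate kernel - the empty circumcircle fits
  between the rows - and such an edge is geometrically a path *through* the
  middle kernel. Removing it keeps connectivity (the two-leg path survives)
  and makes shortest paths enumerate every kernel they pass.
* **Guard rings.** A shortest-path band (a row-counting station, the KNR
  central band, or the KT graph near the circular seam) is triangulated
  together with one extra ring of kernels beyond the band (or ghost copies
  across the seam, which never enter counts), because hull-adjacent
  circumcircles bulge into empty space and admit shortcut edges that an
  interior band never sees. Terminals anchor only on the inner band.

Row number (RNE) is the mean of three transverse shortest-path counts at
stations 30/50/70% of the kernel-bearing span (each station uses kernels
within one median spacing); it is reported unrounded, per the trait
definition. Kernels per row (KNR) is the maximum axial path count over the
start terminals of the central 50% of the circumference. KNE is the number
of valid kernels.

**Known counting limit.** When two kernels of one row jitter nearly on top
of each other (axial offsets beyond roughly 3 standard deviations of the
benchmark jitter), both genuinely lie on the transverse path line and one
station counts the row twice. One affected station shifts the unrounded RNE
by 1/3, which still rounds to the correct integer; the tests therefore
compare rounded row counts under heavy jitter (0.15 lattice spacings, where
at least 19 of 20 ears are exact) and use 0.05-spacing jitter for the
strict, unrounded 50-ear recovery suite.

## Trait layer

The radius profile is the per-column mask half-extent averaged over frames.
For the surface/volume integrals the profile is smoothed with a 5-sample
running mean first: the staircase quantization of a mask boundary otherwise
inflates the frustum slant lengths on tapered spans by a few percent while
leaving widths and volumes almost untouched. Tip position is recovered by
extrapolating the lower taper flank (radii below 35% of the maximum) to
zero radius, because the morphological brush eats the last few
single-pixel-wide columns of a pointed tip.

The trait formulas themselves:

* $EV = \sum \pi\,\frac{r_i^2 + r_{i+1}^2}{2}\,\Delta y$ and
  $ESA = \sum \pi (r_i + r_{i+1}) \sqrt{\Delta y^2 + \Delta r^2}$
  (composite frustum rule, end caps excluded - ears taper to near-zero
  radius, so caps are negligible, and the cylinder test values are stated
  cap-free).
* $EW$ is the mean diameter over profile samples with $r \ge 0.25\,\max r$
  (excluding the tapered ends from the average); $EP = \pi\,EW$ identically.
* $ES = ESA / \left(\pi^{1/3} (6\,EV)^{2/3}\right)$, the surface area
  relative to the equal-volume sphere (the reciprocal Wadell sphericity):
  1 for a sphere, larger for any other shape. "Non-sphericity index" is an
  umbrella term in the morphometrics literature; this exact formula is the
  package's chosen reading and is stated prominently for that reason.
* $BTL$ is the axial distance from the (extrapolated) profile tip to the
  right edge of the furthest valid-kernel pixel; $BTA$ integrates the
  frustum rule over that span. Both are resolved to about 2 pixels, which
  is also the tolerance the trait definition itself carries at this pixel
  size.
* $AKA$ is the mean valid-kernel pixel area in cm²; $KT$ (kernel thickness,
  i.e. the stacking pitch along a row) is the mean consecutive-centroid
  distance along the axial shortest paths; $KW$ (crown width) is the mean
  transverse bounding extent. An alternative reading of "kernel width" as
  the spacing along the transverse path would measure the row pitch
  instead; the bounding-extent reading was chosen because crowns, not row
  spacing, are what a breeder calls kernel width.
* Ear colors average over the whole ear region - kernels, exposed cob and
  barren tip alike - while kernel colors average over valid kernel regions
  only. Specular highlights do not exist in the renderer, so no highlight
  exclusion is implemented or needed.

## Quantitative genetics layer

`fitMixedModel()` fits $y = X\beta + Z_g u_g + Z_{gl} u_{gl} + \epsilon$
with site fixed and genotype and genotype-by-site random (the interaction
enters only with two or more sites; which effects are fixed follows standard
multi-environment BLUP practice). Variance components are estimated by
EM-REML on Henderson's mixed-model equations - derivative-free and
guaranteed to stay in the parameter space - with three numerical choices:

* the genotype-by-site block of the equations is diagonal, so each iteration
  eliminates it by a Schur complement and solves only a
  (sites + genotypes)-sized dense system;
* convergence is declared when the largest component change falls below
  $10^{-8}$ of the total variance (a per-component relative criterion stalls
  on boundary components whose relative wobble is numerically meaningless);
  components creeping to the boundary are absorbed to exactly zero and
  pinned by a large ridge, and Aitken extrapolation is applied along the
  geometric EM trajectory every few iterations - EM alone approaches zero
  components only geometrically slowly;
* a zeroed or tiny residual variance leaves the intercept/genotype
  confounding resolved only in the limit, so the variance ratio ridge is
  floored at $10^{-8}$ for conditioning.

On balanced single-site data the estimates agree with the ANOVA
method-of-moments estimators to $10^{-6}$, and on two-site data with lme4's
REML to at least four decimals (lme4 is a test oracle only). Broad-sense
heritability is $H^2 = V_g / (V_g + V_{gl}/L + V_e/(LR))$; $R$ is an
explicit input everywhere, never inferred from the data, because with
multiple ears per plot the effective replication is a design decision the
data table cannot reveal.

Per-SNP phenotypic variance explained is computed exactly as
$\mathrm{PVE} = 2\beta^2 af(1-af) / (2\beta^2 af(1-af) + se^2\,2N\,af(1-af))$;
the allele-frequency factors cancel algebraically to
$\beta^2/(\beta^2 + N\,se^2)$, and the tests assert that identity to
$10^{-12}$. SNP QC keeps markers with MAF strictly above 0.05 and call rate
strictly above 0.9 (strict, following the wording "more than" / "greater
than"); MAF is folded to at most 0.5 and computed from non-missing calls.
Spearman correlations use mid-ranks and the $t$ approximation for p-values
(exact permutation nulls are impractical at panel scale), Holm-corrected
over the unique trait pairs; subpopulation comparisons run a one-way ANOVA
plus all pairwise Welch tests, Holm-corrected ("pairwise comparison test"
is underspecified; Welch avoids the equal-variance assumption). Holm
adjustment itself is delegated to `stats::p.adjust`; a brute-force
step-down implementation in the test suite checks it over all permutations
of up to six p-values.

## Benchmark conditions and problem sizes

The accuracy benchmark (`benchmarkAccuracy()`, also what
`scripts/acceptance.R` runs) draws 100 ears with lengths uniform on
12-20 cm, maximum radii uniform on 2.2-2.6 cm, row numbers uniform on
{8, 10, 12, 14, 16, 18}, axial kernel pitch near 0.45 cm, barren tip
fractions uniform on 0.05-0.15, centroid jitter sd 0.1 lattice spacings,
and additive pixel noise sd 5 - one render per ear of 28 frames at
15°/frame plus ear-free lead-in/lead-out frames, at the native pixel size
of 3.126e-2 cm/px. The frames-per-ear and rotation step are free
parameters of this package (the rotation geometry of the source system is
not public); 28 x 15° gives 420° of coverage and roughly 50% strip
overlap, comfortable for correlation-based stitching. Scores are the mean
ear-length accuracy (100% minus the mean absolute relative error) and the
fraction of ears whose rounded row number is exact.

The test suite's heavier blocks use 50 clean ears for trait recovery, 20
simulation replicates of a 300-genotype, 2-site, 3-replicate balanced
design for EM-REML recovery (true $V_g = 4$, $V_e = 1$, with a modest
$V_{gl} = 0.5$ so the interaction term is non-degenerate), and exhaustive
oracles only at sizes where exhaustion is cheap (Delaunay point sets up to
n = 12, path enumeration up to 10 kernels, Holm permutations up to 6).

## What passing tests do and do not show

The generator emulates the geometry, the color statistics, the rotation
kinematics and the pixel noise of an ear line, and the recovery suites show
the pipeline reads its own ground truth back through rendering,
segmentation, stitching and counting. It does **not** emulate husk or
silk debris, specular highlights, depth-of-field blur, irregular (non-
lattice) kernel packing, doubled or aborted kernels, or lens distortion.
Accuracy figures on synthetic ears are therefore upper bounds on real-world
performance: they validate the algorithmic machinery, not the biology of
difficult ears. The quantitative-genetics layer, by contrast, is exact
arithmetic on its inputs and transfers directly.

Other known limitations: stitched panoramas of strongly tapered ears blur
near butt and tip (strips composite at the mid-body offset, while the local
circumference shrinks with the radius), which is why kernel-level recovery
is only claimed - and only holds - where the counting stations live, on the
near-cylindrical body; and the degenerate near-coincident-kernel case
described above bounds exact unrounded row counting at high jitter.
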