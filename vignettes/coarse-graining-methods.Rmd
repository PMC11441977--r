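---
title: "Multiscale coarse-graining of cortical surfaces: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale coarse-graining of cortical surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

The cerebral cortex is a folded sheet. Three whole-hemisphere measures
summarise its morphology: the total pial surface area $A_t$ (including the
walls of buried sulci), the exposed area $A_e$ (the area of the convex hull,
the "cling-film" wrap of the hemisphere) and the average cortical thickness
$T$. Across mammals these obey a universal scaling law,

$$A_t \, T^{1/2} = k \, A_e^{5/4},$$

with a near-invariant dimensionless offset $k$. Writing the law as
$A_t/A_0 = (A_e/A_0)^{1.25}$ with $A_0 = T^2/k^4$ makes its fractal reading
explicit: intrinsic size grows as extrinsic size to the power 1.25, i.e. the
cortex behaves like a self-similar surface of fractal dimension
$d_f = 2 \times 1.25 = 2.5$ probed at resolution $A_0$. $A_0$ is the area of
the smallest possible gyri and sulci: a cortex with $A_t = A_e = A_0$ sits at
the threshold between gyrencephaly and lissencephaly.

This package implements the constructive test of that reading: a
coarse-graining ("melting") operation that renders a cortex at any chosen
spatial scale $\lambda$, erasing folds smaller than $\lambda$ while keeping
the surface closed, plus the measurement, rescaling, shape-coordinate and
regression machinery needed to follow an object through scales.

## Coarse-graining

`voxelise_ribbon()` segments the space between the pial and white surfaces
into a grid of $\lambda^3$ boxes. A box is occupied iff it intersects the
cortical ribbon with positive measure: it meets the pial solid and is not
strictly inside the white solid (for single closed meshes, iff it meets the
mesh interior). Occupancy is deliberately conservative — any partial overlap
counts — because that is what fuses sulcal walls closer than $\lambda$ and
produces the melting behaviour. Classification is exact for watertight
meshes: boxes meeting any triangle are found by separating-axis
triangle–box tests; the remaining boxes are classified by ray-parity tests
at box centres, amortised over 6-connected components. Boxes touched only in
a set of measure zero (surfaces lying exactly in a grid plane, common for
axis-aligned test objects) are classified individually so that the component
fill cannot leak across a coplanar surface.

`extract_surfaces()` partitions the empty boxes by flood fill from the grid
border (6-connectivity for the background, the standard complement of a
26-connected foreground) into exterior and interior cavities. The outer
(pial-equivalent) surface bounds the occupied-plus-cavity solid; the inner
(white-equivalent) surface bounds the cavities and disappears once the
interior melts shut.

Two surface estimators are provided:

* `faces` — the exact union of box faces. Areas are integer multiples of
  $\lambda^2$; all voxel-arithmetic identities hold exactly, which makes this
  the oracle-friendly estimator. Its price is the staircase bias: the
  voxel-face area of a smooth surface converges to 3/2 of the true area.
* `marching` — the iso-surface of the binary occupancy at level 0.5. We
  extract it by marching tetrahedra over the box-centre lattice (a six-tet
  decomposition of each cell with consistent face diagonals, so the result is
  watertight by construction; with a binary field the iso-vertices sit at
  lattice-edge midpoints). Optional Taubin $\lambda|\mu$ smoothing removes
  staircase ripple while changing enclosed volume by well under 1% per 10
  iterations.

**Estimator calibration (analytic fixtures).** On a digitised ball the raw
marching-tetrahedra area overestimates the true sphere area by about 30%;
Taubin smoothing reduces this to roughly +13% (20 iterations) and +9%
(40 iterations) at $\lambda = r/40$, while the convex-hull area $A_e$ of the
same iso-surface is accurate to a few percent (its only bias is the genuine
half-box inflation of conservative occupancy, which enters $A_t$ and $A_e$
alike and therefore cancels in their ratio). Because the residual staircase
factor is nearly constant across scales, it offsets $K$ without affecting
the slope of a $K(S)$ trajectory — convex objects stay on a line of slope
$-1/9$ even though $A_t/A_e$ sits a few percent above 1. Tests and outputs
always record the estimator settings used.

The default scale grid is 20 values log-spaced between the mean input edge
length (floored at 0.25 mm) and a quarter of the largest bounding-box
extent. Scales where fewer than 8 boxes remain are flagged degenerate rather
than dropped. A `jitter` origin policy draws a uniform offset in
$[0,\lambda)^3$ (seeded) to support robustness-over-realisations
experiments; the default origin is aligned to the padded bounding box.

## Measurement, rescaling, and K/I/S

For each realisation, $A_t$ is the outer-surface triangle-area sum, $A_e$
the convex-hull area of its vertices (computed by an exact incremental hull),
$V = N\lambda^3$ the occupied volume and $T = 2V/(A_t + A_i)$ with $A_i$ the
inner-surface area. This thickness estimator is exact for slabs and
concentric shells, and degrades gracefully to $2V/A_t$ after the cavity
melts. Note the slab identity includes the side walls in $A_t$, so a slab
must be wide relative to its thickness for $T$ to approach the physical
thickness; the calibration tests use a 100:1 aspect.

Native-scale measurements take $A_t$, $A_e$ and $V$ from the meshes directly
and estimate $T$ as the symmetric mean nearest-surface distance between the
pial and white surfaces (exact for concentric tessellations; per-vertex
thickness files may be substituted upstream where available).

Coarse realisations are made shape-comparable by isometric rescaling with
$s = \lambda_{\mathrm{ref}}/\lambda$ (areas $\times s^2$, thickness
$\times s$, volume $\times s^3$): fixing the box as the unit of length is
equivalent to shrinking the surface, so rescaled thickness decreases under
melting. Conservative occupancy thickens the ribbon by up to about half a
box per side, so rescaled thickness can exceed the native value by at most
$O(\lambda_{\mathrm{ref}})$; the tests bound this by
$\sqrt{3}\,\lambda_{\mathrm{ref}}$.

The shape coordinates are the orthogonal log-linear combinations

$$K = \log A_t - \tfrac54 \log A_e + \tfrac14 \log T^2, \quad
  I = \log A_t + \log A_e + \log T^2, \quad
  S = \tfrac32 \log A_t + \tfrac34 \log A_e - \tfrac94 \log T^2,$$

in base-10 logs (the base is recorded in outputs; $K$ and $S$ values are
base-dependent). $K$ is the scaling-law offset direction, $I$ pure isometric
size, $S$ morphological complexity. Scaling a shape by $c$ leaves $K$ and
$S$ unchanged and shifts $I$ by exactly $6\log_{10} c$; any shape with
$A_e = A_t$ satisfies $K = -S/9$ identically, which is the convex reference
line in the $K \times S$ plane. Raw coordinates are canonical; dividing by
the coefficient-vector norms ($\sqrt{42}/4$, $\sqrt3$, $\sqrt{126}/4$) gives
the normalised plane as a flag — unit-norm directions being the only
parameter-free choice.

## Fitting and classification

`fit_scaling_law()` regresses $\log_{10}(A_t\sqrt T)$ on $\log_{10} A_e$
by OLS, exactly the algebraic form of the law above (an alternative axis
convention that plots $A_t T$ is exposed as a plotting choice only, not used
for fitting). It reports $\alpha$ with a t-based confidence interval,
$\log_{10} k$, $d_f = 2\alpha$, $R^2$ and $A_0$ at the reference thickness.
A fit range in $\lambda$ can restrict the points, since different objects
are self-similar over different scale bands. Group fits are two-stage by
default (per-object OLS, then t statistics over objects, intercept spread as
the SD of per-object intercepts); a random-intercept common-slope mixed
model (lme4) is available and reports the same fields.

`box_count_dimension()` is the classical route: the slope of $\log_{10} N$
against $\log_{10}(1/\lambda)$ over the occupied-box counts of the same
voxelisation — the solid cube gives exactly 3, the thin slab exactly 2.

`classify_trajectory()` summarises a trajectory by the OLS slope of $K$ on
$S$: `convex-line` within 0.02 of $-1/9$ (small residuals), `flat-fractal`
when $|$slope$| < 0.02$ and the $K$ range is below 0.05 (a constant-$K$
trajectory is the signature of $d_f = 2.5$), otherwise `other`. For non-flat
trajectories we report the slope itself rather than converting it to a
dimension, because the slope-to-$d_f$ mapping away from the flat case is not
identified by the measures alone. All thresholds are configurable and
reported.

## Synthetic shapes: what they emulate and what they do not

All fixtures are closed shells or boxes so that every pipeline precondition
(watertightness, containment) holds by construction, mirroring hemisphere
topology. The white surface of folded shells is built by a *radial* inward
offset ($r_{\mathrm{white}} = r_{\mathrm{pial}} - t$) rather than a
vertex-normal offset: a radial graph over the sphere is star-shaped for any
positive radius, so the construction cannot self-intersect and containment
is analytic — at the cost of the perpendicular thickness being slightly
below $t$ on steep fold walls.

* `make_slab()` / `make_cube()` — convex references with closed-form area
  and volume.
* `make_sphere_shell()` — concentric icospheres; lissencephalic reference
  with exact native thickness.
* `make_sinusoid_shell()` — radial displacement by sums of randomly oriented
  spherical plane waves per frequency band, unit-rms per band, scaled to the
  requested rms amplitude. The wavelength of a band is $2\pi R/f$; the gaps
  between its ridges are about half a wavelength wide, so a band starts
  fusing at $\lambda \approx w/2$ and its area excess is largely gone for
  $\lambda > w$. We quantify the fold excess as $A_t - A_e$ of the same
  realisation (convexity deficit): comparing against a plain sphere instead
  would conflate erasure with the genuine envelope growth of a melted
  folded object.
* `make_fbm_shell()` — a fractional-Brownian-like radial field: log-spaced
  frequency octaves with per-octave rms $\propto w^H$ (spectral density
  $\propto f^{-2(H+1)}$), giving a graph dimension of $3 - H$ over the
  synthesised band. The defaults ($R = 20$ mm, rms amplitude $R/2.5$, band
  from 4 mesh edges to $R/2$) were chosen from a structure-function analysis
  so that the relief within a counting box dominates the box size over the
  probed band — the regime in which box counting can see the fractal
  scaling.
* `make_cohort()` — two groups of folded shells with per-subject seeded
  phases and log-normal amplitude jitter; group B differs only in one
  band's amplitude. This emulates two populations whose morphology differs
  at a single spatial scale, with the between-subject variance concentrated
  in a different (smaller-scale) band, the way ageing effects can hide
  inside native-scale variability.

**Known limitations.** A radial shell cannot carry relief much larger than
its radius, so the self-similar band of the fBm fixture spans roughly one
decade and the box-count estimator compresses extreme dimensions toward the
centre of its range: at the default resolution $H = 0.5$ lands on
$d_f \approx 2.4$, comfortably bracketing the cortical value 2.5 within
estimator tolerance, but $H = 0.3$ (theory 2.7) is recovered low at about
2.4 as well. The ordering across $H$ is preserved (tested with common random
numbers across $H$), and both estimation routes (box count and area
scaling) agree within 0.2; absolute recovery of extreme $H$ would need
meshes and grids beyond what routine test runs should cost. None of the
synthetic shapes attempts to reproduce real gyral geometry — coarse-grained
surfaces are morphometric objects, not anatomical predictions — so passing
tests validate the estimators and the pipeline, not anatomical claims about
any particular brain.

## Group comparison across scales

`compare_groups()` compares a chosen metric (default $A_t$, rescaled; a
flag switches to raw physical values) between two cohorts at every shared
scale: Cohen's d with the pooled SD (Hedges' g deliberately not the
default, matching the classical definition) and the Wilcoxon rank-sum z
with continuity and tie correction, positive when the first group is
larger. Effect sizes are the primary output; p values are reported for
reference and gate nothing, and no multiple-testing correction is applied
across scales by default (the curve is descriptive; a Bonferroni flag
exists for pre-registered single-scale tests). `peak_effect_scale()` returns
the scale of maximal absolute effect (ties resolved to the smallest scale,
boundary maxima flagged) together with the native-scale effect, the
headline contrast between scale-resolved and conventional analysis.

`area_fraction_below_scale()` reports $1 - A_t(\lambda_c)/A_t(\text{native})$
— the fraction of native area carried by features smaller than
$\lambda_c$ — using physically sized (unrescaled) areas, interpolated
log-linearly between grid scales; applying a common rescaling factor to
numerator and denominator would not change the ratio, while per-scale
factors would make it depend on the reference scale, so raw areas are the
meaningful choice.

## Numerical choices and problem sizes

Grids are padded by one empty box on all sides; jittered origins require a
seed and are bitwise-reproducible. Ray-parity tests retry along a fixed
sequence of irrational directions on degenerate hits, so results are
deterministic without global RNG state. The convex hull uses an exact
incremental algorithm with outside-point sets and a relative tolerance of
$10^{-10}$ of the point-cloud extent. All generator randomness flows through
explicit seeds; generators are pure functions of (specification, seed).

Routine tests and the acceptance script use deliberately modest problem
sizes — icosphere subdivisions 3–6 (1.3k–82k faces), grids of up to a few million
boxes, cohorts of 10 subjects per group, 100 null replicates at subdivision
4 — chosen as the smallest sizes at which each property under test is
expressed with a clear margin. The same functions run unchanged on full
FreeSurfer meshes (~300k faces per hemisphere); only the wall-clock cost
grows.
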