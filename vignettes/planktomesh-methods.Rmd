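---
title: "Methods: mesh morphometry, image validation and equivalent-sphere scattering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mesh morphometry, image validation and equivalent-sphere scattering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planktomesh)
```

`planktomesh` supports a workflow in which realistic 3D models of
phytoplankton cells — typically reconstructed from scanning electron
micrographs — are measured, validated against the micrographs, and used as
inputs to simple optical baselines. This vignette documents the models and
procedures, the parameters that matter, the numerical choices, and the
limits of what the synthetic test fixtures demonstrate.

## Mesh representation and file formats

A `triangle_mesh` is an indexed triangle soup: an $n \times 3$ vertex
matrix and an $m \times 3$ matrix of 1-based vertex indices,
counter-clockwise when seen from outside. STL and OBJ are supported in both
directions. Neither format carries units; the package's convention is
micrometres throughout, with `scale_mesh()` (and the CLI `--scale` flag)
for models exported on another scale. This matters in practice: deposited
models from third-party pipelines may be in arbitrary units, and every
morphometric quantity inherits the coordinate unit (area as the square,
volume as the cube), so a unit mistake is a factor of $10^6$–$10^9$.

Two deliberate parser choices:

- STL facet soups are indexed by merging vertices that are *exactly* equal
  in all three coordinates. Exact equality keeps the topology deterministic;
  a tolerance weld would make watertightness depend on a threshold. Meshes
  written by ordinary exporters duplicate shared vertices bit-identically,
  so exact merging recovers the intended topology.
- The OBJ reader takes geometry only (`v`, `f`), ignores `vt`/`vn`
  references and materials, and fan-triangulates polygons around their
  first vertex. Texture handling is out of scope.

Binary STL stores 32-bit floats, so a double-precision mesh loses precision
on its first write; from the second write onward the cycle is byte-stable
(verified in the tests).

## Morphometry

Surface area is the sum of triangle areas via the cross product. Biovolume
uses the divergence theorem,
$V = \left|\sum_f v_0 \cdot (v_1 \times v_2)\right|/6$, which is exact for
closed meshes and translation-invariant. Taking the absolute value at the
end means a globally inverted mesh (inward normals, common in archived STL
files) still yields a positive volume, while *mixed* windings are a hard
error: the per-face signs disagree and no meaningful volume exists. The
`fix_orientation` option repairs mixed windings by flood-filling a
consistent orientation across edge-adjacent faces before integrating.

Watertightness is the classical 2-manifold test — every undirected edge
shared by exactly two faces — and consistent orientation requires each such
edge to be traversed once in each direction. Both are preconditions the
same way a slicer for 3D printing requires them; `boundary_edges` counts
edges used by only one face as a repair hint.

Length, width and depth are the extents of the mesh along the principal
axes of its **surface covariance**: the covariance of the uniform measure
on the triangulated surface, assembled from exact per-triangle second
moments ($E[xx^\top]$ over a triangle is
$(\sum_i v_i v_i^\top + s s^\top)/12$ with $s = \sum_i v_i$), area-weighted.
An alternative we rejected is lumping one third of each face's area onto
its vertices: for asymmetric triangulations (e.g. a box split along
diagonals) the lumped weights tilt the eigenvectors and a
$16.27 \times 3.94 \times 3.24$ box does not measure as its own edge
lengths. The surface-measure covariance is symmetric whenever the surface
is, and is invariant to refinement. Near-equal eigenvalues (spheres) make
individual axes arbitrary; output axes are ordered by extent with a
lexicographic tie-break on the eigenvectors so results are deterministic.
Flat or collinear inputs (third eigenvalue below $10^{-12}$ of the first)
are rejected. `method = "aabb"` exposes axis-aligned bounding-box extents
for comparison with tools that measure the as-exported orientation; the
principal-axis method is the default because it is rotation-invariant.

Equivalent diameters are $d_{ESA} = \sqrt{SA/\pi}$ and
$d_{ESV} = (6V/\pi)^{1/3}$. The isoperimetric inequality guarantees
$d_{ESA} \ge d_{ESV}$ with equality only for a sphere; the package treats a
violation on a watertight mesh as an implementation bug, and the tests
assert the inequality on every fixture.

## Geometric shape proxies

Before realistic meshes, cell surface area and biovolume were estimated by
assigning each taxon a simple solid. The package provides the standard
closed forms (sphere, prolate/oblate spheroid, capsule, cylinder), the
Thomsen approximation for general ellipsoids
($p = 1.6075$, relative error $\le 1.1\%$), and a pyriform **drop of
revolution** for pear-shaped dinoflagellates: a quarter-ellipse profile
from the rounded anterior to the widest point at `shoulder * length`,
joined $C^1$-continuously to a cosine taper
$r(z) = (W/2)\cos(\pi t/2)$ ending in a true point. The cosine taper was
chosen (over, say, a smoothstep cubic) because its posterior slope is
finite and nonzero — a pointed end, matching the gross morphology it
emulates — while staying below the quarter-ellipse everywhere, so the drop
volume is strictly less than the circumscribing ellipsoid's. Drop surface
area and volume use adaptive quadrature (`stats::integrate`, relative
tolerance $10^{-8}$/$10^{-10}$).

## Synthetic fixtures: what they do and do not show

`make_icosphere()` (subdivided icosahedron, $20 \cdot 4^s$ faces, vertices
projected to the radius) and `make_revolution()` (rings with cosine-spaced
z-levels and triangle-fan pole caps, so poles are never degenerate
quadrilaterals) generate watertight, consistently oriented meshes with
closed-form ground truth. Two presets put them at the scale of the study
organisms: a $40 \times 25\,\mu m$ pyriform drop and a
$16.27 \times 3.94\,\mu m$ prolate spheroid, dimensions taken from typical
light-microscopy descriptions of the two taxa. Optional jitter displaces
vertices along their normals by uniform noise up to 1% of the half-extent —
enough to break perfect symmetry, small enough to preserve watertightness
and avoid self-intersection.

`make_image_pair()` renders a shaded ellipse (dome profile, bright centre,
darker rim) on a dark flat background, then applies a known monotone
brightness transform (identity or gamma) plus optional Gaussian noise,
clipped and rounded to the bit depth, and returns the exact foreground
mask. It is deterministic for a given seed and restores the caller's RNG
state.

These fixtures validate the *algorithms*: convergence of mesh morphometry
to closed forms, inversion of monotone photometric distortions, mask
recovery on clean boundaries. They do not emulate what makes real SEM
comparisons hard — charging artifacts, background impurities, texture from
surface ornamentation, partially occluded outlines, or geometric
misalignment between render and micrograph. Passing tests therefore show
correctness of the computations, not that a given real model is accurate.

## Image validation pipeline

The pipeline for a pre-aligned render/micrograph pair is fixed and
deterministic:

1. **Mask** from the SEM image: Sobel gradient magnitude, Otsu threshold on
   the gradient map, morphological closing (disc, default 5 px), hole fill,
   then retention of connected components covering at least
   `min_object_fraction` (default 1%) of the frame. Thresholding the
   *gradient* rather than the intensity makes the mask robust to monotone
   brightness differences between the two sources.
2. **Histogram matching** of the render to the micrograph, restricted to
   in-mask pixels on both sides — matching over the (black) background
   would bias the mapping. The map sends a source value with mid-rank CDF
   $p = (F(v^-) + F(v))/2$ to the reference quantile at $p$ (piecewise
   linear between observed values). The mid-rank convention makes a
   constant source map to the reference median, and the mapping is
   idempotent: re-matching an already matched image changes no pixel.
3. **Relative difference** per in-mask pixel, $|X^M_i - X^S_i|/X^S_i$,
   normalised by the SEM intensity. The statistic is intentionally
   asymmetric — the micrograph is the reference. Pixels with zero SEM
   intensity have no defined ratio; they are excluded and counted
   (`excluded_zero_pixels`) rather than regularised with an epsilon, which
   would introduce an arbitrary constant into every summary. The mean and
   median over defined pixels are both reported; maps are best inspected
   via `autoplot()`.

Geometric registration (view angle, scale) between render and micrograph is
the user's responsibility, as it is in manual comparison workflows.

## Equivalent-sphere scattering

The Lorenz–Mie solution for homogeneous spheres provides the classical
baseline for phytoplankton optics. Coefficients $a_n, b_n$ come from
Riccati–Bessel functions with the logarithmic derivative $D_n(mx)$ by
downward recurrence (started 16 orders above
$\max(N, |mx|)$, stable for absorbing indices) and $\psi_n, \chi_n$ at the
real argument by upward recurrence; the series is truncated at the Wiscombe
criterion $N = \lceil x + 4x^{1/3} + 2 \rceil$. Defaults follow common
practice for phytoplankton: $\lambda = 0.532\,\mu m$ and relative index
$m = 1.05 + 0.01i$, passed through exactly as given; a `medium_index`
option rescales the wavelength for users who want in-water wavenumbers.

From the amplitudes $S_1, S_2$ the package reports the parallel (HH,
$|S_2|^2/k^2$, the primary output), perpendicular (VV) and unpolarised
differential scattering cross sections in $\mu m^2\,sr^{-1}$ on an angle
grid (default $0$–$180^\circ$ at $1^\circ$). The backscattering cross
section integrates the unpolarised DSCS over
$\theta \in [90^\circ, 180^\circ]$ with solid-angle weighting by the
trapezoid rule **on the configured grid** — it is therefore grid-dependent
but reproducible. The grid must resolve the phase function: a $1^\circ$
grid reproduces the series $c_{sca}$ to better than 0.1% for size
parameters up to roughly $x \approx 7$, while a $x \approx 150$ sphere
(the scale of a $25\,\mu m$ cell at 532 nm) has a forward lobe narrower
than $1^\circ$ and needs a correspondingly finer grid (the tests use
$0.01^\circ$ there). `equivalent_sphere_spectra()` runs the computation at
a report's $d_{ESA}$ and $d_{ESV}$.

T-matrix or DDA scattering of the actual non-spherical meshes is out of
scope; the spherical baselines are exactly the comparison curves such
studies plot alongside their shape-resolved results. Homogeneous spheres
ignore internal structure (vacuoles, chloroplasts, frustule walls), which
is known to matter especially for backscattering; the numbers here are
baselines, not predictions for real cells.

## Verification strategy and problem sizes

Every module is tested against ground truth that does not share code with
the implementation: closed-form solids for morphometry; an independent
established mesh library (via full-precision OBJ interchange) agreeing with
surface area and volume to $10^{-9}$ relative; a from-scratch Mie oracle
built on direct Bessel-function evaluation and exact Legendre derivatives,
frozen into the test suite, agreeing to $10^{-6}$ relative; and exact
hand-computable cases (unit cube, single triangles, 2-pixel images)
asserted identically. Property-style tests cover the invariants: scaling
laws ($SA \sim s^2$, $V \sim s^3$), rotation invariance, the isoperimetric
inequality, monotone convergence of icosphere refinement, watertightness of
every generated mesh, idempotence and determinism of the image pipeline,
and energy bounds ($c_{bb} \le c_{sca}$, $q_{ext} \ge q_{sca}$ under
absorption).

Default problem sizes are chosen to be desk-scale: icospheres at 4
subdivisions (5,120 faces), revolution meshes at $128–256 \times 96–128$
resolution (up to ~65,000 faces), images at $256 \times 192$, scattering
grids of 181 angles (18,001 where a fine grid is the point). At these sizes
the accuracy targets (0.2–0.5% against closed forms) are met with a
comfortable margin and the full suite runs in well under a minute.

## Known limitations

- No mesh repair beyond degenerate-face dropping and winding fixes; holes,
  self-intersections and non-manifold vertices are detected (as
  non-watertightness) but not healed.
- Total-cell biovolume only: the volume integral is over the outer surface,
  so wall thickness is included — cytoplasmic volume would need interior
  surfaces the meshes do not carry.
- One mesh, one report: population statistics across individuals are the
  caller's concern (`dplyr::bind_rows()` over reports is the intended
  idiom).
- The edge-detection mask assumes a specimen that is tonally distinct from
  a relatively clean background; heavily textured backgrounds will need a
  tuned `min_object_fraction` or an externally supplied mask (every stage
  accepts one).
- Scattering is for homogeneous spheres at the equivalent diameters, not
  for the mesh geometry itself.
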