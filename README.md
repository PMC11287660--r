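# planktomesh

Quantitative tools for 3D phytoplankton models reconstructed from scanning
electron microscopy (SEM). Realistic triangle-mesh models of cells — built,
for example, by structure-from-motion photogrammetry over tilted/rotated SEM
views — open up morphometry and optics that 2D imaging cannot support:
surface area and biovolume of the actual cell surface, watertightness checks
needed before 3D printing, pixel-level validation of a model against the
micrographs it was built from, and equivalent-sphere light-scattering
baselines for optical modelling. `planktomesh` implements that computable
core as a tidyverse-friendly R package with a command-line interface, plus a
synthetic fixture generator so everything can be exercised without any
external data.

## What it computes

**Mesh morphometry.** For a watertight triangle mesh with vertices
$v \in \mathbb{R}^3$ (coordinates in $\mu m$):

- surface area $SA = \sum_f \tfrac12 \lVert (v_1-v_0)\times(v_2-v_0) \rVert$;
- biovolume $V = \left|\sum_f v_0 \cdot (v_1 \times v_2)\right|/6$
  (divergence theorem);
- spherical equivalent diameters
  $d_{ESA} = \sqrt{SA/\pi}$ and $d_{ESV} = (6V/\pi)^{1/3}$, with
  $d_{ESA} \ge d_{ESV}$ by the isoperimetric inequality — the gap measures
  departure from sphericity;
- length/width/depth as extents along the principal axes of the surface
  covariance;
- watertightness / orientation QC (every edge shared by exactly two faces,
  traversed once in each direction) — the precondition for both the volume
  integral and print slicing.

**Model-vs-SEM validation.** For a render/micrograph pair at the same view:
an edge-detected specimen mask (Sobel + Otsu + closing + hole fill), in-mask
histogram matching of the render to the micrograph, and the per-pixel
relative difference $|X_i^M - X_i^S| / X_i^S$ with its mean and median over
defined pixels.

**Equivalent-sphere scattering.** Lorenz–Mie differential scattering cross
sections (HH/VV and unpolarised) versus angle for homogeneous spheres at the
equivalent diameters, by default at $\lambda = 0.532\,\mu m$ and relative
index $m = 1.05 + 0.01i$, including total and backscattering
($90$–$180^\circ$) cross sections.

Closed-form geometric proxies (spheres, spheroids, ellipsoids, capsules,
cylinders, pyriform drops of revolution) and mesh/image fixture generators
round out the toolkit.

## Worked example

```r
library(planktomesh)

# a watertight pyriform surrogate at dinoflagellate scale (40 x 25 um)
mesh <- plankton_preset("p-micans-like")
mesh
#> <triangle_mesh> p-micans-like: 12034 vertices, 24064 faces (generated)

mesh_morphometry(mesh)
#>   name          n_faces surface_area biovolume length width depth d_esa d_esv ...
#> 1 p-micans-like   24064        2534.    11445.     40  25.0  25.0  28.4  28.0
```

The report says: the surrogate encloses about $11{,}445\,\mu m^3$ behind
$2{,}534\,\mu m^2$ of surface; a sphere with the same surface area would be
$28.4\,\mu m$ across, one with the same volume $28.0\,\mu m$ — the small gap
reflects the drop's mild elongation. From a published model's measured
surface area and biovolume the same conversion gives the published
equivalent diameters:

```r
equivalent_diameters(2341.26, 8714.20)   # P. micans model SA (um^2), V (um^3)
#>   d_esa d_esv
#> 1  27.3  25.5

glance(angular_dscs(scattering_config(diameter = 25.53)))
#>   diameter wavelength  m_re  m_im q_sca q_ext c_sca c_ext  c_bb  b_ratio
#> 1     25.5      0.532  1.05  0.01  1.06  2.06  540. 1056. 0.214 0.000396
```

i.e. the volume-equivalent sphere scatters $540\,\mu m^2$ of cross section,
of which only $0.21\,\mu m^2$ goes into the backward hemisphere. The image
pipeline scores a synthetic render/SEM pair:

```r
pair <- make_image_pair(256, 192, transform = "gamma", gamma = 0.5)
compare_pair(pair$distorted, pair$reference)
#> <comparison_result> 16644 in-mask pixels (0 zero-denominator excluded)
#>   mean relative difference:   0.0021
#>   median relative difference: 0.0027
```

Histogram matching has undone the gamma distortion to within 0.2% per pixel.

A CLI wraps the same functions:

```sh
Rscript inst/exec/planktomesh measure model.stl --round2
Rscript inst/exec/planktomesh mie --diameter 27.30 --csv spectrum.csv
Rscript inst/exec/planktomesh compare --sem sem.tif --render render.tif --out diff.tif
```

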