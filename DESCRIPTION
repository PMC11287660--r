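Package: planktomesh
Title: Mesh Morphometry, Image Validation and Equivalent-Sphere Scattering
    for 3D Phytoplankton Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantitative work with triangle-mesh models of
    phytoplankton cells reconstructed from scanning electron microscopy.
    Reads and writes STL (binary and ASCII) and Wavefront OBJ meshes;
    computes surface area, biovolume, principal extents, spherical
    equivalent diameters and watertightness/printability checks; compares
    model renders against SEM micrographs via edge masking, histogram
    matching and per-pixel relative differences; and provides Lorenz-Mie
    equivalent-sphere differential scattering cross sections as optical
    baselines. Includes closed-form geometric shape proxies and a synthetic
    fixture generator so every computation can be exercised without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    stats,
    tibble,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
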