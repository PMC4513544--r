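Package: stackmap
Title: Cartographic Map Projections of Surfaces in 3D Fluorescence Image Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Unfolds the surface signal of multidimensional (up to 5D)
    fluorescence microscopy image stacks onto single, structurally connected
    2D cartographic map projections. An axis-aligned reference ellipsoid is
    fitted to the labeled surface and serves both as the unfolding geometry
    and as the elevation baseline for hypsometric height maps. Every valid
    map pixel carries a cross-reference to the stack voxel that produced it,
    so regions of interest and plot profiles drawn on the map are measured
    on the original voxel data. Nine map projections (equirectangular,
    Mercator, Braun, Miller, Lambert cylindrical, sinusoidal, Mollweide,
    Wagner VI and Bonne) are provided with exact forward and inverse
    formulas, together with a synthetic spheroid phantom generator and a
    surface diffusion simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    graphics,
    grDevices,
    igraph,
    mgcv,
    png,
    pracma,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
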