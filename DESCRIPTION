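Package: molray
Title: Headless Molecular Graphics, Surfaces and Structural Analysis
Version: 0.1.0
Authors@R: person("molray", "authors", role = c("aut", "cre"),
    email = "molray@users.noreply.github.com")
Description: A deterministic, headless molecular graphics toolkit. Molecular
    structures (PDB, mmCIF, DCD trajectories) are rendered by per-pixel
    ray-casting of implicit primitives (spheres, cylinders) and triangle
    meshes into a deferred G-buffer, followed by screen-space post-processing
    (flat/matte/glossy/toon shading, ambient occlusion, fog, outline,
    supersampling anti-aliasing) and snapshot export to PNG with custom
    background transparency. Molecular surfaces use a discrete Solvent
    Excluded Surface pipeline: a solvent-accessible signed field on a regular
    grid, an exact Euclidean distance transform, and marching-cubes
    extraction with gradient normals. Also provides cartoon ribbon meshes,
    trackball and free-fly cameras, distance/angle/dihedral measurements,
    Kabsch superposition and combinatorial-extension (CE) structural
    alignment, plus a command-line interface with JSON sessions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
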