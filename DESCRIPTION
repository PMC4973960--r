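Package: ramanum
Title: Ramachandran Numbers for Protein and Peptoid Backbone Geometry
Version: 0.1.0
Authors@R:
    person("Maintainer", "Packages", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Collapses the two backbone dihedral angles (phi, psi) of a
    polypeptide or peptoid residue into a single structurally meaningful
    scalar, the Ramachandran number R, by rotating the Ramachandran plot
    45 degrees, discretizing it at a configurable resolution sigma and
    raster-indexing the grid. Provides the exact integer codec and its
    inverse (back-mapping with error bounded by 1/sigma degrees), a
    deterministic internal-coordinate backbone builder for geometric
    validation (end-to-end distance maps, round-trip RMSD), readers for
    PDB (single- and multi-model) and classic DSSP output, per-residue R
    traces and R-code histograms for single structures, protein classes
    and trajectories, seeded synthetic fixture generators, and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
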