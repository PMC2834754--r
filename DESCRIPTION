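Package: ppiprofiler
Title: Protein-Protein Interface Descriptors and Druggability Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the structural descriptor panel used to characterise
    protein-protein interfaces with known small-molecule inhibitors directly
    from PDB coordinates: buried accessible surface area (Shrake-Rupley SASA),
    interface segments, gap volume and gap-volume index, planarity and
    eccentricity of the interface plane, hydrogen-bond density, salt bridges,
    secondary-structure interface classes, probe-energy pockets and
    Kabsch-superposition RMSD.  Bundles the curated 17-complex reference table
    of druggable protein-protein interfaces, reproduces its class I/II split
    and PCA/k-means cluster structure, and scores the druggability of a query
    interface by proximity to the reference distribution.  Includes a
    synthetic-structure generator so the whole pipeline is testable without
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
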