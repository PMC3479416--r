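Package: chigrid
Title: Side-Chain Dihedral-Angle Distribution Functions on Protein Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds per-amino-acid dihedral-angle distribution functions
    (DADFs) for interface and non-interface surface residues of bound and
    unbound protein structures, and quantifies their similarity. Includes a
    minimal PDB structure model, Shrake-Rupley solvent-accessible surface
    area with interface classification by SASA loss upon binding, IUPAC
    side-chain chi torsions with symmetry folding for terminal aromatic and
    carboxylate groups, n-dimensional circular histograms with randomized
    split origins, offset-averaged Pearson correlation and Manhattan
    distance across grid spacings with critical-spacing detection, and a
    von Mises/wrapped-normal rotamer-mixture generator for fully synthetic
    end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    Biostrings,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
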