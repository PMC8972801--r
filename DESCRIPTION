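Package: sugarpucker
Title: Conformation-Aware Restraint Dictionaries and Ring-Pucker Validation
    for Pyranose Sugars
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for producing and validating conformation-aware restraint
    dictionary entries for pyranose sugars. Reads and writes monomer-library
    style CIF restraint dictionaries, detects the pyranose ring from
    connectivity, measures ring torsions from low-energy conformer
    coordinates and patches dictionaries with unimodal ring torsion
    restraints (ring_1..ring_6, tight sigma) separated from the remaining
    torsions. Validates sugar models through Cremer-Pople puckering
    coordinates, classification onto the 38 canonical pyranose conformers
    and a yes/no/check diagnosis covering anomeric configuration, chirality,
    puckering amplitude and ring conformation. Includes a masked real-space
    correlation coefficient against Gaussian-atom density grids, a toy
    restrained regularizer demonstrating that unimodal ring torsion
    restraints maintain the minimal-energy chair, and synthetic fixture
    generators for rings, dictionaries and density maps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: bio3d, stats, utils, graphics
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
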