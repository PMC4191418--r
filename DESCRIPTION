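Package: stepflip
Title: Rigid-Body Helical Analysis of DNA Duplexes and Triplexes and
    Base-Flipping Free Energies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the structural analysis of double- and triple-helical
    DNA and for base-pair opening thermodynamics.  Implements base-frame
    fitting to standard reference geometries, the six rigid-body base-pair
    step parameters and local helical parameters in the CEHS/mid-frame
    convention, Zp/Zp(h) conformational classifiers, groove widths, stacking
    overlap areas, bend angles, block-averaged statistics and ensemble PCA.
    A synthetic builder rebuilds helices from step parameters, places a
    reverse-Hoogsteen third strand, and draws Gaussian step-parameter
    ensembles and umbrella-biased samples from known free-energy surfaces.
    The base-flipping machinery covers the pseudo-dihedral reaction
    coordinate, umbrella-window scheduling, periodic WHAM, Shrake-Rupley
    solvent-accessible surface areas, SASA-based open/closed classification,
    and opening free energies with blocked errors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
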