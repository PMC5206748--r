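Package: xdclash
Title: Steric Compatibility Analysis of Antibody-Bound Cadherin Dimer Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to test whether an antibody bound to the adhesive EC1 domain of a
    classical cadherin is sterically compatible with the cadherin's dimeric states.
    Builds hypothetical "dimer plus two antibodies" assemblies by rigid superposition of
    an antibody-antigen complex onto each protomer of a dimer template, scores them by
    grid-based van der Waals overlap volume and a signed clearance margin, and screens
    point mutations (idealized rotamer placement) for designed steric hindrance.
    Includes Kabsch superposition with per-residue deviations, relative domain rotation
    angles, Shrake-Rupley solvent-accessible and buried surface areas, one-site
    isothermal titration calorimetry and 1:1 global surface plasmon resonance kinetic
    fits, epitope calling from mutant binding panels, and seeded synthetic-data
    generators with analytic ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
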