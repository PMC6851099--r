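Package: periloc
Title: Transcription Kinetics and Gene-Locus Relocation to the Nucleoid
    Periphery in E. coli
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of live-cell transcription imaging in
    rod-shaped bacteria. Generates synthetic fluorescence image stacks of
    cells with gene-bound RNA polymerases following an immigration-death
    process; quantifies focus intensity via the region of maximum
    integrated fluorescence (ROMIF) and calibrates it to polymerase counts
    with a single-fluorophore unit; localizes diffraction-limited foci by
    2D Gaussian fitting and maps them into cell-normalized, first-quadrant
    coordinates; fits induction curves to the single-exponential kinetic
    model a(1-exp(-b t)) to derive on/off rates and elongation rates; fits
    first-order mRNA decay and degradation-corrected expression ratios;
    and implements a cylindrical Monte Carlo model of radial locus
    displacement toward the nucleoid periphery, including the inverse
    problem of recovering a physical displacement from a projected
    normalized shift.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    tiff,
    deSolve
Config/testthat/edition: 3
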