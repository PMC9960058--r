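Package: casekin
Title: Kinetics of Micelle Rearrangement During Tryptic Proteolysis of
    Beta-Casein
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the rearrangement of beta-casein micelles during
    proteolysis by trypsin as a three-stage first-order reaction chain
    (intact micelles, hydrolyzed micelles, reassembled nanoparticles,
    peptide products). Provides closed-form and numerical trajectories,
    the transcendental condition for the time of peak nanoparticle
    concentration, least-squares estimation of the enzyme-independent
    rearrangement rate constant from observed peak times, and predicted
    secondary-structure time courses. Includes the FTIR
    difference-spectrum processing chain used to monitor proteolysis
    (reference subtraction, two-anchor baseline correction, equal-area
    normalization, band time courses), quantitative summaries of AFM
    nanoparticle ensembles (height and diameter distributions, volume
    models, sphere-equivalent radii), and synthetic-data generators with
    recorded ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
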