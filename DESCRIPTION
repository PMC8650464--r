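Package: braintransport
Title: Quantification of Macroscopic Solute Transport in the Brain from
    DCE-MRI
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify macroscopic solute transport in the rodent
    brain from dynamic contrast-enhanced MRI (DCE-MRI). The package converts
    T1-weighted signal to gadoteridol concentration via variable-flip-angle
    T1 mapping, segments the brain into transport subdomains (brain tissue,
    surface and branching periarterial spaces, arteries, ventricles), fits
    subdomain effective diffusivities with a diffusion-form finite-volume
    transport model under a no-flux boundary condition, and derives Peclet
    numbers, mean velocities and transport enhancement ratios. A synthetic
    digital brain phantom with known ground truth supports end-to-end
    validation without any experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
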