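Package: putsim
Title: Simulation and Quantification Tools for Photo-Mediated Ultrasound Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the cavitation physics behind photo-mediated ultrasound
    therapy (PUT), in which nanosecond laser pulses superimpose a photoacoustic
    transient onto the rarefaction phase of a low-frequency ultrasound burst to
    nucleate and grow bubbles inside blood vessels. Provides a Keller-Miksis
    bubble-dynamics solver with rectified-diffusion fate classification and
    subharmonic (period-doubling) detection, bisection-based cavitation
    threshold curves and pressure-fluence regime maps, active cavitation
    detection statistics (per-pixel baseline thresholding and cavitation
    probability) for B-mode frame stacks, speckle-variance OCT angiography
    vessel-density quantification with paired significance testing, and
    seeded synthetic-data generators for both imaging pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    tibble
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
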