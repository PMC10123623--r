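Package: laurdanspec
Title: Laurdan Emission Spectral Analysis for Lipid Membrane Hydration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies lipid-membrane hydration and cholesterol effects from
    Laurdan steady-state emission spectra. Implements generalized polarization
    (GP) with windowed intensity averaging, decomposition of spectra into two
    asymmetric log-normal (Siano-Metzler) bands by bounded least squares, both
    per-spectrum and as global fits with shared band peak positions, and
    band-area population fractions of the relaxed and nonrelaxed Laurdan
    populations tracked along a relative-humidity or cholesterol condition
    axis. A calibrated synthetic-data generator emulates dehydration and
    cholesterol series so that every pipeline stage can be exercised and
    validated without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
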