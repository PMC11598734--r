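Package: leafrt
Title: Two-Layer Radiative-Transfer Model of Leaf Reflectance Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analytical forward simulator of reflectance and transmittance
    spectra of dicot leaves with distinct palisade and spongy mesophyll
    layers. Air-leaf boundary optics follow Snell's and Fresnel's laws with
    a rough-surface fraction and hemispherically averaged diffuse
    transmittances; the palisade layer attenuates four light flows
    (collimated and scattered, forward and backward) by the
    Beer-Bouguer-Lambert law with a closed-form backscatter source; the
    spongy layer is solved analytically as a four-flux Kubelka-Munk system.
    Internal reflections are iterated to convergence and accumulated into
    exit totals. Wavelength-dependent absorption is built from chlorophyll a,
    chlorophyll b and carotenoid concentrations and specific absorption
    spectra. Includes spectrum comparison metrics (R squared, RMSE), grid
    scans for model parameterization, pseudo-experimental spectrum
    generation, CSV/YAML interfaces and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    Matrix,
    jsonlite
Config/testthat/edition: 3
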