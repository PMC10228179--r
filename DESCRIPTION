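Package: soretfit
Title: Soret Coefficient Extraction from MicroScale Thermophoresis Traces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies colloid thermophoresis from MicroScale Thermophoresis
    (MST) fluorescence time courses. A forward model couples an axisymmetric
    laser-heating solve (Gaussian beam, Beer-Lambert attenuation) to a
    thermophoretic drift-diffusion solve for the particle concentration, and
    reduces the result to the normalized probe-region concentration Conc(t).
    A two-stage deconvolution first fits the free-fluorophore intensity decay
    (TRIC plus photobleaching, lumped into one exponential) and then matches
    the particle trace against a library of simulated Conc(t) curves to
    extract the Soret coefficient S_T with replicate statistics.
    Electrokinetic side-calculations (Debye length, Debye-Huckel
    zeta-to-charge conversion, surface charge density, and the
    S_T proportional to sigma^2 lambda scaling) and a seeded synthetic-trace
    generator are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
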