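Package: yasdose
Title: Dosimetry of a Beta-Emitting Yttrium-Aluminosilicate Glass
    Brachytherapy Seed
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Dosimetric characterization of a cylindrical
    yttrium-aluminosilicate (YAS) glass brachytherapy seed carrying the
    pure beta emitter 90Y and a 153Sm SPECT marker. Provides a Fermi-theory
    beta spectrum generator, a seedable dose-point-kernel Monte Carlo engine
    (condensed-history kernel generation and volume-source convolution with
    glass self-absorption), extraction of the AAPM TG-60/TG-149 parameters
    (reference absorbed dose rate, radial dose function, 1D and 2D
    anisotropy functions, polynomial fit), thermal neutron activation and
    cooling arithmetic for the glass composition, and implant-level planning
    metrics (lifetime dose, contained-to-apparent activity ratio, isodose
    contours, multi-seed superposition), together with the packaged
    reference tables they are validated against.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    pracma,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
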