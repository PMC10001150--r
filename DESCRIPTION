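Package: eyevit
Title: Finite-Element Simulation of Intravitreal Drug Distribution in a Virtual Eye
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A patient-adaptable simulator for the distribution of
    intravitreally injected drugs (anti-VEGF antibodies) in the human
    vitreous body. Fits a modified-Limacon profile to ultrasound point
    data to obtain a personalized vitreous geometry, solves the steady
    Darcy equation for aqueous-humor percolation with mixed
    (Raviart-Thomas / piecewise-constant) finite elements and a Schur
    complement solver, and advances a convection-diffusion equation for
    the drug concentration over a 30-day horizon with the strongly
    A-stable fractional-step theta scheme, including gravity settling
    and an anisotropic-diffusion hook. Therapy-evaluation functionals
    (drug remaining in the vitreous, drug amount at the macula,
    time-integrated macular exposure, retinal loss) compare head
    positions, injection positions and angles, and drug diffusion
    coefficients.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports: Matrix, methods, stats, utils, yaml
Suggests: testthat (>= 3.0.0), minpack.lm, jsonlite, optparse, withr, xml2
Config/testthat/edition: 3
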