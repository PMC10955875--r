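Package: eatlab
Title: Simulation, Signal Processing and Image Reconstruction for
    Electroacoustic Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for electroacoustic tomography (EAT), the
    imaging of electrical energy deposition during pulsed-field
    electroporation from the broadband ultrasound it emits. Provides a
    finite-difference quasi-static field solver for electrode pairs in 2-D
    conductive media, conversion of the electric field to Joule energy
    deposition and initial acoustic pressure, a Green's-function forward
    model for ring detector arrays, the standard trace-processing chain
    (band filtering, Coiflet wavelet denoising with the universal threshold,
    Hilbert envelopes, time-of-flight picking, sound-speed regression, frame
    averaging), universal filtered back-projection and delay-and-sum image
    reconstruction, and scripted experiments for device characterization
    (distance and voltage sweeps, voltage-ramp and moving-source videos).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
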