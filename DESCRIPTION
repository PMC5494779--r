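Package: echotonometry
Title: Corneal Acoustic Impedance Estimation from Pulse-Echo Ultrasound
    and Its Correlation with Intraocular Pressure
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates and analyses high-frequency pulse-echo ultrasound
    A-lines from the cornea of a pressurized eye. Provides a synthetic
    A-line generator (Gaussian-enveloped pulse, two-interface echo model),
    envelope-based echo feature extraction with parabolic sub-sample peak
    fitting, forward and inverse layered reflection/transmission models
    that map echo amplitudes to anterior and posterior corneal acoustic
    impedance, and per-pressure aggregation with Pearson correlation and
    linear fits against intraocular pressure. A Laplace-law thin-shell
    stress utility is included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
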