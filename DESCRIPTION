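Package: photonfret
Title: Photon Budgets and Precision Bounds for FRET Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analytical and numerical tools for planning Förster resonance
    energy transfer (FRET) imaging experiments under Poisson photon
    statistics.  Implements the forward model and crosstalk-corrected
    estimators (cFRET, dFRET, aFRET) for three-cube sensitized-emission
    FRET, their photon-normalized precision bounds via error propagation
    and the Fisher information matrix, the Cramér-Rao lower bound for FRET
    estimation from binned time-correlated single-photon counting (TCSPC)
    donor decays with configurable instrument response function and
    background, a photon-budget calculator, Monte-Carlo validation by
    Poisson replicate simulation, a synthetic multi-channel image
    generator, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
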