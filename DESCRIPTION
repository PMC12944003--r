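Package: depotr
Title: Release Kinetics and Point-to-Point IVIVC for Long-Acting Injectable Depots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis of in vitro release (IVR) studies and point-to-point
    in vitro-in vivo correlation (IVIVC) for polymer depot formulations such
    as PLGA in situ gels. Converts raw dissolution-vessel concentrations to
    withdrawal-corrected cumulative release profiles, fits piecewise
    Korsmeyer-Peppas (power-law) release models with mechanism
    classification, computes f1/f2 dissolution similarity factors, performs
    non-compartmental analysis of plasma profiles, estimates biexponential
    unit impulse response functions from intravenous data, deconvolves
    subcutaneous plasma profiles to fraction-absorbed curves, estimates
    phase-specific in vitro to in vivo scaling factors with tie constraints,
    and convolves scaled release models back to predicted plasma profiles
    with internal prediction errors. Includes simulators for dissolution
    vessels with withdrawal/replacement bookkeeping and for small-animal
    pharmacokinetic studies, so every stage is testable without external
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
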