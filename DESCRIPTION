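Package: leupet
Title: Quantification of Cerebral Protein Synthesis Rate from [11C]Leucine PET
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kinetic quantification of cerebral protein synthesis rate (PSR)
    from dynamic [11C]leucine PET in small animals. Implements the
    irreversible two-tissue compartment model with an exact piecewise-linear
    input convolution, weighted nonlinear least-squares estimation of the
    rate constants K1, k2 and k3, the derived quantities lambda, Kcplx and
    PSR, Patlak graphical analysis as an independent cross-check, processing
    of arterial blood data into a plasma free-leucine input function,
    population-based input function construction and image-derived scaling,
    ROI time-activity extraction and SUV computation, descriptive study-level
    summaries, and a fully seeded synthetic-study generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
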