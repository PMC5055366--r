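Package: fecundr
Title: Determinate and Indeterminate Annual Fecundity Estimation for
    Batch-Spawning Fishes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates potential annual fecundity (PAF) of iteroparous,
    batch-spawning fishes by two independent routes and checks the
    assumptions that separate them. The determinate route expands a
    gravimetric subsample count to the whole ovary (PAF = C_S/M_S * M_O)
    and supplies the three validity diagnostics: the oocyte size-gap
    ("gap uncertainty") profile, an ANCOVA test for the decline of the
    yolked standing crop once spawning begins, and terminal atresia
    flags. The indeterminate route simulates PAF = RT/SI * BF from
    fitted probability distributions of residence time, spawning
    interval (from postovulatory-follicle day classes), and batch
    fecundity, with bootstrap replicates. A synthetic oogenesis and
    population generator with known ground truth (group-synchronous or
    asynchronous vitellogenesis) makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    optparse,
    withr
Config/testthat/edition: 3
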