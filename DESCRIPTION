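Package: phagekit
Title: Phage Susceptibility Testing Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for phage susceptibility testing (PST) of
    bacterial clinical isolates. Turns plate-reader growth curves from
    planktonic killing assays (PKA) into normalized area-under-curve
    statistics, lysis calls and times of lysis; computes local and global
    virulence indices from multiplicity-of-infection (MOI) series;
    summarises and compares host-range matrices from plaque assays (DPA)
    and PKA including the six-group concordance classification; interprets
    disc-diffusion antibiograms against EUCAST-style breakpoints and
    assigns 3MRGN/4MRGN multidrug-resistance classes; scores phages with a
    therapeutic-potential rubric; and designs maximum-coverage phage
    cocktails by exhaustive or greedy optimization. A seed-deterministic
    synthetic-data generator (logistic growth with MOI-dependent lysis
    kinetics, block-structured host-range matrices, antibiograms) makes
    every pipeline stage testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
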