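Package: clampeq
Title: Binding Equilibria, Calorimetry and Light-Scattering Models for
    Complexin-SNARE Clamping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative models for the thermodynamics of complexin binding
    to assembling SNARE complexes. Provides closed-form and numerical solvers
    for 1:1 and self-association binding equilibria; simulation and
    non-linear least-squares fitting of isothermal titration calorimetry
    (ITC) thermograms under the one-set-of-sites (Wiseman) model and a
    two-independent-site-classes bivalent model; a semi-quantitative dynamic
    light scattering (DLS) oligomerization model mapping cross-link
    occupancy to mean particle radius; and Forster-theory conversion of
    donor-quenching FRET measurements into inter-probe distances. Seeded
    synthetic-data generators emulate each instrument so every estimator can
    be validated by parameter recovery.
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
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
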