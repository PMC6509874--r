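Package: synergyscreen
Title: Screening Two-Target Drug Combinations in Kinetic Disease Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening synergistic two-target drug combinations in
    kinetic models of disease-related metabolic networks. Networks are
    described by Michaelis-Menten style rate laws (with competitive
    inhibition, activation, irreversible enzyme inactivation and
    transcriptional up-regulation), integrated as ordinary differential
    equations, and scored by the cumulative production of a readout
    metabolite. Single enzyme targets are classified as sensitive or
    insensitive by the relative concentration change needed to restore a
    normal state; sensitive pairs are screened by Loewe combination-index
    isobolograms, insensitive pairs by joint-perturbation feasibility, and
    mixed pairs by alpha-assisted dose reduction. Includes a synthetic
    arachidonic-acid pathway model, fixture generators with known
    dose-effect behaviour, tidy result tables and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    yaml,
    jsonlite,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
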