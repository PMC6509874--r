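#' Load the synthetic arachidonic-acid (AA) network model
#'
#' Loads the package's kinetic model of the arachidonic-acid metabolic
#' pathway in human polymorphonuclear leukocytes (PMNs): membrane
#' phospholipid is hydrolysed by PLA2 to free AA, which is metabolised
#' through the 5-LOX branch (5-HPETE, LTA4, then LTB4 via LTA4H, degraded by
#' CYP4F3), the 15-LOX and 12-LOX branches (hydroperoxides reduced by
#' PHGPx), and the COX-2 branch (PGH2 split to TXA2 by TXAS and PGE2 by
#' PGES). The model carries 24 species (14 metabolites, 10 enzyme pools),
#' the 8 canonical anti-inflammatory drug targets (PLA2, 5-LOX, 15-LOX,
#' 12-LOX, TXAS, LTA4H, CYP4F3, PHGPx), readout LTB4 and a one-hour horizon,
#' and exercises all five rate-law families (including 15-HETE inhibition of
#' 5-LOX, LTB4 feedback activation of PLA2, peroxide-mediated COX-2
#' inactivation and PGE2-driven COX-2 induction).
#'
#' All kinetic constants are *synthetic*: they are order-of-magnitude
#' placeholders chosen for qualitatively realistic pathway behaviour, not
#' literature-fitted values, as recorded per constant in
#' [aa_model_provenance()]. Quantitative screening results on this model are
#' therefore illustrative only.
#'
#' @return A validated [network_model()].
#' @export
load_aa_model <- function() {
  path <- system.file("extdata", "models", "aa_pmn_synthetic.yaml",
                      package = "synergyscreen", mustWork = TRUE)
  read_network_model(path)
}

#' Per-constant provenance of the synthetic AA model
#'
#' @return A tibble with one row per kinetic constant: `reaction`,
#'   `constant`, `value` and `provenance` (all `"synthetic"` in this model).
#' @export
aa_model_provenance <- function() {
  path <- system.file("extdata", "models", "aa_pmn_synthetic_provenance.csv",
                      package = "synergyscreen", mustWork = TRUE)
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
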