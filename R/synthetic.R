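# Fixture networks: small, hand-solvable stoichiometric models used
# throughout the tests, plus the richer toy-core network that stands in
# for a genome-scale model at desk scale.

rxn_row <- function(id, lb = 0, ub = 1000, rule = "", exch = FALSE, name = id) {
  data.frame(id = id, name = name, lower_bound = lb, upper_bound = ub,
             gene_rule = rule, is_exchange = exch, stringsAsFactors = FALSE)
}

met_df <- function(ids, compartment = "c") {
  data.frame(id = ids, name = ids, compartment = compartment, stringsAsFactors = FALSE)
}

#' Three-reaction linear chain fixture
#'
#' Uptake (capacity 10) -> conversion -> export; the export optimum equals
#' the uptake bottleneck. The smallest possible sanity fixture.
#'
#' @return a [flux_model()].
#' @export
build_micro3 <- function() {
  mets <- met_df(c("A", "B"))
  rxns <- rbind(
    rxn_row("EX_A_in", ub = 10, exch = TRUE),
    rxn_row("AtoB"),
    rxn_row("EX_B_out", exch = TRUE))
  flux_model("micro3", mets, rxns,
             stoichiometry = list(EX_A_in = c(A = 1), AtoB = c(A = -1, B = 1),
                                  EX_B_out = c(B = -1)),
             objective = "EX_B_out")
}

#' Parallel-path fixture
#'
#' Two equivalent routes split a fixed uptake of 10; the maximal-export face
#' is the segment x + y = 10, so sampled route fluxes average about 5.
#'
#' @return a [flux_model()].
#' @export
build_parallel_path <- function() {
  mets <- met_df(c("A", "B"))
  rxns <- rbind(
    rxn_row("EX_A_in", ub = 10, exch = TRUE),
    rxn_row("path_x"),
    rxn_row("path_y"),
    rxn_row("EX_B_out", exch = TRUE))
  flux_model("parallel-path", mets, rxns,
             stoichiometry = list(EX_A_in = c(A = 1), path_x = c(A = -1, B = 1),
                                  path_y = c(A = -1, B = 1), EX_B_out = c(B = -1)),
             objective = "EX_B_out")
}

#' Minimal forced-fermentation fixture ("warburg-mini")
#'
#' An 8-metabolite, 10-reaction network whose maximal-growth state is fully
#' determined by hand: glucose uptake capped at 10, oxygen at 2.5, lumped
#' glycolysis (2 ATP + 2 NADH per glucose), respiration (2 ATP per NADH at
#' 0.5 O2), lactate dehydrogenase (isoenzyme pair), an oxidative
#' NADH-producing branch, and a biomass reaction costing 6 ATP per unit.
#' Under the oxygen cap, maximal growth is 5 and at that growth the model
#' must secrete 15 units of lactate; with unlimited oxygen growth rises to
#' 110/7 and the forced secretion vanishes.
#'
#' @return a [flux_model()] with bioenergetic annotations set.
#' @export
build_warburg_mini <- function() {
  mets <- met_df(c("glc", "o2", "lac", "co2", "biomass",
                   "pyr", "atp", "adp", "nad", "nadh"))
  rxns <- rbind(
    rxn_row("EX_glc_in", ub = 10, exch = TRUE),
    rxn_row("EX_o2_in", ub = 2.5, exch = TRUE),
    rxn_row("EX_lac_out", exch = TRUE),
    rxn_row("EX_co2_out", exch = TRUE),
    rxn_row("EX_biomass", exch = TRUE),
    rxn_row("GLY", rule = "gGLY"),
    rxn_row("RESP", rule = "gRESP"),
    rxn_row("LDH", rule = "gLDH1 OR gLDH2"),
    rxn_row("TCA", rule = "gTCA"),
    rxn_row("BIO"))
  flux_model("warburg-mini", mets, rxns,
    stoichiometry = list(
      EX_glc_in = c(glc = 1),
      EX_o2_in = c(o2 = 1),
      EX_lac_out = c(lac = -1),
      EX_co2_out = c(co2 = -1),
      EX_biomass = c(biomass = -1),
      GLY = c(glc = -1, adp = -2, nad = -2, pyr = 2, atp = 2, nadh = 2),
      RESP = c(nadh = -1, o2 = -0.5, adp = -2, nad = 1, atp = 2),
      LDH = c(pyr = -1, nadh = -1, lac = 1, nad = 1),
      TCA = c(pyr = -1, nad = -4, nadh = 4, co2 = 1),
      BIO = c(pyr = -1, atp = -6, biomass = 1, adp = 6)),
    objective = "EX_biomass",
    medium = c(EX_glc_in = 10, EX_o2_in = 2.5),
    annotations = list(
      metric_config = metric_config(
        lactate_export = "EX_lac_out", oxygen_uptake = "EX_o2_in",
        glycolytic_atp = "GLY", oxphos_atp = "RESP"),
      glucose_uptake = "EX_glc_in",
      internal_screen_set = c("GLY", "RESP", "LDH", "TCA"),
      reference = list(max_biomass = 5, min_lactate = 15,
                       max_biomass_o2_free = 110 / 7,
                       ldh_ko_biomass = 55 / 26, afr = 2, ecar = 15,
                       ocr = 2.5, eor = 6)))
}

#' Catalogue of fixture models
#'
#' Named builders plus their documented reference optima (each value is
#' re-derived by an independent vertex-enumeration oracle in the test
#' suite).
#'
#' @return named list: each entry has `build` (function) and `reference`.
#' @export
fixture_catalog <- function() {
  list(
    micro3 = list(build = build_micro3,
                  reference = list(max_export = 10)),
    `parallel-path` = list(build = build_parallel_path,
                           reference = list(max_export = 10, mean_path_flux = 5)),
    `warburg-mini` = list(build = build_warburg_mini,
                          reference = build_warburg_mini()$annotations$reference),
    `toy-core` = list(build = build_toy_core,
                      reference = list(requirements = c("forced lactate at calibrated O2",
                                                        "no forced lactate with free O2",
                                                        "OCR rises under glycolytic inhibition",
                                                        ">= 2 reroutable branch knockouts",
                                                        "isoenzyme rule present"))))
}
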