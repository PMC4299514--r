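# The toy-core network: a desk-scale stand-in for a genome-scale human
# model, built so that the whole Warburg pipeline is exercised end to end.
#
# Bioenergetic architecture (all irreversible, single compartment):
#  * glucose -> glycolysis (HEX/PFK/GAPD/PYK) with a small low-NADH bypass
#    (BYP) and a pentose-like shunt (PPP);
#  * NADH is re-oxidised by capacity-capped respiration (RESP, 2 ATP per
#    NADH), an uncapped non-phosphorylating oxidase (NOX) or lactate
#    dehydrogenase (LDH, isoenzyme pair);
#  * glutamine feeds capped oxidative ATP (GLNOX) and an oxygen-costly
#    anaplerotic pyruvate route (PYROX);
#  * biomass costs pyruvate, serine, methionine and 8 ATP; serine comes
#    from a capacity-capped NADH-producing synthesis branch (SERSYN) or a
#    small medium uptake, methionine from serine (METHSYN) or a small
#    uptake.
#
# At the shipped normoxic oxygen bound, maximal growth is ATP-limited with
# glycolysis saturated, respiration at capacity, and the NADH excess forced
# into lactate: the forced-Warburg state. With unlimited oxygen the NOX
# sink removes the forcing. Inhibiting the glycolytic entry shifts ATP and
# pyruvate supply onto the oxygen-costly glutamine routes, so sampled ECAR
# falls and OCR rises, while serine/methionine-branch knockouts reroute to
# the capped uptakes: lactate is abolished at a moderate growth cost.

toy_core_requirements <- c(
  R1 = "forced lactate secretion at the shipped normoxic oxygen bound",
  R2 = "no forced lactate secretion with unbounded oxygen",
  R3 = "glycolytic-entry inhibition lowers ECAR and raises OCR",
  R4 = "serine-like and methionine-like branch knockouts abolish lactate while sparing > 10% growth",
  R5 = "at least one isoenzyme (OR) gene rule")

#' Build the toy-core fixture network
#'
#' Constructs the 25-reaction core-carbon network described above,
#' calibrates its oxygen bound, applies the normoxic margin, and verifies
#' its structural requirements: (R1) forced lactate at the shipped oxygen
#' bound, (R2) no forcing with unbounded oxygen, (R3) glycolytic inhibition
#' lowers the attainable lactate range and raises the committed oxygen
#' consumption, (R4) the serine- and methionine-branch knockouts abolish
#' forced lactate while retaining more than 10% of maximal growth, and
#' (R5) an isoenzyme OR rule is present. Construction is deterministic;
#' `seed` is recorded in the annotations for provenance of downstream
#' sampling.
#'
#' @param seed recorded seed (the construction itself is deterministic).
#' @param normoxic_fraction shipped oxygen bound as a fraction of the
#'   calibrated zero-forcing threshold (default 0.42; below 1 so the
#'   forced-lactate margin is substantial).
#' @param maintenance_atp optional non-growth ATP drain capacity; 0 (the
#'   default) omits the reaction so the cofactor pools are closed cycles.
#' @param check run the build-time self-checks (LP-based, fast).
#' @return a [flux_model()] with bioenergetic annotations, including
#'   `reroutable_branch` (knockouts that abolish lactate and spare growth)
#'   and `planted_targets` (the knockouts additionally expected to pass the
#'   AFR filter of the screen).
#' @export
build_toy_core <- function(seed = 1L, normoxic_fraction = 0.42,
                           maintenance_atp = 0, check = TRUE) {
  stopifnot(normoxic_fraction > 0, normoxic_fraction < 1)
  mets <- met_df(c("glc", "gln", "o2", "lac", "co2", "ser", "meth",
                   "g6p", "g3p", "pep", "pyr", "atp", "adp", "nad", "nadh", "bm"))
  rxns <- rbind(
    rxn_row("EX_glc_in", ub = 10, exch = TRUE),
    rxn_row("EX_gln_in", ub = 12, exch = TRUE),
    rxn_row("EX_o2_in", ub = 1000, exch = TRUE),
    rxn_row("EX_lac_out", exch = TRUE),
    rxn_row("EX_co2_out", exch = TRUE),
    rxn_row("EX_ser_in", ub = 1.2, exch = TRUE),
    rxn_row("EX_meth_in", ub = 0.4, exch = TRUE),
    rxn_row("EX_biomass", exch = TRUE),
    rxn_row("HEX", ub = 8, rule = "gHK1 OR gHK2"),
    rxn_row("PFK", rule = "gPFK"),
    rxn_row("GAPD", rule = "gGAPDH"),
    rxn_row("BYP", ub = 2, rule = "gBYP"),
    rxn_row("PYK", rule = "gPYK"),
    rxn_row("LDH", rule = "gLDHA OR gLDHB"),
    rxn_row("PDH_TCA", rule = "gTCA"),
    rxn_row("RESP", ub = 8, rule = "gETC"),
    rxn_row("NOX", rule = "gNOX"),
    rxn_row("GLNOX", ub = 1, rule = "gGLS AND gGDH"),
    rxn_row("PYROX", rule = "gGLS AND gME"),
    rxn_row("SERSYN", ub = 2, rule = "gPHGDH"),
    rxn_row("SEROX", rule = "gSDS"),
    rxn_row("METHSYN", rule = "gMAT"),
    rxn_row("PPP", ub = 3, rule = "gG6PD"),
    rxn_row("BIOSYN"))
  st <- list(
    EX_glc_in = c(glc = 1), EX_gln_in = c(gln = 1), EX_o2_in = c(o2 = 1),
    EX_lac_out = c(lac = -1), EX_co2_out = c(co2 = -1),
    EX_ser_in = c(ser = 1), EX_meth_in = c(meth = 1), EX_biomass = c(bm = -1),
    HEX = c(glc = -1, atp = -1, g6p = 1, adp = 1),
    PFK = c(g6p = -1, atp = -1, g3p = 2, adp = 1),
    GAPD = c(g3p = -1, nad = -1, adp = -2, pep = 1, nadh = 1, atp = 2),
    BYP = c(g3p = -1, adp = -1, pep = 1, atp = 1),
    PYK = c(pep = -1, adp = -1, pyr = 1, atp = 1),
    LDH = c(pyr = -1, nadh = -1, lac = 1, nad = 1),
    PDH_TCA = c(pyr = -1, nad = -4, nadh = 4, co2 = 3),
    RESP = c(nadh = -1, o2 = -0.5, adp = -2, nad = 1, atp = 2),
    NOX = c(nadh = -1, o2 = -0.5, nad = 1),
    GLNOX = c(gln = -1, o2 = -3, adp = -9, atp = 9, co2 = 5),
    PYROX = c(gln = -1, o2 = -2, pyr = 1, co2 = 2),
    SERSYN = c(g3p = -1, nad = -1, ser = 1, nadh = 1),
    SEROX = c(ser = -1, nad = -1, pyr = 1, nadh = 1),
    METHSYN = c(ser = -1, atp = -1, meth = 1, adp = 1),
    PPP = c(g6p = -1, nad = -2, g3p = 1, co2 = 1, nadh = 2),
    BIOSYN = c(pyr = -1, ser = -0.3, meth = -0.1, atp = -8, bm = 1, adp = 8))
  if (maintenance_atp > 0) {
    rxns <- rbind(rxns, rxn_row("ATPM", ub = maintenance_atp))
    st$ATPM <- c(atp = -1, adp = 1)
  }
  cfg <- metric_config("EX_lac_out", "EX_o2_in",
                       glycolytic_atp = c("GAPD", "BYP", "PYK"),
                       oxphos_atp = c("RESP", "GLNOX"))
  gene_classes <- list(
    glycolytic = c("gHK1", "gHK2", "gPFK", "gGAPDH", "gPYK", "gLDHA", "gLDHB"),
    respiratory = c("gETC", "gNOX", "gTCA", "gGLS", "gGDH", "gME"),
    branch = c("gPHGDH", "gMAT", "gSDS", "gG6PD", "gBYP"))
  model <- flux_model("toy-core", mets, rxns, st, objective = "EX_biomass",
    medium = c(EX_glc_in = 10, EX_gln_in = 12, EX_ser_in = 1.2, EX_meth_in = 0.4),
    annotations = list(
      metric_config = cfg,
      glycolytic_entry = "HEX",
      gene_classes = gene_classes,
      tailoring_targets = c("HEX", "PFK", "GAPD", "PYK", "LDH", "RESP", "NOX",
                            "PDH_TCA", "GLNOX", "PYROX", "SERSYN", "SEROX",
                            "METHSYN", "PPP"),
      reroutable_branch = c("HEX", "PFK", "GAPD", "PYK", "LDH", "SERSYN", "METHSYN"),
      planted_targets = c("HEX", "PFK", "GAPD", "PYK", "LDH"),
      seed = seed))

  cal <- calibrate_oxygen(model, config = cfg)
  model <- set_bounds(model, "EX_o2_in", upper = cal$bound * normoxic_fraction)
  model$annotations$oxygen_threshold <- cal$bound
  model$annotations$normoxic_fraction <- normoxic_fraction
  if (check) toy_core_self_check(model)
  model
}

# Build-time verification of the structural requirements (LP-based only;
# the sampling-level properties are exercised in the test suite).
toy_core_self_check <- function(model) {
  fail <- function(req) stop("toy-core self-check failed: ", req, " (",
                             toy_core_requirements[[req]], ")", call. = FALSE)
  cfg <- model$annotations$metric_config
  fl <- forced_lactate(model)
  if (!(fl$min_lactate > 1e-3)) fail("R1")
  free <- forced_lactate(set_bounds(model, cfg$oxygen_uptake, upper = 1e5))
  if (free$min_lactate > 1e-6) fail("R2")
  # R3 proxy: committed oxygen rises and the attainable lactate range falls
  # under full glycolytic inhibition (sampled means are checked in tests)
  face_stats <- function(m) {
    s <- solve_fba(m)
    fx <- stats::setNames(list(c(s$objective_value, 1e-9)), m$objective)
    fv <- flux_variability(m, c(cfg$oxygen_uptake, cfg$lactate_export), fixed = fx)
    list(biomass = s$objective_value, o2 = fv[1, ], lac = fv[2, ])
  }
  wt <- face_stats(model)
  inhib <- face_stats(set_bounds(model, model$annotations$glycolytic_entry, upper = 0))
  if (!(inhib$o2$min > wt$o2$min && inhib$biomass > 0.1 * wt$biomass)) fail("R3")
  if (!(inhib$lac$max < wt$lac$max)) fail("R3")
  # R4: branch knockouts abolish forced lactate, sparing > 10% growth
  for (ko in c("SERSYN", "METHSYN")) {
    km <- knockout_reaction(model, ko)
    s <- solve_fba(km)
    if (s$status != "optimal" || s$objective_value <= 0.1 * wt$biomass) fail("R4")
    lac <- flux_extremum(km, cfg$lactate_export, "min",
                         fixed = stats::setNames(list(c(s$objective_value, 1e-9)),
                                                 km$objective))
    if (lac > 1e-6) fail("R4")
  }
  has_or <- any(vapply(model$reactions$gene_rule, function(r) {
    a <- parse_gene_rule(r); !is.null(a) && !is.null(a$op) && a$op == "or"
  }, logical(1)))
  if (!has_or) fail("R5")
  invisible(model)
}
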