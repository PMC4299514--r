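# The three-filter knockout screen.

test_that("the warburg-mini worked example yields exactly the LDH target", {
  m <- build_warburg_mini()
  scr <- run_screen(m, reactions = c("GLY", "RESP", "LDH", "TCA"),
                    n_samples = 200, seed = 1)
  # stage 1: TCA knockout leaves lactate at 15, the others abolish it
  expect_setequal(scr$stage1, c("GLY", "RESP", "LDH"))
  tca <- scr$records[scr$records$reaction == "TCA", ]
  expect_equal(tca$ko_min_lactate, 15, tolerance = 1e-6)
  # stage 2: GLY and RESP knockouts kill growth
  expect_setequal(scr$stage2, "LDH")
  expect_equal(scr$records$ko_growth[scr$records$reaction == "GLY"], 0)
  expect_equal(scr$records$ko_growth[scr$records$reaction == "RESP"], 0)
  # stage 3: the LDH knockout reduces the AFR to ~13.5% of wild type
  expect_identical(scr$survivors, "LDH")
  ldh <- scr$records[scr$records$reaction == "LDH", ]
  expect_equal(ldh$growth_fraction, 55 / 130, tolerance = 1e-6)
  expect_equal(scr$summary$mean_afr_fraction[scr$summary$reaction == "LDH"],
               7 / 52, tolerance = 1e-4)
  # verdict booleans consistent with the stored numbers
  s <- scr$summary
  expect_true(all(s$survives == (s$lactate_abolished & s$growth_spared & s$afr_reduced)))
})

test_that("filter stages nest and thresholds act strictly", {
  m <- build_warburg_mini()
  scr <- run_screen(m, reactions = c("GLY", "RESP", "LDH", "TCA"),
                    n_samples = 100, seed = 1)
  expect_true(all(scr$survivors %in% scr$stage2))
  expect_true(all(scr$stage2 %in% scr$stage1))
  # growth threshold 1.0: no knockout strictly exceeds wild-type growth
  scr2 <- run_screen(m, config = screen_config(growth_fraction_threshold = 1.0),
                     reactions = c("GLY", "RESP", "LDH", "TCA"),
                     n_samples = 50, seed = 1)
  expect_length(scr2$survivors, 0)
  # the objective reaction is never tested
  scr3 <- run_screen(m, reactions = c("LDH", "EX_biomass"),
                     n_samples = 50, seed = 1)
  expect_false("EX_biomass" %in% scr3$summary$reaction)
})

test_that("wild types must grow and ferment before screening", {
  free <- set_bounds(build_warburg_mini(), "EX_o2_in", upper = Inf)
  expect_error(run_screen(free, reactions = "LDH"), "no forced lactate")
})

test_that("a normal cohort adds a growth-sparing filter", {
  m <- build_warburg_mini()
  # a 'normal' model whose growth depends entirely on LDH flux
  normal <- knockout_reaction(m, "TCA")
  normal <- set_bounds(normal, "RESP", upper = 0.1)
  cfg <- screen_config(normal_cohort = list(normal))
  scr <- run_screen(m, config = cfg, reactions = c("GLY", "RESP", "LDH", "TCA"),
                    n_samples = 100, seed = 1)
  # LDH knockout starves the LDH-dependent normal model -> filtered out
  expect_length(scr$survivors, 0)
  expect_false(scr$summary$normal_spared[scr$summary$reaction == "LDH"])
})

test_that("survivor genes are mapped with knockdown sufficiency", {
  m <- build_warburg_mini()
  tab <- map_targets_to_genes(m, c("LDH", "GLY"))
  expect_setequal(tab$gene, c("gLDH1", "gLDH2", "gGLY"))
  # isoenzymes: knocking one LDH gene cannot close the reaction
  expect_false(tab$knockdown_sufficient[tab$gene == "gLDH1"])
  expect_false(tab$knockdown_sufficient[tab$gene == "gLDH2"])
  expect_true(tab$knockdown_sufficient[tab$gene == "gGLY"])

  tc <- build_toy_core(check = FALSE)
  tab2 <- map_targets_to_genes(tc, c("GLNOX", "PYROX"))
  # gGLS sits in both AND complexes: listed once with two reactions
  expect_equal(sum(tab2$gene == "gGLS"), 1)
  expect_equal(tab2$n_reactions[tab2$gene == "gGLS"], 2)
  expect_true(tab2$knockdown_sufficient[tab2$gene == "gGLS"])
  expect_warning(map_targets_to_genes(m, "BIO"), "no gene rule")
})

test_that("target expression test is one-sided with calibrated type I error", {
  set.seed(7)
  expr <- matrix(rnorm(12 * 10), 12, 10,
                 dimnames = list(paste0("g", 1:12), paste0("L", 1:10)))
  targets <- paste0("g", 1:5); background <- paste0("g", 6:12)
  expr[targets, ] <- expr[targets, ] + 3
  expect_lt(target_expression_test(expr, targets, background), 0.05)
  # direction: targets below background gives p near 1
  expr2 <- expr; expr2[targets, ] <- expr2[targets, ] - 6
  expect_gt(target_expression_test(expr2, targets, background), 0.95)
  expect_error(target_expression_test(expr, targets, c("g1", "g6")), "overlap")
  expect_error(target_expression_test(expr, character(0), background), "non-empty")
  # null calibration by label shuffling
  n_sim <- 200; hits <- 0
  for (i in seq_len(n_sim)) {
    e <- matrix(rnorm(12 * 6), 12, 6, dimnames = list(paste0("g", 1:12), NULL))
    if (target_expression_test(e, targets, background) <= 0.05) hits <- hits + 1
  }
  expect_lt(hits / n_sim, 0.05 + 3 * sqrt(0.05 * 0.95 / n_sim))
})
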