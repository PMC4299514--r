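# The toy-core fixture and the synthetic cohort generator.

test_that("toy-core passes its structural self-checks and fixture catalogue", {
  tc <- build_toy_core()                 # check = TRUE runs R1-R5
  expect_s3_class(tc, "flux_model")
  expect_gte(nrow(tc$reactions), 24)
  cat_names <- names(fixture_catalog())
  expect_setequal(cat_names, c("micro3", "parallel-path", "warburg-mini", "toy-core"))

  fl <- forced_lactate(tc)
  expect_gt(fl$min_lactate, 1)           # R1: forced at the shipped bound
  free <- forced_lactate(set_bounds(tc, "EX_o2_in", upper = 1e5))
  expect_equal(free$min_lactate, 0, tolerance = 1e-6)   # R2

  # R4: branch knockouts abolish lactate and spare growth
  for (ko in c("SERSYN", "METHSYN")) {
    km <- knockout_reaction(tc, ko)
    g <- solve_fba(km)$objective_value
    expect_gt(g / fl$max_biomass, 0.1)
    expect_lt(g / fl$max_biomass, 0.97)
    expect_equal(flux_extremum(km, "EX_lac_out", "min",
                               fixed = list(EX_biomass = c(g, 1e-9))), 0,
                 tolerance = 1e-6)
  }
})

test_that("glycolytic-entry inhibition lowers ECAR and raises OCR", {
  tc <- build_toy_core(check = FALSE)
  dr <- dose_response(tc, "HEX", n_levels = 9, n_samples = 300, seed = 5)
  tol_e <- 0.03 * diff(range(dr$ecar))
  tol_o <- 0.10 * diff(range(dr$ocr))
  expect_true(all(diff(dr$ecar) <= tol_e))
  expect_true(all(diff(dr$ocr) >= -tol_o))
  expect_gt(dr$ocr[9], dr$ocr[1] + 0.5)
  expect_gt(dr$ecar[1], dr$ecar[9] + 1)
})

test_that("the screen's survivors match the planted target structure", {
  tc <- build_toy_core(check = FALSE)
  internal <- tc$reactions$id[!tc$reactions$is_exchange &
                                nzchar(tc$reactions$gene_rule)]
  scr <- run_screen(tc, reactions = internal, n_samples = 300, seed = 2)
  expect_setequal(scr$survivors, tc$annotations$planted_targets)
  expect_true(all(tc$annotations$reroutable_branch %in% scr$stage2))
  expect_true(all(scr$survivors %in% tc$annotations$reroutable_branch))
  # every survivor record satisfies the stored thresholds in every line
  rec <- scr$records[scr$records$reaction %in% scr$survivors, ]
  expect_true(all(rec$ko_min_lactate <= 1e-6))
  expect_true(all(rec$growth_fraction > 0.1))
})

test_that("cohort generation is seeded and plants the documented structure", {
  tc <- build_toy_core(check = FALSE)
  a <- generate_cohort(tc, n_lines = 8, seed = 3)
  b <- generate_cohort(tc, n_lines = 8, seed = 3)
  expect_identical(a$expression, b$expression)
  expect_identical(a$responses, b$responses)
  expect_false(identical(a$expression,
                         generate_cohort(tc, n_lines = 8, seed = 4)$expression))
  expect_true(all(a$expression >= 0))
  expect_equal(length(a$planted_compounds), 30)

  # planted relations hold in expectation: growth down, migration up with w
  big <- generate_cohort(tc, n_lines = 40, seed = 6)
  expect_gt(cor(big$w, big$phenotypes$migration, method = "spearman"), 0.5)
  expect_lt(cor(big$w, big$phenotypes$growth, method = "spearman"), -0.5)
  # glycolytic expression rises with w, respiratory falls
  expect_gt(cor(big$w, big$expression["gGAPDH", ], method = "spearman"), 0.5)
  expect_lt(cor(big$w, big$expression["gETC", ], method = "spearman"), -0.5)

  nor <- generate_cohort(tc, n_lines = 8, seed = 3, mode = "normal")
  expect_true(all(nor$w >= 0.25 & nor$w <= 0.75))
  expect_error(generate_cohort(tc, n_lines = 3), "at least 4")
  expect_error(generate_cohort(tc, n_lines = 8, drug_noise = -1), "invalid")
})

test_that("zero-noise equally spaced cohorts give AFR strictly increasing in w", {
  tc <- build_toy_core(check = FALSE)
  co <- generate_cohort(tc, n_lines = 6, seed = 1, expr_noise = 0,
                        growth_noise = 0, migration_noise = 0)
  # overwrite w deterministically: equally spaced via expression regeneration
  res <- cohort_warburg(tc, co$expression, n_samples = 300, seed = 9)
  ord <- order(co$w)
  expect_true(all(diff(res$afr[ord]) > 0))
})

test_that("a tailored cohort's screen survivors stay within the planted set", {
  tc <- build_toy_core(check = FALSE)
  co <- generate_cohort(tc, n_lines = 5, seed = 5)
  cw <- cohort_warburg(tc, co$expression, n_samples = 100, seed = 5,
                       oxygen = "per_line")
  expect_true(all(cw$forced))
  models <- attr(cw, "models")
  internal <- tc$reactions$id[!tc$reactions$is_exchange &
                                nzchar(tc$reactions$gene_rule)]
  scr <- run_screen(models, reactions = internal, n_samples = 150, seed = 5)
  expect_gt(length(scr$survivors), 0)
  expect_true(all(scr$survivors %in% tc$annotations$planted_targets))
  expect_true(all(scr$stage2 %in% tc$annotations$reroutable_branch))
})
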