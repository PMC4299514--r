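# Oxygen calibration, forced lactate, hypoxia, dose-response and metrics.

test_that("forced lactate reproduces the hand-solved fixture states", {
  m <- build_warburg_mini()
  fl <- forced_lactate(m)
  expect_equal(fl$max_biomass, 5, tolerance = 1e-8)
  expect_equal(fl$min_lactate, 15, tolerance = 1e-6)
  expect_true(fl$forced)

  free <- forced_lactate(set_bounds(m, "EX_o2_in", upper = Inf))
  expect_equal(free$max_biomass, 110 / 7, tolerance = 1e-8)
  expect_equal(free$min_lactate, 0, tolerance = 1e-6)
  expect_false(free$forced)

  ko <- forced_lactate(knockout_reaction(m, "LDH"))
  expect_equal(ko$max_biomass, 55 / 26, tolerance = 1e-8)
  expect_equal(ko$min_lactate, 0, tolerance = 1e-6)
})

test_that("oxygen calibration finds the forcing threshold", {
  m <- set_bounds(build_warburg_mini(), "EX_o2_in", upper = Inf)
  cal <- calibrate_oxygen(m, resolution = 1e-4)
  # hand-derived zero-forcing threshold: lactate (260 - 14c)/15 hits 0 at 130/7
  expect_equal(cal$bound, 130 / 7, tolerance = 2e-3)
  expect_gt(cal$min_lactate, 0)
  expect_false(cal$saturated)
  # the returned bound is applied to the model copy
  i <- match("EX_o2_in", cal$model$reactions$id)
  expect_equal(cal$model$reactions$upper_bound[i], cal$bound)
  # a model already below the threshold still calibrates to a forcing bound
  low <- set_bounds(build_warburg_mini(), "EX_o2_in", upper = 1)
  cal2 <- calibrate_oxygen(low)
  fl2 <- forced_lactate(cal2$model)
  expect_gt(fl2$min_lactate, 0)
  # a model that cannot ferment at any oxygen bound: never forced
  dead <- knockout_reaction(build_warburg_mini(), "GLY")
  expect_error(calibrate_oxygen(dead), "never forced")
})

test_that("hypoxia halves the oxygen bound and nothing else", {
  m <- build_warburg_mini()
  h <- apply_hypoxia(m, 0.5)
  i <- match("EX_o2_in", h$reactions$id)
  expect_equal(h$reactions$upper_bound[i], 1.25)
  other <- setdiff(seq_len(nrow(m$reactions)), i)
  expect_identical(h$reactions[other, ], m$reactions[other, ])
  fl <- forced_lactate(h)
  expect_equal(fl$max_biomass, 2.5, tolerance = 1e-8)
  expect_equal(fl$min_lactate, 7.5, tolerance = 1e-6)
  expect_equal(oracle_optimum(h), 2.5, tolerance = 1e-8)

  expect_identical(apply_hypoxia(m, 1.0), m)
  expect_error(apply_hypoxia(m, 0), "fraction")
  expect_error(apply_hypoxia(m, 1.5), "fraction")
  expect_error(apply_hypoxia(set_bounds(m, "EX_o2_in", upper = Inf)), "finite")
})

test_that("metrics on the degenerate warburg-mini face are exact", {
  m <- build_warburg_mini()
  fs <- sample_optimal_face(m, n = 100, seed = 1)
  met <- compute_metrics(fs, m)
  expect_equal(met$ecar, 15, tolerance = 1e-6)
  expect_equal(met$ocr, 2.5, tolerance = 1e-6)
  expect_equal(met$eor, 6, tolerance = 1e-6)
  expect_equal(met$glycolytic_atp_flux, 20, tolerance = 1e-6)
  expect_equal(met$oxphos_atp_flux, 10, tolerance = 1e-6)
  expect_equal(met$afr, 2, tolerance = 1e-6)
  expect_length(met$flags, 0)

  # LDH knockout: AFR = (2 * 35/26) / 10 = 7/26, i.e. ~13.5% of wild type
  ko <- knockout_reaction(m, "LDH")
  fsk <- sample_optimal_face(ko, n = 100, seed = 1)
  mk <- compute_metrics(fsk, ko)
  expect_equal(mk$afr, 7 / 26, tolerance = 1e-6)
  expect_equal(mk$afr / met$afr, 7 / 52, tolerance = 1e-6)

  # glycolysis shut in toy-core: glycolytic ATP (hence AFR) goes to zero
  tc <- build_toy_core(check = FALSE)
  hx <- knockout_reaction(tc, "HEX")
  fsx <- sample_optimal_face(hx, n = 100, seed = 1)
  mx <- compute_metrics(fsx, hx)
  expect_equal(mx$afr, 0, tolerance = 1e-6)

  # undefined ratios are flagged, never silently zero
  gly <- knockout_reaction(m, "GLY")    # zero growth, all fluxes zero
  fsg <- sample_optimal_face(gly, n = 50, seed = 1)
  mg <- compute_metrics(fsg, gly)
  expect_true(all(c("eor_undefined", "afr_undefined") %in% mg$flags))
  expect_true(is.na(mg$afr))
})

test_that("dose-response reproduces wild type at level zero and dies at full inhibition", {
  m <- build_warburg_mini()
  dr <- dose_response(m, "EX_glc_in", n_levels = 5, n_samples = 100, seed = 2)
  expect_equal(dr$ecar[1], 15, tolerance = 1e-6)
  expect_equal(dr$ocr[1], 2.5, tolerance = 1e-6)
  expect_equal(dr$biomass[1], 5, tolerance = 1e-8)
  expect_equal(dr$ecar[5], 0, tolerance = 1e-6)   # no carbon, no lactate
  expect_true(all(diff(dr$ecar) <= 1e-9))
  # a reaction carrying no flux at the optimum flags a flat curve
  dr2 <- dose_response(m, "TCA", n_levels = 3, n_samples = 50, seed = 2)
  expect_true(attr(dr2, "flat"))
})

test_that("BEC index is the GAPDH / ATP-synthase-beta expression ratio", {
  expr <- matrix(c(6, 3, 4, 4, 5, 0), nrow = 2,
                 dimnames = list(c("GAPDH", "ATP5B"), c("L1", "L2", "L3")))
  bec <- suppressWarnings(bec_index(expr, "GAPDH", "ATP5B"))
  expect_equal(unname(bec["L1"]), 2)
  expect_equal(unname(bec["L2"]), 1)
  expect_true(is.na(bec["L3"]))
  expect_warning(bec_index(expr, "GAPDH", "ATP5B"), "undefined")
  expect_error(bec_index(expr, "NOPE", "ATP5B"), "not in expression")

  # on a synthetic cohort, BEC rank-correlates with the glycolytic character
  co <- generate_cohort(build_toy_core(check = FALSE), n_lines = 15, seed = 21)
  bec2 <- bec_index(co$expression, "gGAPDH", "gETC")
  r <- spearman_exact(bec2, co$w, "greater", seed = 1)
  expect_gt(r$rho, 0)
  expect_lt(r$p, 0.05)
})
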