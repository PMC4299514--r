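# Flux-balance solving against the independent vertex-enumeration oracle.

test_that("linear chains solve to their bottleneck", {
  m <- build_micro3()
  sol <- solve_fba(m)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 10)
  expect_equal(sol$objective_value, oracle_optimum(m))
  broken <- knockout_reaction(m, "AtoB")
  expect_equal(solve_fba(broken)$objective_value, 0)
})

test_that("warburg-mini optima match the vertex-enumeration oracle", {
  m <- build_warburg_mini()
  opt <- solve_fba(m)$objective_value
  expect_equal(opt, 5, tolerance = 1e-8)
  expect_equal(opt, oracle_optimum(m), tolerance = 1e-8)

  lac <- flux_extremum(m, "EX_lac_out", "min", fixed = list(EX_biomass = c(opt)))
  expect_equal(lac, 15, tolerance = 1e-6)
  expect_equal(lac, oracle_optimum(m, "EX_lac_out", "min",
                                   fixed = list(EX_biomass = c(5))),
               tolerance = 1e-6)

  free <- set_bounds(m, "EX_o2_in", upper = Inf)
  optf <- solve_fba(free)$objective_value
  expect_equal(optf, 110 / 7, tolerance = 1e-8)
  expect_equal(optf, oracle_optimum(free), tolerance = 1e-6)
  expect_equal(flux_extremum(free, "EX_lac_out", "min",
                             fixed = list(EX_biomass = c(optf))), 0,
               tolerance = 1e-6)

  ldh <- knockout_reaction(m, "LDH")
  expect_equal(solve_fba(ldh)$objective_value, 55 / 26, tolerance = 1e-8)
  expect_equal(oracle_optimum(ldh), 55 / 26, tolerance = 1e-8)

  expect_equal(solve_fba(knockout_reaction(m, "GLY"))$objective_value, 0)
})

test_that("optimal solutions satisfy mass balance and bounds", {
  for (m in list(build_micro3(), build_parallel_path(), build_warburg_mini(),
                 build_toy_core(check = FALSE))) {
    sol <- solve_fba(m)
    res <- constraint_residuals(m, sol$fluxes)
    expect_lt(res$mass_balance, 1e-6)
    expect_lt(res$bounds, 1e-9)
  }
})

test_that("flux extrema are ordered and knockouts never help the objective", {
  m <- build_warburg_mini()
  opt <- solve_fba(m)$objective_value
  fx <- list(EX_biomass = c(opt))
  for (r in c("EX_lac_out", "EX_o2_in", "TCA", "RESP")) {
    lo <- flux_extremum(m, r, "min", fixed = fx)
    hi <- flux_extremum(m, r, "max", fixed = fx)
    expect_lte(lo, hi + 1e-9)
  }
  for (r in setdiff(m$reactions$id, m$objective)) {
    ko <- solve_fba(knockout_reaction(m, r))
    val <- if (ko$status == "optimal") ko$objective_value else 0
    expect_lte(val, opt + 1e-8)
  }
  # knockout of a reaction already bounded to zero: minimum flux is zero
  z <- set_bounds(m, "TCA", lower = 0, upper = 0)
  expect_equal(flux_extremum(z, "TCA", "min"), 0)
})

test_that("infeasible fixings raise errors naming the constraint", {
  m <- build_warburg_mini()
  expect_error(flux_extremum(m, "EX_lac_out", "min",
                             fixed = list(EX_biomass = c(50))),
               "EX_biomass")
  infeasible <- set_bounds(m, "EX_glc_in", lower = 20, upper = 30)
  expect_equal(solve_fba(infeasible)$status, "infeasible")
})

test_that("degenerate and randomly rewired small models agree with the oracle", {
  # parallel-path (degenerate optimum) and random bound perturbations
  p <- build_parallel_path()
  expect_equal(solve_fba(p)$objective_value, oracle_optimum(p))
  set.seed(42)
  m <- build_warburg_mini()
  for (i in 1:10) {
    m2 <- m
    js <- sample(nrow(m2$reactions), 3)
    m2$reactions$upper_bound[js] <- round(runif(3, 0.5, 20), 2)
    got <- solve_fba(m2)
    want <- oracle_optimum(m2)
    if (got$status == "optimal") {
      expect_equal(got$objective_value, want, tolerance = 1e-6,
                   info = paste("case", i))
    } else {
      expect_true(is.na(want) || abs(want) < 1e-6)
    }
  }
})
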