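# Expression-to-bound tailoring.

two_line_model <- function() {
  mets <- data.frame(id = c("A", "B"), name = c("A", "B"), compartment = "c")
  rx <- data.frame(id = c("up", "convA", "convB", "out"),
                   lower_bound = 0, upper_bound = c(10, 1000, 1000, 1000),
                   gene_rule = c("", "gA", "gB1 OR gB2", ""),
                   is_exchange = c(TRUE, FALSE, FALSE, TRUE),
                   stringsAsFactors = FALSE)
  st <- list(up = c(A = 1), convA = c(A = -1, B = 1),
             convB = c(A = -1, B = 1), out = c(B = -1))
  flux_model("two-line", mets, rx, st, "out")
}

test_that("reaction expression aggregates over gene rules per line", {
  m <- two_line_model()
  expr <- matrix(c(3, 5, 2,
                   7, 1, 1), nrow = 3,
                 dimnames = list(c("gA", "gB1", "gB2"), c("L1", "L2")))
  re <- reaction_expression(m, expr, "L1")
  expect_equal(unname(re["convA"]), 3)
  expect_equal(unname(re["convB"]), 5 + 2)   # isoenzymes sum
  expect_false("up" %in% names(re))          # no rule: absent
  expect_error(reaction_expression(m, expr, "LX"), "unknown cell line")
})

test_that("min-max tailoring maps expression onto [eps, 1] of the base bound", {
  m <- two_line_model()
  expr <- matrix(c(10, 30, 20, 30), nrow = 2,
                 dimnames = list(c("gA", "gB1"), c("L1", "L2")))
  cohort <- tailor_cohort(m, expr, tailoring_config(c("convA", "convB"), 0.1, 100))
  b1 <- cohort[[1]]$bounds; b2 <- cohort[[2]]$bounds
  # convA: levels 10 vs 20 -> x = 0 and 1 -> bounds 10 and 100
  expect_equal(b1$bound[b1$reaction == "convA"], 10)
  expect_equal(b2$bound[b2$reaction == "convA"], 100)
  # convB: zero cross-line variance -> no penalty for anyone
  expect_equal(b1$bound[b1$reaction == "convB"], 100)
  expect_equal(b2$bound[b2$reaction == "convB"], 100)
  # untargeted reactions identical to the generic model
  i <- match("up", cohort[[1]]$model$reactions$id)
  expect_equal(cohort[[1]]$model$reactions$upper_bound[i], 10)
})

test_that("tailoring is deterministic, bounded by base, and rank-preserving", {
  tc <- build_toy_core(check = FALSE)
  co <- generate_cohort(tc, n_lines = 6, seed = 9)
  cfg <- tailoring_config(tc$annotations$tailoring_targets, 0.1, 12)
  a <- tailor_cohort(tc, co$expression, cfg)
  b <- tailor_cohort(tc, co$expression, cfg)
  expect_identical(lapply(a, `[[`, "bounds"), lapply(b, `[[`, "bounds"))

  bounds <- sapply(a, function(cl) cl$bounds$bound)
  rownames(bounds) <- a[[1]]$bounds$reaction
  expect_true(all(bounds <= 12 + 1e-12))
  expect_true(all(bounds >= 0.1 * 12 - 1e-12))
  # per-reaction bound ranks equal aggregated-expression ranks
  for (r in rownames(bounds)) {
    agg <- sapply(colnames(co$expression), function(l)
      reaction_expression(tc, co$expression, l)[r])
    expect_equal(rank(bounds[r, ]), rank(agg), ignore_attr = TRUE)
  }
  # tailored maximum growth never exceeds the base-bounded generic model
  base_generic <- set_bounds(tc, rownames(bounds), upper = 12)
  base_opt <- solve_fba(base_generic)$objective_value
  for (cl in a)
    expect_lte(solve_fba(cl$model)$objective_value, base_opt + 1e-8)
})

test_that("tailoring requires a cohort and gene rules on targets", {
  m <- two_line_model()
  expr1 <- matrix(5, 1, 1, dimnames = list("gA", "L1"))
  expect_error(tailor_cohort(m, expr1), "at least 2")
  expr <- matrix(c(1, 2), 1, 2, dimnames = list("gA", c("L1", "L2")))
  expect_error(tailor_cohort(m, expr, tailoring_config("up")), "gene rule")
})
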