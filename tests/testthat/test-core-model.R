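# Model container invariants and knockout semantics.

test_that("model validation enforces the structural invariants", {
  mets <- data.frame(id = c("A", "B"), name = c("A", "B"), compartment = "c")
  rx <- data.frame(id = c("up", "conv", "out"),
                   lower_bound = 0, upper_bound = c(10, 1000, 1000),
                   gene_rule = "", is_exchange = c(TRUE, FALSE, TRUE),
                   stringsAsFactors = FALSE)
  st <- list(up = c(A = 1), conv = c(A = -1, B = 1), out = c(B = -1))

  expect_s3_class(flux_model("ok", mets, rx, st, "out"), "flux_model")
  expect_error(flux_model("m", mets, rx, st, "nope"), "objective")

  bad <- rx; bad$lower_bound[2] <- 2000
  expect_error(flux_model("m", mets, bad, st, "out"), "lower_bound")

  st_bad <- st; st_bad$up <- c(A = 1, B = 1)   # exchange touching two species
  expect_error(flux_model("m", mets, rx, st_bad, "out"), "exactly one")

  st_missing <- st; st_missing$conv <- NULL
  expect_error(flux_model("m", mets, rx, st_missing, "out"), "empty stoichiometry")

  expect_error(flux_model("m", mets, rx, c(st, list(ghost = c(A = 1))), "out"),
               "unknown reaction")
})

test_that("medium application only tightens exchange bounds", {
  m <- build_warburg_mini()
  i <- match("EX_glc_in", m$reactions$id)
  expect_equal(m$reactions$upper_bound[i], 10)
  m2 <- apply_medium(m, c(EX_glc_in = 4))
  expect_equal(m2$reactions$upper_bound[match("EX_glc_in", m2$reactions$id)], 4)
  m3 <- apply_medium(m, c(EX_glc_in = 50))   # looser cap leaves bound alone
  expect_equal(m3$reactions$upper_bound[match("EX_glc_in", m3$reactions$id)], 10)
  expect_error(apply_medium(m, c(GLY = 1)), "non-exchange")
})

test_that("reaction knockouts zero bounds on a copy and are idempotent", {
  m <- build_warburg_mini()
  k <- knockout_reaction(m, "LDH")
  i <- match("LDH", k$reactions$id)
  expect_equal(k$reactions$lower_bound[i], 0)
  expect_equal(k$reactions$upper_bound[i], 0)
  # original untouched
  expect_equal(m$reactions$upper_bound[match("LDH", m$reactions$id)], 1000)
  expect_identical(knockout_reaction(k, "LDH"), k)
  expect_error(knockout_reaction(m, "NOPE"), "unknown reaction")
})

test_that("gene knockouts respect isoenzyme and complex semantics", {
  m <- build_warburg_mini()
  # one isoenzyme down: LDH stays open
  k1 <- knockout_gene(m, "gLDH1")
  expect_equal(k1$reactions$upper_bound[match("LDH", k1$reactions$id)], 1000)
  # both isoenzymes down: LDH closed
  k2 <- knockout_gene(m, c("gLDH1", "gLDH2"))
  expect_equal(k2$reactions$upper_bound[match("LDH", k2$reactions$id)], 0)
  # complexes break with any member (toy-core GLNOX is gGLS AND gGDH)
  tc <- build_toy_core(check = FALSE)
  k3 <- knockout_gene(tc, "gGDH")
  expect_equal(k3$reactions$upper_bound[match("GLNOX", k3$reactions$id)], 0)
  expect_gt(k3$reactions$upper_bound[match("PYROX", k3$reactions$id)], 0)
  expect_warning(knockout_gene(m, "gUNKNOWN"), "ignored")
})
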