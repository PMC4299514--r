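# Permutation rank statistics.

test_that("exact permutation p-values match brute-force enumeration", {
  r <- spearman_exact(1:3, 1:3, "greater")
  expect_equal(r$rho, 1)
  expect_equal(r$p, 1 / 6)
  expect_equal(r$method, "exact")
  expect_equal(spearman_exact(1:3, 3:1)$rho, -1)

  set.seed(5)
  for (i in 1:4) {
    x <- rnorm(7); y <- rnorm(7)
    for (s in c("two", "greater", "less")) {
      got <- spearman_exact(x, y, s)
      expect_equal(got$p, brute_spearman_p(x, y, s), tolerance = 1e-12,
                   info = paste("case", i, s))
      expect_equal(got$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
    }
  }
  # ties handled with mid-ranks
  x <- c(1, 2, 2, 4, 5); y <- c(2, 2, 3, 5, 5)
  expect_equal(spearman_exact(x, y)$rho, cor(x, y, method = "spearman"))

  expect_equal(spearman_exact(rep(1, 5), 1:5)$method, "undefined")
  expect_error(spearman_exact(1:2, 1:2), "n >= 3")
})

test_that("the Monte-Carlo path is seeded and consistent with exact", {
  set.seed(2)
  x <- rnorm(9); y <- x + rnorm(9)
  a <- spearman_exact(x, y, "greater", n_exact = 5, n_perm = 2e4, seed = 7)
  b <- spearman_exact(x, y, "greater", n_exact = 5, n_perm = 2e4, seed = 7)
  expect_identical(a$p, b$p)
  expect_equal(a$method, "montecarlo")
  # forcing enumeration on the same data gives a p within Monte-Carlo error
  ex <- spearman_exact(x, y, "greater")
  expect_equal(ex$method, "exact")
  se <- sqrt(ex$p * (1 - ex$p) / 2e4)
  expect_lt(abs(a$p - ex$p), 4 * se + 1e-4)
})

test_that("permutation p-values are valid under the null", {
  n_sim <- 300
  hits01 <- hits05 <- 0
  set.seed(31)
  xs <- matrix(rnorm(8 * n_sim), n_sim)
  ys <- matrix(rnorm(8 * n_sim), n_sim)
  for (i in seq_len(n_sim)) {
    p <- spearman_exact(xs[i, ], ys[i, ], "two")$p
    hits01 <- hits01 + (p <= 0.01)
    hits05 <- hits05 + (p <= 0.05)
  }
  se <- function(a) sqrt(a * (1 - a) / n_sim)
  expect_lte(hits01 / n_sim, 0.01 + 3 * se(0.01))
  expect_lte(hits05 / n_sim, 0.05 + 3 * se(0.05))
})

test_that("partial Spearman removes controlled-away signal", {
  set.seed(8)
  # z independent of both: partial rho approximates plain rho
  x <- rnorm(1000); y <- 0.6 * x + rnorm(1000); z <- rnorm(1000)
  pr <- partial_spearman(x, y, z, n_perm = 200, seed = 1)
  plain <- cor(x, y, method = "spearman")
  expect_lt(abs(pr$rho - plain), 0.05)
  # y identical to z: nothing left after controlling
  pr2 <- partial_spearman(x, z, z, n_perm = 200, seed = 1)
  expect_lt(abs(pr2$rho), 1e-6)
  # a real partial signal is detected
  w <- runif(40)
  mig <- w + rnorm(40, 0, 0.1); gro <- 1 - 0.5 * w + rnorm(40, 0, 0.1)
  pr3 <- partial_spearman(w, mig, gro, sidedness = "greater",
                          n_perm = 2000, seed = 2)
  expect_gt(pr3$rho, 0)
  expect_lt(pr3$p, 0.05)
  expect_error(partial_spearman(1:3, 1:3, 1:3), "n >= 4")
})

test_that("Benjamini-Hochberg matches the manual step-up rule", {
  r <- bh_fdr(c(0.01, 0.02, 0.04))
  expect_true(all(r$significant))          # 0.01<=0.0167, 0.02<=0.0333, 0.04<=0.05
  expect_equal(r$adjusted, c(0.03, 0.03, 0.04))
  expect_false(any(bh_fdr(c(0.5, 0.6, 0.9))$significant))
  expect_true(bh_fdr(0.05)$significant)    # m = 1 reduces to the raw threshold
  # never more discoveries than unadjusted thresholding
  set.seed(3)
  p <- runif(50)^2
  r2 <- bh_fdr(p)
  expect_lte(sum(r2$significant), sum(p <= 0.05))
  expect_error(bh_fdr(c(0.1, 0)), "p > 0")
})
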