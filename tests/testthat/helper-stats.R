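# Brute-force Spearman permutation oracle: enumerates permutations
# recursively and evaluates cor() directly, independent of the package's
# rank-sum shortcut.
brute_spearman_p <- function(x, y, sidedness) {
  n <- length(x)
  rho_obs <- cor(x, y, method = "spearman")
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  rhos <- vapply(perms(seq_len(n)), function(p)
    cor(x[p], y, method = "spearman"), numeric(1))
  eps <- 1e-12
  switch(sidedness,
         two = mean(abs(rhos) >= abs(rho_obs) - eps),
         greater = mean(rhos >= rho_obs - eps),
         less = mean(rhos <= rho_obs + eps))
}
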