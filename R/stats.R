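# Rank statistics: Spearman correlation with exact or Monte-Carlo
# permutation p-values, partial Spearman correlation, Benjamini-Hochberg
# FDR, and the shuffle-based cohort-level drug-response association.

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  for (k in seq_len(n)) {
    rows <- (k - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- k
    out[rows, -1L] <- ifelse(sub >= k, sub + 1L, sub)
  }
  out
}

rho_from_sums <- function(s, rx, ry) {
  n <- length(rx)
  num <- s - n * mean(rx) * mean(ry)
  den <- (n - 1) * stats::sd(rx) * stats::sd(ry)
  num / den
}

perm_pvalue <- function(rho_null, rho_obs, sidedness, exact) {
  eps <- 1e-12
  count <- switch(sidedness,
    two = sum(abs(rho_null) >= abs(rho_obs) - eps),
    greater = sum(rho_null >= rho_obs - eps),
    less = sum(rho_null <= rho_obs + eps))
  if (exact) count / length(rho_null)
  else (1 + count) / (1 + length(rho_null))   # add-one for Monte Carlo
}

#' Spearman correlation with permutation p-value
#'
#' Rank correlation (mid-ranks for ties) with a p-value from the exact
#' permutation distribution when `n <= n_exact`, otherwise from seeded
#' Monte-Carlo permutations.
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @param sidedness `"two"`, `"greater"` or `"less"`.
#' @param n_exact maximal n for full enumeration (n! permutations).
#' @param n_perm Monte-Carlo permutation count for larger n.
#' @param seed RNG seed for the Monte-Carlo path.
#' @return list of class `assoc_result`: `rho`, `p`, `n`, `method`
#'   (`"exact"` or `"montecarlo"`), `sidedness`. A constant input yields
#'   `rho = NA` with `method = "undefined"`.
#' @export
#' @examples
#' spearman_exact(1:3, 1:3, "greater")$p   # 1/6
spearman_exact <- function(x, y, sidedness = c("two", "greater", "less"),
                           n_exact = 9L, n_perm = 1e5L, seed = 1L) {
  sidedness <- match.arg(sidedness)
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("need n >= 3", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not supported", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(list(rho = NA_real_, p = NA_real_, n = n,
                          method = "undefined", sidedness = sidedness),
                     class = "assoc_result"))
  rx <- rank(x); ry <- rank(y)
  rho <- rho_from_sums(sum(rx * ry), rx, ry)
  if (n <= n_exact) {
    P <- all_permutations(n)
    s_null <- as.numeric(matrix(rx[P], nrow(P)) %*% ry)
    rho_null <- rho_from_sums(s_null, rx, ry)
    p <- perm_pvalue(rho_null, rho, sidedness, exact = TRUE)
    method <- "exact"
  } else {
    rho_null <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i)
        rho_from_sums(sum(sample(rx) * ry), rx, ry), numeric(1))
    })
    p <- perm_pvalue(rho_null, rho, sidedness, exact = FALSE)
    method <- "montecarlo"
  }
  structure(list(rho = rho, p = p, n = n, method = method, sidedness = sidedness),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("<assoc_result> rho = %.4f, p = %.4g (%s, %s-sided, n = %d)\n",
              x$rho, x$p, x$method, x$sidedness, x$n))
  invisible(x)
}

#' Partial Spearman correlation
#'
#' Rank correlation of `x` and `y` after removing the linear effect of the
#' ranks of `z` from both (residual-of-ranks). The permutation p-value
#' permutes x's ranks and re-residualises.
#'
#' @param x,y,z numeric vectors of equal length (n >= 4).
#' @param sidedness `"two"`, `"greater"` or `"less"`.
#' @param n_perm number of seeded permutations.
#' @param seed RNG seed.
#' @return an `assoc_result` (method `"montecarlo"`).
#' @export
partial_spearman <- function(x, y, z, sidedness = c("two", "greater", "less"),
                             n_perm = 1e4L, seed = 1L) {
  sidedness <- match.arg(sidedness)
  n <- length(x)
  stopifnot(length(y) == n, length(z) == n)
  if (n < 4L) stop("need n >= 4", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(list(rho = NA_real_, p = NA_real_, n = n,
                          method = "undefined", sidedness = sidedness),
                     class = "assoc_result"))
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  res_on_z <- function(r) stats::residuals(stats::lm.fit(cbind(1, rz), r))
  ey <- res_on_z(ry)
  degen <- function(e, r) stats::sd(e) <= 1e-10 * max(1, stats::sd(r))
  prho <- function(rxp) {
    ex <- res_on_z(rxp)
    if (degen(ex, rxp) || degen(ey, ry)) return(0)
    stats::cor(ex, ey)
  }
  rho <- prho(rx)
  rho_null <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    prho(sample(rx)), numeric(1)))
  p <- perm_pvalue(rho_null, rho, sidedness, exact = FALSE)
  structure(list(rho = rho, p = p, n = n, method = "montecarlo",
                 sidedness = sidedness),
            class = "assoc_result")
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up adjustment; a hypothesis is significant when its adjusted
#' p-value is at most `alpha`.
#'
#' @param p vector of p-values in (0, 1].
#' @param alpha FDR level (default 0.05).
#' @return list with `adjusted` and logical `significant`.
#' @export
bh_fdr <- function(p, alpha = 0.05) {
  stopifnot(all(p > 0 & p <= 1))
  adjusted <- stats::p.adjust(p, method = "BH")
  list(adjusted = adjusted, significant = adjusted <= alpha)
}

#' Cohort-level association between a bioenergetic measure and drug response
#'
#' Correlates a per-line measure (typically the AFR) with every compound's
#' response profile (seeded Monte-Carlo permutation Spearman), applies
#' BH-FDR, and derives an empirical cohort p-value by shuffling the
#' response matrix `n_shuffles` times and recomputing the significant
#' fraction each time (add-one estimator). When `growth` is supplied, a
#' second pass flags compounds associated with the measure but not with
#' growth.
#'
#' @param measure named per-line numeric vector.
#' @param responses compounds x lines matrix (column names = line ids).
#' @param growth optional named per-line growth vector.
#' @param n_shuffles shuffle count for the empirical cohort p-value.
#' @param seed RNG seed.
#' @param alpha FDR level.
#' @param n_perm Monte-Carlo permutations for the per-compound p-values.
#' @param statistic per-compound statistic driving the shuffle test:
#'   `"spearman"` (default) or `"wilcoxon"` (response split by the measure's
#'   median).
#' @return list of class `response_association`: `per_compound` data.frame
#'   (compound, rho, p, p_adj, significant, sign), `fraction_significant`,
#'   `fraction_positive` (among significant), `empirical_p`,
#'   `measure_specific` (compound ids, if growth given) and `settings`.
#' @export
response_association <- function(measure, responses, growth = NULL,
                                 n_shuffles = 1000L, seed = 1L, alpha = 0.05,
                                 n_perm = 1e5L,
                                 statistic = c("spearman", "wilcoxon")) {
  statistic <- match.arg(statistic)
  if (nrow(responses) < 2L) stop("need at least 2 compounds", call. = FALSE)
  if (is.null(names(measure)) || is.null(colnames(responses)) ||
      !setequal(names(measure), colnames(responses)))
    stop("measure and response line ids are misaligned", call. = FALSE)
  responses <- responses[, names(measure), drop = FALSE]
  n <- length(measure)
  rx <- rank(measure)

  with_seed(seed, {
    # shared permutation null: permuting the measure's ranks once serves
    # every compound (the lines are exchangeable under the null); each
    # compound keeps its sorted |rho| null so shuffle p-values are lookups
    Pm <- matrix(rx[vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))],
                 nrow = n_perm, byrow = TRUE)
    nulls <- vector("list", nrow(responses))
    rho <- p <- rep(NA_real_, nrow(responses))
    for (k in seq_len(nrow(responses))) {
      ry <- rank(responses[k, ])
      if (stats::sd(ry) == 0) next
      rho[k] <- rho_from_sums(sum(rx * ry), rx, ry)
      rho_null <- rho_from_sums(as.numeric(Pm %*% ry), rx, ry)
      nulls[[k]] <- sort(abs(rho_null))
      p[k] <- perm_pvalue(rho_null, rho[k], "two", exact = FALSE)
    }
    lookup_p <- function(null_sorted, rho_b) {
      below <- findInterval(abs(rho_b) - 1e-12, null_sorted)
      (1 + length(null_sorted) - below) / (1 + length(null_sorted))
    }
    ok <- !is.na(p)
    fdr <- bh_fdr(p[ok], alpha)
    p_adj <- rep(NA_real_, length(p)); sig <- rep(FALSE, length(p))
    p_adj[ok] <- fdr$adjusted; sig[ok] <- fdr$significant
    frac_sig <- mean(sig[ok])
    frac_pos <- if (any(sig[ok])) mean(rho[ok][sig[ok]] > 0) else NA_real_

    if (statistic == "wilcoxon") {
      hi <- measure > stats::median(measure)
      comp_p <- function(y) stats::wilcox.test(y[hi], y[!hi], exact = FALSE)$p.value
    }
    # empirical cohort p: shuffle each compound's responses, recompute the
    # per-compound p against its stored permutation null, re-apply BH
    frac_null <- vapply(seq_len(n_shuffles), function(b) {
      ps <- vapply(seq_len(nrow(responses)), function(k) {
        ys <- sample(responses[k, ])
        if (statistic == "wilcoxon") return(comp_p(ys))
        if (is.null(nulls[[k]])) return(NA_real_)
        ry <- rank(ys)
        rho_b <- rho_from_sums(sum(rx * ry), rx, ry)
        lookup_p(nulls[[k]], rho_b)
      }, numeric(1))
      ps <- ps[!is.na(ps)]
      mean(bh_fdr(ps, alpha)$significant)
    }, numeric(1))
    empirical_p <- (1 + sum(frac_null >= frac_sig)) / (1 + n_shuffles)

    measure_specific <- NULL
    if (!is.null(growth)) {
      growth <- growth[names(measure)]
      rg <- rank(growth)
      Pg <- matrix(rg[vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))],
                   nrow = n_perm, byrow = TRUE)
      stg <- t(apply(responses, 1, function(y) {
        ry <- rank(y)
        if (stats::sd(ry) == 0) return(c(NA_real_, NA_real_))
        rho_g <- rho_from_sums(sum(rg * ry), rg, ry)
        rho_null <- rho_from_sums(as.numeric(Pg %*% ry), rg, ry)
        c(rho_g, perm_pvalue(rho_null, rho_g, "two", exact = FALSE))
      }))
      okg <- !is.na(stg[, 2])
      sig_g <- rep(FALSE, nrow(responses))
      sig_g[okg] <- bh_fdr(stg[okg, 2], alpha)$significant
      measure_specific <- rownames(responses)[sig & !sig_g]
    }

    structure(list(
      per_compound = data.frame(compound = rownames(responses), rho = rho, p = p,
                                p_adj = p_adj, significant = sig,
                                sign = ifelse(is.na(rho), NA, sign(rho)),
                                stringsAsFactors = FALSE),
      fraction_significant = frac_sig, fraction_positive = frac_pos,
      empirical_p = empirical_p, measure_specific = measure_specific,
      settings = list(n_shuffles = n_shuffles, seed = seed, alpha = alpha,
                      n_perm = n_perm, statistic = statistic)),
      class = "response_association")
  })
}

#' @export
print.response_association <- function(x, ...) {
  cat(sprintf("<response_association> %.0f%% of %d compounds significant (FDR %.2g), %.0f%% positive; empirical cohort p = %.4g\n",
              100 * x$fraction_significant, nrow(x$per_compound),
              x$settings$alpha, 100 * x$fraction_positive, x$empirical_p))
  invisible(x)
}

#' Write an association table as TSV
#' @param assoc a [response_association()] result.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_association_tsv <- function(assoc, path) {
  utils::write.table(assoc$per_compound, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
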