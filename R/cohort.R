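# Synthetic cell-line cohorts with planted phenotype structure.
#
# Each line carries a latent glycolytic character w in [0,1]. Expression of
# the network's glycolytic genes increases with w and of its respiratory
# genes decreases with w (cancer mode); lymphoblast-like "normal" mode
# draws w near 0.5 and uses a glycolysis-low / respiration-high signature,
# so that after tailoring the normal models are never forced to ferment.
# Phenotypes are generated from w: growth decreases with w, migration speed
# increases with w, and a planted fraction of drug-response profiles is
# monotone in w; the rest are pure noise.

#' Generate a synthetic cell-line cohort
#'
#' @param model the generic network the cohort is tailored to (default the
#'   toy-core fixture); must carry `gene_classes` annotations.
#' @param n_lines number of cell lines (>= 4).
#' @param seed RNG seed; everything (expression, phenotypes, drug matrix)
#'   is reproducible from it.
#' @param mode `"cancer"` (w ~ Uniform(0,1), glycolysis scaling with w) or
#'   `"normal"` (w near 0.5, respiration-high signature).
#' @param expr_noise sdlog of the multiplicative log-normal expression noise.
#' @param growth_noise,migration_noise SD of the additive phenotype noise.
#' @param n_compounds number of drug-response profiles.
#' @param planted_fraction fraction of compounds whose response increases
#'   monotonically with w (the rest are standard-normal noise).
#' @param drug_noise SD of the noise added to planted compound responses.
#' @return object of class `synthetic_cohort`: list with `expression`
#'   (genes x lines), `w` (ground truth), `phenotypes` (line, growth,
#'   migration), `responses` (compounds x lines), `planted_compounds`,
#'   `mode`, `seed` and `params`.
#' @export
generate_cohort <- function(model = build_toy_core(check = FALSE),
                            n_lines = 20L, seed = 1L,
                            mode = c("cancer", "normal"),
                            expr_noise = 0.15, growth_noise = 0.05,
                            migration_noise = 0.05, n_compounds = 100L,
                            planted_fraction = 0.3, drug_noise = 0.15) {
  mode <- match.arg(mode)
  if (n_lines < 4L) stop("need at least 4 cell lines", call. = FALSE)
  if (planted_fraction < 0 || planted_fraction > 1 || expr_noise < 0 ||
      growth_noise < 0 || migration_noise < 0 || drug_noise < 0)
    stop("invalid generator parameters", call. = FALSE)
  gc <- model$annotations$gene_classes
  if (is.null(gc)) stop("model carries no gene_classes annotation", call. = FALSE)
  genes <- unique(unlist(gc))

  with_seed(seed, {
    w <- if (mode == "cancer") stats::runif(n_lines)
         else pmin(0.75, pmax(0.25, stats::rnorm(n_lines, 0.5, 0.08)))
    lines <- sprintf("%s%03d", if (mode == "cancer") "C" else "N", seq_len(n_lines))
    expression <- matrix(0, length(genes), n_lines, dimnames = list(genes, lines))
    for (g in genes) {
      base <- if (g %in% gc$glycolytic) {
        if (mode == "cancer") 1.0 + w else rep(0.5, n_lines)
      } else if (g %in% gc$respiratory) {
        if (mode == "cancer") 0.4 + 0.4 * (1 - w) else rep(1.5, n_lines)
      } else {
        if (mode == "cancer") 0.8 + 0.2 * w else rep(0.9, n_lines)
      }
      expression[g, ] <- 100 * base * exp(stats::rnorm(n_lines, 0, expr_noise))
    }
    growth <- 1.0 - 0.5 * w + stats::rnorm(n_lines, 0, growth_noise)
    migration <- 0.2 + 1.0 * w + stats::rnorm(n_lines, 0, migration_noise)
    n_planted <- round(planted_fraction * n_compounds)
    responses <- matrix(stats::rnorm(n_compounds * n_lines), n_compounds, n_lines,
                        dimnames = list(sprintf("compound_%03d", seq_len(n_compounds)),
                                        lines))
    planted <- if (n_planted > 0) rownames(responses)[seq_len(n_planted)] else character(0)
    for (cp in planted)
      responses[cp, ] <- w + stats::rnorm(n_lines, 0, drug_noise)
    structure(list(
      expression = expression, w = stats::setNames(w, lines),
      phenotypes = data.frame(line = lines, growth = growth,
                              migration = migration, stringsAsFactors = FALSE),
      responses = responses, planted_compounds = planted,
      mode = mode, seed = seed,
      params = list(n_lines = n_lines, expr_noise = expr_noise,
                    growth_noise = growth_noise, migration_noise = migration_noise,
                    n_compounds = n_compounds, planted_fraction = planted_fraction,
                    drug_noise = drug_noise)),
      class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d %s lines, %d genes, %d compounds (%d planted), seed %d\n",
              length(x$w), x$mode, nrow(x$expression), nrow(x$responses),
              length(x$planted_compounds), x$seed))
  invisible(x)
}

#' Write cohort tables to a directory
#'
#' Emits `expression.tsv`, `phenotypes.tsv`, `responses.tsv` and a
#' `cohort.json` metadata sidecar matching the pipeline's input schema.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort_tsv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_tsv(cohort$expression, file.path(dir, "expression.tsv"))
  utils::write.table(cohort$phenotypes, file.path(dir, "phenotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(compound = rownames(cohort$responses),
                                cohort$responses, check.names = FALSE),
                     file.path(dir, "responses.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(mode = cohort$mode, seed = cohort$seed,
                            w = as.list(cohort$w),
                            planted_compounds = cohort$planted_compounds,
                            params = cohort$params),
                       file.path(dir, "cohort.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
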