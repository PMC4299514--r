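# Sampling the optimal face: approximately uniform flux distributions from
# the polytope {v : S v = 0, bounds, objective fixed at its maximum}.
#
# Strategy: fix the objective exactly at its optimum, run flux-variability
# analysis on that face, pin the reactions the FVA shows to be determined,
# and hit-and-run walk in the null space of the remaining equality
# constraints starting from the average of the FVA vertices. Uniformity is
# approximate and never contractual; constraint satisfaction is.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

null_basis <- function(M, tol = 1e-10) {
  if (nrow(M) == 0L) return(diag(1, ncol(M)))
  sv <- svd(M, nu = 0, nv = ncol(M))
  keep <- sv$d > tol * max(sv$d, 1)
  r <- sum(keep)
  if (r >= ncol(M)) return(matrix(0, ncol(M), 0))
  sv$v[, (r + 1L):ncol(M), drop = FALSE]
}

#' Sample flux distributions on the maximal-biomass face
#'
#' Draws `n` approximately uniform feasible flux distributions from the
#' solution space restricted to the maximal objective value (fixed exactly,
#' not within a fraction). Warm-up points come from flux-variability
#' vertices; the walk is hit-and-run with the stated burn-in and thinning.
#' Deterministic given `seed`. A face that the flux-variability analysis
#' shows to be a single point yields `n` identical rows, flagged
#' `degenerate`.
#'
#' @param model a [flux_model()]; must be feasible.
#' @param n number of samples (the conventional choice is 1000).
#' @param seed RNG seed (required for reproducibility).
#' @param burn_in discarded initial steps of the walk.
#' @param thin steps between recorded samples.
#' @param degenerate_tol flux range below which a reaction counts as
#'   determined on the face.
#' @return object of class `flux_samples`: list with `samples`
#'   (`n` x reactions matrix), `optimum`, `objective`, `degenerate`,
#'   `seed`, `settings`, `model_id` and `line_id`.
#' @export
sample_optimal_face <- function(model, n = 1000L, seed = 1L,
                                burn_in = 1000L, thin = 100L,
                                degenerate_tol = 1e-9) {
  sol <- solve_fba(model)
  if (sol$status != "optimal")
    stop("cannot sample: model is ", sol$status, call. = FALSE)
  opt <- sol$objective_value
  face <- set_bounds(model, model$objective, lower = opt, upper = opt)

  fva <- flux_variability(face, keep_solutions = TRUE)
  verts <- attr(fva, "vertices")
  rng <- fva$max - fva$min
  fixed <- rng <= degenerate_tol
  settings <- list(burn_in = burn_in, thin = thin, degenerate_tol = degenerate_tol)

  if (all(fixed)) {
    point <- (fva$min + fva$max) / 2
    samples <- matrix(rep(point, each = n), n, n_reactions(model),
                      dimnames = list(NULL, model$reactions$id))
    return(structure(list(samples = samples, optimum = opt,
                          objective = model$objective, degenerate = TRUE,
                          seed = seed, settings = settings,
                          model_id = model$id, line_id = attr(model, "line_id")),
                     class = "flux_samples"))
  }

  lb <- face$reactions$lower_bound
  ub <- face$reactions$upper_bound
  mid <- (fva$min + fva$max) / 2
  lb[fixed] <- mid[fixed]; ub[fixed] <- mid[fixed]

  # equality system: mass balance plus pinned coordinates
  Ifix <- diag(1, n_reactions(model))[fixed, , drop = FALSE]
  N <- null_basis(rbind(face$S, Ifix))
  x <- colMeans(verts)                       # interior-ish start (convexity)
  x[fixed] <- mid[fixed]

  samples <- matrix(NA_real_, n, n_reactions(model),
                    dimnames = list(NULL, model$reactions$id))
  free <- which(!fixed)
  Nf <- N[free, , drop = FALSE]              # pinned rows of N are ~0
  walk <- with_seed(seed,
    .hit_and_run_walk(Nf, lb[free], ub[free], x[free],
                      as.integer(n), as.integer(burn_in), as.integer(thin)))
  samples[, free] <- walk
  samples[, fixed] <- matrix(rep(mid[fixed], each = n), n)
  structure(list(samples = samples, optimum = opt, objective = model$objective,
                 degenerate = FALSE, seed = seed, settings = settings,
                 model_id = model$id, line_id = attr(model, "line_id")),
            class = "flux_samples")
}

#' @export
print.flux_samples <- function(x, ...) {
  cat(sprintf("<flux_samples> %d samples x %d reactions (model %s, optimum %.6g%s)\n",
              nrow(x$samples), ncol(x$samples), x$model_id, x$optimum,
              if (x$degenerate) ", degenerate face" else ""))
  invisible(x)
}

#' Mean (and SD) of a sampled reaction flux
#'
#' The predicted secretion or uptake rate of a reaction is its average flux
#' over the sampled optimal-face distributions.
#'
#' @param samples a [sample_optimal_face()] result.
#' @param reaction reaction id.
#' @return named numeric `c(mean, sd)` for `flux_summary`; `mean_flux`
#'   returns the mean alone.
#' @export
mean_flux <- function(samples, reaction) {
  if (!reaction %in% colnames(samples$samples))
    stop("unknown reaction id: ", reaction, call. = FALSE)
  mean(samples$samples[, reaction])
}

#' @rdname mean_flux
#' @export
flux_summary <- function(samples, reaction) {
  if (!reaction %in% colnames(samples$samples))
    stop("unknown reaction id: ", reaction, call. = FALSE)
  v <- samples$samples[, reaction]
  c(mean = mean(v), sd = stats::sd(v))
}

#' Persist / restore a sample set
#'
#' Samples are written as TSV (rows = samples) with a JSON sidecar holding
#' the seed, settings and provenance.
#'
#' @param samples a `flux_samples` object.
#' @param path TSV path; the sidecar is `<path>.json`.
#' @return `write_flux_samples`: the path, invisibly. `read_flux_samples`:
#'   the restored `flux_samples` object.
#' @export
write_flux_samples <- function(samples, path) {
  utils::write.table(as.data.frame(samples$samples), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- samples[setdiff(names(samples), "samples")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_flux_samples
#' @export
read_flux_samples <- function(path) {
  m <- as.matrix(utils::read.delim(path, check.names = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(c(list(samples = m), meta), class = "flux_samples")
}
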