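# Flux-balance analysis: linear optimisation of a reaction flux subject to
# steady-state mass balance S v = 0 and per-reaction capacity bounds.

#' Solve a flux-balance problem
#'
#' Maximises (or minimises) the flux of a target reaction subject to
#' `S v = 0` and the model's bounds. Only the objective value is unique
#' under LP degeneracy; the returned flux vector is one optimal vertex.
#'
#' @param model a [flux_model()].
#' @param target reaction id to optimise; defaults to the model objective.
#' @param sense `"max"` or `"min"`.
#' @return object of class `fba_solution`: list with `fluxes` (named
#'   numeric; `NA` unless optimal), `objective_value`, `status`
#'   (`"optimal"`, `"infeasible"` or `"unbounded"`) and `target`.
#' @export
#' @examples
#' m <- build_micro3()
#' solve_fba(m)$objective_value   # 10, the uptake bottleneck
solve_fba <- function(model, target = model$objective, sense = c("max", "min")) {
  sense <- match.arg(sense)
  j <- rxn_index(model, target)
  obj <- numeric(n_reactions(model)); obj[j] <- 1
  res <- lp_solve(obj, model$S, rep(0, n_metabolites(model)),
                  model$reactions$lower_bound, model$reactions$upper_bound,
                  maximize = sense == "max")
  fluxes <- stats::setNames(res$x, model$reactions$id)
  structure(list(fluxes = fluxes, objective_value = res$objective,
                 status = res$status, target = target, sense = sense),
            class = "fba_solution")
}

#' @export
print.fba_solution <- function(x, ...) {
  cat(sprintf("<fba_solution> %s %s: status %s, objective %s\n",
              x$sense, x$target, x$status,
              format(x$objective_value, digits = 10)))
  invisible(x)
}

fix_reactions <- function(model, fixed) {
  for (rid in names(fixed)) {
    spec <- fixed[[rid]]
    value <- spec[[1L]]
    tol <- if (length(spec) >= 2L) spec[[2L]] else 1e-9
    lo <- min(value * (1 - tol), value * (1 + tol))
    hi <- max(value * (1 - tol), value * (1 + tol))
    i <- rxn_index(model, rid)
    model$reactions$lower_bound[i] <- max(model$reactions$lower_bound[i], lo)
    model$reactions$upper_bound[i] <- min(model$reactions$upper_bound[i], hi)
    if (model$reactions$lower_bound[i] > model$reactions$upper_bound[i])
      stop("fixing reaction '", rid, "' at ", value,
           " is incompatible with its bounds", call. = FALSE)
  }
  model
}

#' Flux extremum under fixed fluxes
#'
#' Minimum or maximum feasible flux of a target reaction after fixing other
#' reactions to stated values within a relative tolerance (two-sided bound
#' `value * (1 +/- tol)`). The canonical use is the minimal lactate
#' secretion with biomass fixed at its maximum.
#'
#' @param model a [flux_model()].
#' @param target reaction id whose extremum is sought.
#' @param sense `"min"` or `"max"`.
#' @param fixed named list: reaction id -> `c(value, tol)` (tol optional,
#'   default 1e-9 relative).
#' @return scalar extremum (deterministic regardless of LP degeneracy).
#' @export
#' @examples
#' m <- build_warburg_mini()
#' g <- solve_fba(m)$objective_value
#' flux_extremum(m, "EX_lac_out", "min", fixed = list(EX_biomass = c(g)))  # 15
flux_extremum <- function(model, target, sense = c("min", "max"), fixed = list()) {
  sense <- match.arg(sense)
  model2 <- fix_reactions(model, fixed)
  sol <- solve_fba(model2, target = target, sense = sense)
  if (sol$status == "infeasible") {
    # name the offending constraint if a single fixed reaction reproduces it
    for (rid in names(fixed)) {
      one <- tryCatch(fix_reactions(model, fixed[rid]), error = function(e) NULL)
      if (is.null(one) || solve_fba(one, target, sense)$status == "infeasible")
        stop("fixing reaction '", rid, "' makes the model infeasible", call. = FALSE)
    }
    stop("fixed constraints (", paste(names(fixed), collapse = ", "),
         ") are jointly infeasible", call. = FALSE)
  }
  if (sol$status == "unbounded")
    stop("flux of '", target, "' is unbounded under the given constraints", call. = FALSE)
  sol$objective_value
}

#' Flux variability at (optionally) fixed fluxes
#'
#' Per-reaction minimum and maximum flux, typically used on the
#' maximal-biomass face (fix the objective at its optimum first).
#'
#' @param model a [flux_model()].
#' @param reactions reaction ids (default: all).
#' @param fixed as in [flux_extremum()].
#' @param keep_solutions return the optimal vertices visited (used by the
#'   sampler as warm-up points).
#' @return data.frame with `reaction`, `min`, `max`; if `keep_solutions`,
#'   the matrix of vertices is attached as attribute `"vertices"`.
#' @export
flux_variability <- function(model, reactions = model$reactions$id,
                             fixed = list(), keep_solutions = FALSE) {
  model2 <- fix_reactions(model, fixed)
  n <- length(reactions)
  mins <- maxs <- numeric(n)
  verts <- if (keep_solutions) matrix(NA_real_, 2L * n, n_reactions(model),
                                      dimnames = list(NULL, model2$reactions$id))
  for (k in seq_len(n)) {
    lo <- solve_fba(model2, reactions[k], "min")
    hi <- solve_fba(model2, reactions[k], "max")
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("flux variability infeasible for reaction '", reactions[k], "'", call. = FALSE)
    mins[k] <- lo$objective_value; maxs[k] <- hi$objective_value
    if (keep_solutions) { verts[2L * k - 1L, ] <- lo$fluxes; verts[2L * k, ] <- hi$fluxes }
  }
  out <- data.frame(reaction = reactions, min = mins, max = maxs,
                    stringsAsFactors = FALSE)
  if (keep_solutions) attr(out, "vertices") <- verts
  out
}

#' Mass-balance and bound residuals of a flux vector
#'
#' @param model a [flux_model()].
#' @param v named or positional flux vector.
#' @return list with `mass_balance` (max |S v|) and `bounds`
#'   (max bound violation, 0 if none).
#' @export
constraint_residuals <- function(model, v) {
  v <- if (!is.null(names(v))) v[model$reactions$id] else v
  list(mass_balance = max(abs(model$S %*% v)),
       bounds = max(0, model$reactions$lower_bound - v, v - model$reactions$upper_bound))
}
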