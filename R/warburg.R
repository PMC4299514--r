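# Bioenergetic analysis: oxygen calibration, forced lactate secretion,
# hypoxia, inhibition dose-response curves, and the Warburg metrics
# ECAR, OCR, EOR, AFR and the transcript-level BEC index.

#' Bioenergetic metric configuration
#'
#' Names the exchanges and ATP-producing reaction sets a model's Warburg
#' metrics are computed from. Fixture models carry a suitable configuration
#' in `model$annotations`.
#'
#' @param lactate_export,oxygen_uptake exchange reaction ids.
#' @param glycolytic_atp,oxphos_atp reaction ids producing ATP in glycolysis
#'   and in oxidative phosphorylation respectively; mean fluxes are weighted
#'   by each reaction's ATP stoichiometric coefficient.
#' @param atp_metabolite metabolite id used to look up ATP coefficients.
#' @return list of class `metric_config`.
#' @export
metric_config <- function(lactate_export, oxygen_uptake,
                          glycolytic_atp, oxphos_atp, atp_metabolite = "atp") {
  stopifnot(length(glycolytic_atp) >= 1, length(oxphos_atp) >= 1)
  structure(list(lactate_export = lactate_export, oxygen_uptake = oxygen_uptake,
                 glycolytic_atp = glycolytic_atp, oxphos_atp = oxphos_atp,
                 atp_metabolite = atp_metabolite),
            class = "metric_config")
}

model_metric_config <- function(model, config = NULL) {
  cfg <- config %||% model$annotations$metric_config
  if (is.null(cfg))
    stop("no metric_config given and model '", model$id,
         "' carries none in its annotations", call. = FALSE)
  cfg
}

#' Forced lactate secretion
#'
#' Maximal growth and the minimal feasible lactate secretion at that
#' growth. A strictly positive minimum means the model cannot grow
#' optimally without fermenting (the forced-Warburg property).
#'
#' @param model a [flux_model()].
#' @param config a [metric_config()]; defaults to the model's annotations.
#' @param growth_tol relative tolerance used to fix growth at its maximum.
#' @return list with `max_biomass`, `min_lactate` and logical `forced`.
#' @export
#' @examples
#' forced_lactate(build_warburg_mini())   # biomass 5, lactate 15
forced_lactate <- function(model, config = NULL, growth_tol = 1e-9) {
  cfg <- model_metric_config(model, config)
  sol <- solve_fba(model)
  if (sol$status != "optimal")
    stop("growth maximisation is ", sol$status, call. = FALSE)
  opt <- sol$objective_value
  fx <- stats::setNames(list(c(opt, growth_tol)), model$objective)
  lac <- flux_extremum(model, cfg$lactate_export, "min", fixed = fx)
  list(max_biomass = opt, min_lactate = lac, forced = lac > 1e-6)
}

#' Calibrate the oxygen uptake bound
#'
#' Sets the maximal oxygen uptake rate to the highest value under which the
#' minimal lactate secretion (at maximal growth) is still positive: with
#' unlimited oxygen a yield-maximising model stops fermenting, so the
#' normoxic simulations cap oxygen just below that point.
#'
#' The threshold is found by scanning a coarse bound grid for a forcing
#' region and bisecting its upper edge to the requested relative
#' resolution.
#'
#' @param model a [flux_model()].
#' @param resolution relative resolution of the returned bound.
#' @param config a [metric_config()]; defaults to the model's annotations.
#' @param search_max largest oxygen bound considered; if the model is
#'   forced even there, that bound is returned with `saturated = TRUE`.
#' @param grid number of scan points used to locate the forcing region.
#' @return list with `bound` (calibrated O2 upper bound), `model` (copy with
#'   the bound applied), `min_lactate` at the bound, and `saturated`.
#'   Errors with "never forced to ferment" if no oxygen bound forces
#'   lactate secretion.
#' @export
calibrate_oxygen <- function(model, resolution = 1e-3, config = NULL,
                             search_max = NULL, grid = 24L) {
  cfg <- model_metric_config(model, config)
  o2 <- cfg$oxygen_uptake
  cur <- model$reactions$upper_bound[rxn_index(model, o2)]
  hi0 <- search_max %||% if (is.finite(cur)) max(cur * 8, 64) else 1024
  f <- function(b) {
    m <- set_bounds(model, o2, upper = b)
    s <- solve_fba(m)
    if (s$status != "optimal") return(NA_real_)
    flux_extremum(m, cfg$lactate_export, "min",
                  fixed = stats::setNames(list(c(s$objective_value, 1e-9)), m$objective))
  }
  # linear grid to bracket the upper edge plus a geometric tail so narrow
  # low-oxygen forcing regions are not stepped over
  pts <- sort(unique(c(0, hi0 * seq_len(grid) / grid, hi0 / 2^(1:16))))
  vals <- vapply(pts, f, numeric(1))
  pos <- which(!is.na(vals) & vals > 1e-6)
  if (length(pos) == 0L)
    stop("model never forced to ferment: minimal lactate secretion is zero ",
         "at every oxygen bound tested", call. = FALSE)
  top <- max(pos)
  if (top == length(pts)) {
    m <- set_bounds(model, o2, upper = pts[top])
    return(list(bound = pts[top], model = m, min_lactate = vals[top], saturated = TRUE))
  }
  lo <- pts[top]; hi <- pts[top + 1L]      # f(lo) > 0, f(hi) == 0
  while ((hi - lo) > resolution * max(lo, 1e-12)) {
    mid <- (lo + hi) / 2
    v <- f(mid)
    if (!is.na(v) && v > 1e-6) lo <- mid else hi <- mid
  }
  list(bound = lo, model = set_bounds(model, o2, upper = lo),
       min_lactate = f(lo), saturated = FALSE)
}

#' Impose hypoxia
#'
#' Scales the oxygen maximal uptake rate to `fraction` of its normoxic
#' value (default 50%); nothing else is altered.
#'
#' @param model a [flux_model()] with a finite oxygen bound.
#' @param fraction retained fraction of the normoxic bound, in (0, 1].
#' @param config a [metric_config()]; defaults to the model's annotations.
#' @return modified copy of the model.
#' @export
apply_hypoxia <- function(model, fraction = 0.5, config = NULL) {
  if (!(fraction > 0 && fraction <= 1))
    stop("hypoxia fraction must be in (0, 1]", call. = FALSE)
  cfg <- model_metric_config(model, config)
  i <- rxn_index(model, cfg$oxygen_uptake)
  ub <- model$reactions$upper_bound[i]
  if (!is.finite(ub)) stop("oxygen bound must be finite before applying hypoxia", call. = FALSE)
  set_bounds(model, cfg$oxygen_uptake, upper = ub * fraction)
}

#' Warburg metrics from a flux sample set
#'
#' ECAR is identified with the mean lactate-secretion flux, OCR with the
#' mean oxygen-consumption flux, EOR is their ratio, and the AFR is the
#' ratio of mean glycolytic ATP-producing flux to mean OXPHOS ATP-producing
#' flux, each weighted by the reactions' ATP stoichiometric coefficients.
#' Undefined ratios (zero denominator) are flagged, never silently zero.
#'
#' @param samples a [sample_optimal_face()] result.
#' @param model the sampled [flux_model()] (source of ATP coefficients).
#' @param config a [metric_config()]; defaults to the model's annotations.
#' @return list of class `warburg_metrics`: `ecar`, `ocr`, `eor`, `afr`,
#'   `glycolytic_atp_flux`, `oxphos_atp_flux`, `flags` (character), and the
#'   line id when present.
#' @export
compute_metrics <- function(samples, model, config = NULL) {
  cfg <- model_metric_config(model, config)
  mu <- colMeans(samples$samples)
  atp_coeff <- function(rxns) {
    co <- model$S[cfg$atp_metabolite, rxns]
    if (any(co <= 0))
      stop("reaction(s) do not produce ", cfg$atp_metabolite, ": ",
           paste(rxns[co <= 0], collapse = ", "), call. = FALSE)
    co
  }
  gly <- sum(atp_coeff(cfg$glycolytic_atp) * mu[cfg$glycolytic_atp])
  oxp <- sum(atp_coeff(cfg$oxphos_atp) * mu[cfg$oxphos_atp])
  ecar <- unname(mu[cfg$lactate_export])
  ocr <- unname(mu[cfg$oxygen_uptake])
  flags <- character(0)
  eor <- if (ocr > 1e-12) ecar / ocr else { flags <- c(flags, "eor_undefined"); NA_real_ }
  afr <- if (oxp > 1e-12) gly / oxp else { flags <- c(flags, "afr_undefined"); NA_real_ }
  structure(list(line_id = samples$line_id, ecar = ecar, ocr = ocr, eor = eor,
                 afr = afr, glycolytic_atp_flux = gly, oxphos_atp_flux = oxp,
                 flags = flags),
            class = "warburg_metrics")
}

#' @export
print.warburg_metrics <- function(x, ...) {
  cat(sprintf("<warburg_metrics%s> ECAR %.4g  OCR %.4g  EOR %s  AFR %s%s\n",
              if (!is.null(x$line_id)) paste0(" ", x$line_id) else "",
              x$ecar, x$ocr, format(x$eor, digits = 4), format(x$afr, digits = 4),
              if (length(x$flags)) paste0("  [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' Inhibition dose-response of ECAR and OCR
#'
#' Gradually lowers the capacity bound of a target reaction from its full
#' value to zero, and at each level re-solves for maximal growth,
#' re-samples the optimal face and records the mean lactate secretion
#' (ECAR) and mean oxygen consumption (OCR).
#'
#' @param model a [flux_model()].
#' @param reaction id of the inhibited reaction.
#' @param n_levels number of evenly spaced bound levels (full bound -> 0).
#' @param n_samples samples per level.
#' @param seed RNG seed; level k uses `seed + k - 1`.
#' @param config a [metric_config()]; defaults to the model's annotations.
#' @return data.frame of class `dose_response`: `bound_fraction` (1 -> 0),
#'   `inhibition` (0 -> 1), `bound`, `biomass`, `ecar`, `ocr`, `flagged`.
#'   If the reaction carries no flux at the unperturbed optimum the whole
#'   curve is flagged flat.
#' @export
dose_response <- function(model, reaction, n_levels = 21L, n_samples = 1000L,
                          seed = 1L, config = NULL) {
  cfg <- model_metric_config(model, config)
  i <- rxn_index(model, reaction)
  ub0 <- model$reactions$upper_bound[i]
  if (!is.finite(ub0)) stop("inhibited reaction must have a finite upper bound", call. = FALSE)
  sol0 <- solve_fba(model)
  if (sol0$status != "optimal") stop("unperturbed model is ", sol0$status, call. = FALSE)
  face_max <- flux_extremum(model, reaction, "max",
                            fixed = stats::setNames(list(c(sol0$objective_value, 1e-9)),
                                                    model$objective))
  flat <- face_max <= 1e-9
  fracs <- seq(1, 0, length.out = n_levels)
  rows <- lapply(seq_along(fracs), function(k) {
    m <- set_bounds(model, reaction, upper = ub0 * fracs[k])
    s <- solve_fba(m)
    if (s$status != "optimal")
      return(data.frame(bound_fraction = fracs[k], inhibition = 1 - fracs[k],
                        bound = ub0 * fracs[k], biomass = 0, ecar = 0, ocr = 0,
                        flagged = TRUE))
    fs <- sample_optimal_face(m, n = n_samples, seed = seed + k - 1L)
    data.frame(bound_fraction = fracs[k], inhibition = 1 - fracs[k],
               bound = ub0 * fracs[k], biomass = s$objective_value,
               ecar = mean_flux(fs, cfg$lactate_export),
               ocr = mean_flux(fs, cfg$oxygen_uptake),
               flagged = flat)
  })
  out <- do.call(rbind, rows)
  attr(out, "reaction") <- reaction
  attr(out, "flat") <- flat
  class(out) <- c("dose_response", "data.frame")
  out
}

#' BEC index: GAPDH / ATP-synthase-beta expression ratio
#'
#' A transcript-level bioenergetic proxy: the expression ratio between the
#' glycolytic enzyme GAPDH and the beta-catalytic subunit of ATP synthase.
#'
#' @param expression genes x lines matrix.
#' @param gapdh_gene,atp_beta_gene gene ids of the two transcripts.
#' @param line cell-line id(s); `NULL` means all columns.
#' @return named numeric vector of ratios (`NA` where the denominator is 0,
#'   with a warning).
#' @export
bec_index <- function(expression, gapdh_gene, atp_beta_gene, line = NULL) {
  for (g in c(gapdh_gene, atp_beta_gene))
    if (!g %in% rownames(expression)) stop("gene not in expression matrix: ", g, call. = FALSE)
  line <- line %||% colnames(expression)
  num <- expression[gapdh_gene, line]
  den <- expression[atp_beta_gene, line]
  out <- ifelse(den > 0, num / den, NA_real_)
  if (anyNA(out)) warning("BEC undefined (zero ATP-synthase expression) for: ",
                          paste(line[is.na(out)], collapse = ", "))
  stats::setNames(out, line)
}

#' Tabulate Warburg metrics for a cohort
#'
#' @param metrics_list list of `warburg_metrics`.
#' @return data.frame with one row per line.
#' @export
metrics_table <- function(metrics_list) {
  do.call(rbind, lapply(metrics_list, function(m)
    data.frame(line = m$line_id %||% NA_character_, ecar = m$ecar, ocr = m$ocr,
               eor = m$eor, afr = m$afr, flags = paste(m$flags, collapse = ";"),
               stringsAsFactors = FALSE)))
}
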