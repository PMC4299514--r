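# Stoichiometric model container.
#
# A flux_model is a plain list holding a metabolite table, a reaction table
# (bounds, gene rules, exchange flags), the dense stoichiometric matrix S
# (metabolites x reactions), the objective reaction (biomass export), the
# growth-medium uptake caps, and optional bioenergetic annotations used by
# the Warburg metrics. All reactions are treated in the direction they are
# written; uptake and secretion are separate irreversible exchanges.

#' Construct a stoichiometric flux model
#'
#' @param id model identifier.
#' @param metabolites data.frame with columns `id`, `name`, `compartment`.
#' @param reactions data.frame with columns `id`, `lower_bound`,
#'   `upper_bound`, `gene_rule` (character, "" for none) and `is_exchange`.
#'   An optional `name` column is kept.
#' @param stoichiometry named list: for each reaction id, a named numeric
#'   vector of signed coefficients (negative = consumed).
#' @param objective id of the objective (biomass-export) reaction.
#' @param medium optional named numeric: maximal uptake flux per uptake
#'   exchange; applied immediately (bounds are only tightened).
#' @param annotations optional list of bioenergetic annotations; see
#'   [metric_config()].
#' @param units flux units label; fluxes default to mmol/gDW/h and the
#'   biomass flux to 1/h. No conversion is performed.
#'
#' @return object of class `flux_model`.
#' @export
flux_model <- function(id, metabolites, reactions, stoichiometry, objective,
                       medium = NULL, annotations = list(),
                       units = c(flux = "mmol/gDW/h", biomass = "1/h")) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(reactions$gene_rule)) reactions$gene_rule <- ""
  reactions$gene_rule[is.na(reactions$gene_rule)] <- ""
  if (is.null(reactions$is_exchange)) reactions$is_exchange <- FALSE

  S <- matrix(0, nrow(metabolites), nrow(reactions),
              dimnames = list(metabolites$id, reactions$id))
  for (rid in names(stoichiometry)) {
    coef <- stoichiometry[[rid]]
    if (!rid %in% reactions$id) stop("stoichiometry given for unknown reaction: ", rid)
    bad <- setdiff(names(coef), metabolites$id)
    if (length(bad)) stop("reaction ", rid, " references undeclared metabolites: ",
                          paste(bad, collapse = ", "))
    S[names(coef), rid] <- coef
  }

  model <- structure(list(
    id = id, metabolites = metabolites, reactions = reactions, S = S,
    objective = objective, medium = medium %||% stats::setNames(numeric(0), character(0)),
    annotations = annotations, units = units
  ), class = "flux_model")
  model <- apply_medium(model, model$medium)
  validate_flux_model(model)
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate model invariants
#'
#' Checks id uniqueness, bound ordering, non-empty zero-free stoichiometry,
#' that exchanges touch exactly one metabolite, that the objective exists,
#' and that all gene rules parse.
#'
#' @param model a `flux_model`.
#' @return the model, invisibly; errors describe the first violation.
#' @export
validate_flux_model <- function(model) {
  stopifnot(inherits(model, "flux_model"))
  mets <- model$metabolites; rxns <- model$reactions
  if (anyDuplicated(mets$id)) stop("duplicate metabolite ids")
  if (anyDuplicated(rxns$id)) stop("duplicate reaction ids")
  if (any(rxns$lower_bound > rxns$upper_bound))
    stop("lower_bound > upper_bound for: ",
         paste(rxns$id[rxns$lower_bound > rxns$upper_bound], collapse = ", "))
  nz <- colSums(model$S != 0)
  if (any(nz == 0)) stop("empty stoichiometry for: ", paste(rxns$id[nz == 0], collapse = ", "))
  if (any(rxns$is_exchange & nz != 1))
    stop("exchange reactions must touch exactly one metabolite: ",
         paste(rxns$id[rxns$is_exchange & nz != 1], collapse = ", "))
  if (!model$objective %in% rxns$id) stop("objective reaction not in model: ", model$objective)
  for (i in seq_len(nrow(rxns))) parse_gene_rule(rxns$gene_rule[i])
  if (length(model$medium)) {
    bad <- setdiff(names(model$medium), rxns$id[rxns$is_exchange])
    if (length(bad)) stop("medium names non-exchange reactions: ", paste(bad, collapse = ", "))
  }
  invisible(model)
}

#' @export
print.flux_model <- function(x, ...) {
  cat(sprintf("<flux_model '%s'>  %d metabolites, %d reactions (%d exchanges)\n",
              x$id, nrow(x$metabolites), nrow(x$reactions), sum(x$reactions$is_exchange)))
  cat("  objective:", x$objective, "\n")
  invisible(x)
}

#' Number of reactions / metabolites
#' @param model a `flux_model`.
#' @return integer count.
#' @export
n_reactions <- function(model) nrow(model$reactions)

#' @rdname n_reactions
#' @export
n_metabolites <- function(model) nrow(model$metabolites)

rxn_index <- function(model, id) {
  i <- match(id, model$reactions$id)
  if (anyNA(i)) stop("unknown reaction id: ", paste(id[is.na(i)], collapse = ", "), call. = FALSE)
  i
}

#' Set flux bounds on reactions
#'
#' @param model a `flux_model`.
#' @param id reaction id(s).
#' @param lower,upper new bounds (recycled); `NULL` leaves a side unchanged.
#' @return modified copy of the model.
#' @export
set_bounds <- function(model, id, lower = NULL, upper = NULL) {
  i <- rxn_index(model, id)
  if (!is.null(lower)) model$reactions$lower_bound[i] <- lower
  if (!is.null(upper)) model$reactions$upper_bound[i] <- upper
  if (any(model$reactions$lower_bound[i] > model$reactions$upper_bound[i]))
    stop("set_bounds would make lower_bound > upper_bound")
  model
}

#' Apply a growth medium to a model
#'
#' Caps the upper bound of each named uptake exchange at the given maximal
#' uptake flux. Bounds are only ever tightened, never relaxed.
#'
#' @param model a `flux_model`.
#' @param medium named numeric vector, exchange reaction id -> max uptake.
#' @return modified copy of the model.
#' @export
apply_medium <- function(model, medium) {
  if (length(medium) == 0L) return(model)
  i <- rxn_index(model, names(medium))
  if (any(!model$reactions$is_exchange[i]))
    stop("medium names non-exchange reactions: ",
         paste(names(medium)[!model$reactions$is_exchange[i]], collapse = ", "),
         call. = FALSE)
  model$reactions$upper_bound[i] <- pmin(model$reactions$upper_bound[i], unname(medium))
  model$medium <- medium
  model
}

#' Knock out reactions
#'
#' Simulates a knockout by constraining the flux through the reaction to
#' zero (both bounds). The input model is untouched.
#'
#' @param model a `flux_model`.
#' @param id reaction id(s) to knock out.
#' @return modified copy of the model.
#' @export
knockout_reaction <- function(model, id) {
  i <- rxn_index(model, id)
  model$reactions$lower_bound[i] <- 0
  model$reactions$upper_bound[i] <- 0
  model
}

#' Knock out genes
#'
#' Every reaction whose gene rule evaluates to FALSE with the given genes
#' removed (AND = complex broken by any member, OR = isoenzyme backup) is
#' reaction-knocked-out. Gene ids that appear in no rule produce a warning
#' and are ignored.
#'
#' @param model a `flux_model`.
#' @param genes character vector of gene ids to knock out.
#' @return modified copy of the model.
#' @export
knockout_gene <- function(model, genes) {
  asts <- lapply(model$reactions$gene_rule, parse_gene_rule)
  known <- unique(unlist(lapply(asts, rule_genes)))
  unknown <- setdiff(genes, known)
  if (length(unknown))
    warning("gene id(s) not present in any rule, ignored: ", paste(unknown, collapse = ", "))
  closed <- vapply(asts, function(a) !is.null(a) && !eval_rule_knockout(a, genes), logical(1))
  if (any(closed)) model <- knockout_reaction(model, model$reactions$id[closed])
  model
}

#' All genes appearing in a model's rules
#' @param model a `flux_model`.
#' @return character vector of gene ids.
#' @export
model_genes <- function(model) {
  unique(unlist(lapply(model$reactions$gene_rule, function(r) rule_genes(parse_gene_rule(r)))))
}
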