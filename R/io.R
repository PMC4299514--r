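# Model interchange: a native three-table TSV format and SBML Level 3 with
# the FBC (flux-balance constraints) package. The SBML writer/reader covers
# the subset these models use: compartments, species, reactions with
# stoichiometry, FBC flux bounds, gene-product associations and the FBC
# objective. There is no SBML library on CRAN, so the mapping is written
# directly with xml2.

#' Write / read the native TSV model format
#'
#' Three tab-separated tables in `dir`: `metabolites.tsv` (id, name,
#' compartment), `reactions.tsv` (id, name, lower_bound, upper_bound,
#' gene_rule, is_exchange, objective flag and stoichiometry encoded as
#' `"met:coeff;met:coeff;..."`), and `medium.tsv` (exchange, max_uptake).
#'
#' @param model a [flux_model()].
#' @param dir directory (created if needed).
#' @return the directory (write) or the restored model (read).
#' @export
write_model_tsv <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(model$metabolites, file.path(dir, "metabolites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stoich <- vapply(model$reactions$id, function(r) {
    co <- model$S[, r]; co <- co[co != 0]
    paste(sprintf("%s:%.15g", names(co), co), collapse = ";")
  }, character(1))
  rx <- cbind(model$reactions,
              stoichiometry = stoich,
              objective = model$reactions$id == model$objective)
  utils::write.table(rx, file.path(dir, "reactions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  med <- data.frame(exchange = names(model$medium),
                    max_uptake = unname(model$medium), stringsAsFactors = FALSE)
  utils::write.table(med, file.path(dir, "medium.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(model$annotations)) {
    ann <- model$annotations
    if (!is.null(ann$metric_config)) ann$metric_config <- unclass(ann$metric_config)
    jsonlite::write_json(ann, file.path(dir, "annotations.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname write_model_tsv
#' @param id model id for the restored model (default: directory name).
#' @export
read_model_tsv <- function(dir, id = basename(dir)) {
  need <- file.path(dir, c("metabolites.tsv", "reactions.tsv"))
  for (f in need) if (!file.exists(f))
    stop("missing model table: ", f, call. = FALSE)
  mets <- utils::read.delim(file.path(dir, "metabolites.tsv"))
  rx <- utils::read.delim(file.path(dir, "reactions.tsv"),
                          colClasses = c(gene_rule = "character"))
  for (col in c("id", "lower_bound", "upper_bound", "stoichiometry", "objective"))
    if (!col %in% names(rx))
      stop("reactions.tsv lacks column '", col, "'", call. = FALSE)
  stoich <- lapply(rx$stoichiometry, function(s) {
    parts <- strsplit(strsplit(s, ";")[[1]], ":")
    stats::setNames(vapply(parts, function(p) as.numeric(p[2]), numeric(1)),
                    vapply(parts, `[[`, "", 1))
  })
  names(stoich) <- rx$id
  medium <- NULL
  medf <- file.path(dir, "medium.tsv")
  if (file.exists(medf)) {
    med <- utils::read.delim(medf)
    if (nrow(med)) medium <- stats::setNames(med$max_uptake, med$exchange)
  }
  annotations <- list()
  annf <- file.path(dir, "annotations.json")
  if (file.exists(annf)) {
    annotations <- jsonlite::read_json(annf, simplifyVector = TRUE)
    if (!is.null(annotations$metric_config))
      annotations$metric_config <- do.call(metric_config, annotations$metric_config)
  }
  flux_model(id, mets, rx[, setdiff(names(rx), c("stoichiometry", "objective"))],
             stoich, objective = rx$id[rx$objective][1], medium = medium,
             annotations = annotations)
}

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

sbml_id <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

#' Export a model to SBML Level 3 + FBC
#'
#' @param model a [flux_model()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_sbml <- function(model, path) {
  doc <- xml2::xml_new_root("sbml",
    xmlns = SBML_NS, "xmlns:fbc" = FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = sbml_id(model$id),
                             "fbc:strict" = "true")

  comps <- unique(model$metabolites$compartment)
  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cp in comps)
    xml2::xml_add_child(lc, "compartment", id = sbml_id(cp), constant = "true")

  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    xml2::xml_add_child(ls, "species", id = paste0("M_", sbml_id(m$id)),
                        name = m$name, compartment = sbml_id(m$compartment),
                        hasOnlySubstanceUnits = "false", boundaryCondition = "false",
                        constant = "false")
  }

  # flux bounds as shared parameters
  bounds <- sort(unique(c(model$reactions$lower_bound, model$reactions$upper_bound)))
  bid <- function(v) {
    if (!is.finite(v)) return(if (v > 0) "P_inf" else "P_ninf")
    paste0("P_b_", gsub("[^0-9A-Za-z]", "_", format(v, digits = 15)))
  }
  lp <- xml2::xml_add_child(mdl, "listOfParameters")
  for (v in unique(c(bounds, Inf, -Inf)))
    xml2::xml_add_child(lp, "parameter", id = bid(v),
                        value = format(if (is.finite(v)) v else sign(v) * 1e30, digits = 15),
                        constant = "true")

  genes <- model_genes(model)
  if (length(genes)) {
    lg <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
    for (g in genes)
      xml2::xml_add_child(lg, "fbc:geneProduct",
                          "fbc:id" = paste0("G_", sbml_id(g)), "fbc:label" = g)
  }

  add_assoc <- function(node, ast) {
    if (!is.null(ast$gene)) {
      xml2::xml_add_child(node, "fbc:geneProductRef",
                          "fbc:geneProduct" = paste0("G_", sbml_id(ast$gene)))
    } else {
      inner <- xml2::xml_add_child(node, if (ast$op == "and") "fbc:and" else "fbc:or")
      for (a in ast$args) add_assoc(inner, a)
    }
  }

  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    rn <- xml2::xml_add_child(lr, "reaction", id = paste0("R_", sbml_id(r$id)),
                              name = r$name, reversible = if (r$lower_bound < 0) "true" else "false",
                              fast = "false",
                              "fbc:lowerFluxBound" = bid(r$lower_bound),
                              "fbc:upperFluxBound" = bid(r$upper_bound))
    co <- model$S[, r$id]; co <- co[co != 0]
    reac <- co[co < 0]; prod <- co[co > 0]
    if (length(reac)) {
      lrc <- xml2::xml_add_child(rn, "listOfReactants")
      for (mname in names(reac))
        xml2::xml_add_child(lrc, "speciesReference",
                            species = paste0("M_", sbml_id(mname)),
                            stoichiometry = format(-reac[[mname]], digits = 15),
                            constant = "true")
    }
    if (length(prod)) {
      lpd <- xml2::xml_add_child(rn, "listOfProducts")
      for (mname in names(prod))
        xml2::xml_add_child(lpd, "speciesReference",
                            species = paste0("M_", sbml_id(mname)),
                            stoichiometry = format(prod[[mname]], digits = 15),
                            constant = "true")
    }
    ast <- parse_gene_rule(r$gene_rule)
    if (!is.null(ast)) {
      ga <- xml2::xml_add_child(rn, "fbc:geneProductAssociation")
      add_assoc(ga, ast)
    }
  }

  lo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                            "fbc:activeObjective" = "obj")
  ob <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj",
                            "fbc:type" = "maximize")
  lf <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
  xml2::xml_add_child(lf, "fbc:fluxObjective",
                      "fbc:reaction" = paste0("R_", sbml_id(model$objective)),
                      "fbc:coefficient" = "1")
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Import a model from SBML Level 3 + FBC
#'
#' @param path SBML file written by [write_sbml()] or a compatible tool.
#' @param id model id (default: the SBML model id).
#' @return a [flux_model()]. Exchange status is inferred from reactions
#'   touching exactly one metabolite.
#' @export
read_sbml <- function(path, id = NULL) {
  doc <- xml2::read_xml(path)
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (is.na(xml2::xml_name(mdl))) stop("no <model> element found", call. = FALSE)
  id <- id %||% xml2::xml_attr(mdl, "id")

  sp <- xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species", ns)
  mets <- data.frame(
    id = sub("^M_", "", xml2::xml_attr(sp, "id")),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                  sub("^M_", "", xml2::xml_attr(sp, "id")), xml2::xml_attr(sp, "name")),
    compartment = xml2::xml_attr(sp, "compartment"),
    stringsAsFactors = FALSE)

  pars <- xml2::xml_find_all(mdl, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                          xml2::xml_attr(pars, "id"))
  pval[abs(pval) >= 1e30] <- sign(pval[abs(pval) >= 1e30]) * Inf

  gp <- xml2::xml_find_all(mdl, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  glabel <- stats::setNames(xml2::xml_attr(gp, "label"), xml2::xml_attr(gp, "id"))

  assoc_to_rule <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      gid <- xml2::xml_attr(node, "geneProduct")
      lbl <- glabel[gid]
      return(if (is.na(lbl)) sub("^G_", "", gid) else unname(lbl))
    }
    kids <- xml2::xml_children(node)
    parts <- vapply(kids, assoc_to_rule, character(1))
    op <- if (nm == "and") " AND " else " OR "
    paste0("(", paste(parts, collapse = op), ")")
  }

  rns <- xml2::xml_find_all(mdl, ".//s:listOfReactions/s:reaction", ns)
  stoich <- list()
  rxrows <- lapply(rns, function(rn) {
    rid <- sub("^R_", "", xml2::xml_attr(rn, "id"))
    get_side <- function(tag, sgn) {
      refs <- xml2::xml_find_all(rn, paste0("./s:", tag, "/s:speciesReference"), ns)
      stats::setNames(sgn * as.numeric(xml2::xml_attr(refs, "stoichiometry")),
                      sub("^M_", "", xml2::xml_attr(refs, "species")))
    }
    co <- c(get_side("listOfReactants", -1), get_side("listOfProducts", 1))
    stoich[[rid]] <<- co
    ga <- xml2::xml_find_first(rn, "./fbc:geneProductAssociation", ns)
    rule <- if (is.na(xml2::xml_name(ga))) "" else {
      assoc_to_rule(xml2::xml_children(ga)[[1]])
    }
    data.frame(id = rid,
               name = ifelse(is.na(xml2::xml_attr(rn, "name")), rid,
                             xml2::xml_attr(rn, "name")),
               lower_bound = unname(pval[xml2::xml_attr(rn, "lowerFluxBound")]),
               upper_bound = unname(pval[xml2::xml_attr(rn, "upperFluxBound")]),
               gene_rule = gsub("^\\((.*)\\)$", "\\1", rule),
               is_exchange = length(co) == 1L,
               stringsAsFactors = FALSE)
  })
  rx <- do.call(rbind, rxrows)
  obj <- xml2::xml_find_first(
    mdl, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective", ns)
  if (is.na(xml2::xml_name(obj))) stop("no FBC objective found", call. = FALSE)
  objective <- sub("^R_", "", xml2::xml_attr(obj, "reaction"))
  flux_model(id, mets, rx, stoich, objective = objective)
}
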