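# Expression-tailored cell-line models.
#
# A cohort of cell-line models is built from one generic scaffold by
# mapping each line's enzyme expression to maximal flux-capacity bounds on
# a designated growth-associated reaction subset: per reaction, expression
# is aggregated over the gene rule (OR = sum of isoenzymes, AND = minimum
# over complex members), min-max normalised across the cohort, and mapped
# linearly onto [floor_fraction, 1] of a base capacity.

#' Read / write an expression matrix
#'
#' TSV layout: first column `gene`, remaining columns one per cell line.
#'
#' @param path TSV file.
#' @return numeric matrix, genes x lines.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (any(m < 0)) stop("expression levels must be non-negative")
  m
}

#' @rdname read_expression_tsv
#' @param expression genes x lines matrix.
#' @export
write_expression_tsv <- function(expression, path) {
  df <- data.frame(gene = rownames(expression), expression, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Tailoring configuration
#'
#' @param target_reactions reaction ids whose maximal capacity is tailored;
#'   `NULL` selects every non-exchange reaction with a gene rule.
#' @param floor_fraction minimal retained capacity fraction (0 < eps < 1);
#'   even the least-expressing line keeps this fraction of `base_bound`.
#' @param base_bound flux cap applied to target reactions before scaling.
#' @return list of class `tailoring_config`.
#' @export
tailoring_config <- function(target_reactions = NULL, floor_fraction = 0.1,
                             base_bound = 100) {
  stopifnot(floor_fraction > 0, floor_fraction < 1, base_bound > 0)
  structure(list(target_reactions = target_reactions,
                 floor_fraction = floor_fraction, base_bound = base_bound),
            class = "tailoring_config")
}

#' Aggregate expression onto reactions
#'
#' Per reaction, aggregates the expression of its catalysing enzymes over
#' the gene rule: OR-operands (isoenzymes) are summed, AND-operands
#' (complex members) contribute their minimum, recursively. Reactions with
#' no rule or no measured gene are absent from the result.
#'
#' @param model a [flux_model()].
#' @param expression genes x lines numeric matrix.
#' @param line cell-line id (column of `expression`).
#' @return named numeric vector, reaction id -> aggregated level.
#' @export
#' @examples
#' m <- build_warburg_mini()
#' expr <- matrix(c(3, 5), 2, 1, dimnames = list(c("gLDH1", "gLDH2"), "L1"))
#' reaction_expression(m, expr, "L1")   # LDH = 3 + 5 (isoenzymes sum)
reaction_expression <- function(model, expression, line) {
  if (!line %in% colnames(expression)) stop("unknown cell line: ", line, call. = FALSE)
  levels <- expression[, line]
  out <- vapply(model$reactions$gene_rule, function(r)
    eval_rule_expression(parse_gene_rule(r), levels), numeric(1), USE.NAMES = FALSE)
  names(out) <- model$reactions$id
  out[!is.na(out)]
}

#' Build expression-tailored cell-line models
#'
#' For each target reaction r and line l the upper bound becomes
#' `base_bound * (eps + (1 - eps) * x)`, where `x` is the min-max
#' normalisation of the reaction's aggregated expression across the cohort.
#' A target reaction with zero cross-line variance is left unpenalised
#' (`x = 1`). Lower bounds and non-target reactions are untouched.
#'
#' @param generic the generic scaffold [flux_model()].
#' @param expression genes x lines matrix (>= 2 lines).
#' @param config a [tailoring_config()].
#' @return list of `cell_line_model` objects: each has `line`, `model` and
#'   `bounds` (data.frame reaction/line/bound of the applied caps).
#' @export
tailor_cohort <- function(generic, expression, config = tailoring_config()) {
  if (ncol(expression) < 2L)
    stop("cross-line normalisation needs at least 2 cell lines", call. = FALSE)
  lines <- colnames(expression)
  targets <- config$target_reactions
  if (is.null(targets)) {
    has_rule <- nzchar(generic$reactions$gene_rule)
    targets <- generic$reactions$id[has_rule & !generic$reactions$is_exchange]
  } else {
    i <- rxn_index(generic, targets)
    if (any(!nzchar(generic$reactions$gene_rule[i])))
      stop("target reactions must carry a gene rule", call. = FALSE)
  }

  # reaction x line matrix of aggregated expression over the target set
  agg <- vapply(lines, function(l) {
    re <- reaction_expression(generic, expression, l)
    unname(re[targets])
  }, numeric(length(targets)))
  agg <- matrix(agg, nrow = length(targets),
                dimnames = list(targets, lines))
  measured <- rowSums(is.na(agg)) == 0L
  if (any(!measured))
    message("dropping ", sum(!measured), " target reaction(s) with unmeasured genes: ",
            paste(targets[!measured], collapse = ", "))
  agg <- agg[measured, , drop = FALSE]

  lo <- apply(agg, 1, min); hi <- apply(agg, 1, max)
  span <- hi - lo
  eps <- config$floor_fraction
  lapply(lines, function(l) {
    x <- ifelse(span > 0, (agg[, l] - lo) / span, 1)  # zero variance -> no penalty
    bound <- config$base_bound * (eps + (1 - eps) * x)
    model <- set_bounds(generic, rownames(agg), upper = unname(bound))
    model$id <- paste0(generic$id, ":", l)
    attr(model, "line_id") <- l
    structure(list(line = l, model = model,
                   bounds = data.frame(reaction = rownames(agg), line = l,
                                       bound = unname(bound),
                                       stringsAsFactors = FALSE),
                   config = config),
              class = "cell_line_model")
  })
}

#' @export
print.cell_line_model <- function(x, ...) {
  cat(sprintf("<cell_line_model '%s'> %d tailored bounds\n", x$line, nrow(x$bounds)))
  invisible(x)
}

#' Write the tailoring record of a cohort
#'
#' One TSV row per (reaction, line) with the applied upper bound.
#'
#' @param cohort list of `cell_line_model` from [tailor_cohort()].
#' @param path output TSV.
#' @return the path, invisibly.
#' @export
write_tailoring_tsv <- function(cohort, path) {
  rec <- do.call(rbind, lapply(cohort, `[[`, "bounds"))
  utils::write.table(rec, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
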