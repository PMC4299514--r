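# Gene-protein-reaction (GPR) boolean rules.
#
# A rule is a boolean expression over gene identifiers, e.g.
# "(g1 AND g2) OR g3". OR encodes isoenzymes, AND encodes enzyme complexes.
# Rules are parsed once into a nested list AST and evaluated either as
# booleans (knockout semantics) or numerically (expression aggregation:
# OR = sum of operands, AND = minimum of operands).

#' Parse a gene-protein-reaction rule
#'
#' Parses a boolean gene rule such as `"(g1 AND g2) OR g3"` into an AST.
#' `AND`/`OR` are case-insensitive; `&`/`|` are accepted as synonyms.
#' OR binds less tightly than AND.
#'
#' @param rule character rule; `NA` or `""` yields `NULL` (no rule).
#' @return `NULL`, or a nested list: leaves are `list(gene = <id>)`, inner
#'   nodes `list(op = "and"|"or", args = list(...))`.
#' @export
#' @examples
#' parse_gene_rule("(g1 AND g2) OR g3")
parse_gene_rule <- function(rule) {
  if (is.null(rule) || length(rule) == 0L || is.na(rule) || !nzchar(trimws(rule)))
    return(NULL)
  s <- gsub("([()])", " \\1 ", rule)
  s <- gsub("&&|&", " and ", s)
  s <- gsub("\\|\\||\\|", " or ", s)
  toks <- strsplit(trimws(s), "\\s+")[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { pos <<- pos + 1L }
  parse_atom <- function() {
    tk <- peek()
    if (is.na(tk)) stop("malformed gene rule: ", rule, call. = FALSE)
    if (tk == "(") {
      advance()
      node <- parse_or()
      if (!identical(peek(), ")")) stop("unbalanced parentheses in gene rule: ", rule, call. = FALSE)
      advance()
      return(node)
    }
    if (tk == ")" || tolower(tk) %in% c("and", "or"))
      stop("malformed gene rule: ", rule, call. = FALSE)
    advance()
    list(gene = tk)
  }
  parse_and <- function() {
    args <- list(parse_atom())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance()
      args <- c(args, list(parse_atom()))
    }
    if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  }
  parse_or <- function() {
    args <- list(parse_and())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance()
      args <- c(args, list(parse_and()))
    }
    if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  }
  node <- parse_or()
  if (!is.na(peek())) stop("trailing tokens in gene rule: ", rule, call. = FALSE)
  node
}

#' Genes referenced by a parsed rule
#' @param ast parsed rule from [parse_gene_rule()].
#' @return character vector of unique gene ids (empty for `NULL`).
#' @export
rule_genes <- function(ast) {
  if (is.null(ast)) return(character(0))
  if (!is.null(ast$gene)) return(ast$gene)
  unique(unlist(lapply(ast$args, rule_genes)))
}

#' Evaluate a rule under gene knockouts
#'
#' A gene is functional unless listed in `knocked`. AND requires all
#' operands, OR requires at least one.
#'
#' @param ast parsed rule; `NULL` means no gene dependence (always TRUE).
#' @param knocked character vector of knocked-out gene ids.
#' @return logical: is the reaction still catalysed?
#' @export
eval_rule_knockout <- function(ast, knocked) {
  if (is.null(ast)) return(TRUE)
  if (!is.null(ast$gene)) return(!(ast$gene %in% knocked))
  vals <- vapply(ast$args, eval_rule_knockout, logical(1), knocked = knocked)
  if (ast$op == "and") all(vals) else any(vals)
}

#' Aggregate expression levels over a rule
#'
#' OR-nodes (isoenzymes) sum their operands; AND-nodes (complexes) take the
#' minimum, recursively. Genes missing from `levels` contribute `NA` and are
#' dropped within a node; a node whose operands are all missing is `NA`.
#'
#' @param ast parsed rule.
#' @param levels named numeric vector of expression levels per gene.
#' @return aggregated level, or `NA` if no operand gene is measured
#'   (also `NA` for a `NULL` rule).
#' @export
eval_rule_expression <- function(ast, levels) {
  if (is.null(ast)) return(NA_real_)
  if (!is.null(ast$gene)) {
    v <- unname(levels[ast$gene])
    return(if (length(v) == 0L || is.na(v)) NA_real_ else v)
  }
  vals <- vapply(ast$args, eval_rule_expression, numeric(1), levels = levels)
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) return(NA_real_)
  if (ast$op == "and") min(vals) else sum(vals)
}

#' Render a parsed rule back to text
#' @param ast parsed rule.
#' @return character rule ("" for `NULL`).
#' @export
deparse_gene_rule <- function(ast) {
  if (is.null(ast)) return("")
  if (!is.null(ast$gene)) return(ast$gene)
  parts <- vapply(ast$args, function(a) {
    txt <- deparse_gene_rule(a)
    if (is.null(a$gene) && a$op != ast$op) paste0("(", txt, ")") else txt
  }, character(1))
  paste(parts, collapse = if (ast$op == "and") " AND " else " OR ")
}
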