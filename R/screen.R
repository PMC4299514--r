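# The three-filter in-silico knockout screen.
#
# Every candidate reaction is knocked out in every cell-line model.
# Stage 1 keeps knockouts that abolish forced lactate secretion in all
# lines; stage 2 keeps those that retain more than 10% of wild-type growth;
# stage 3 keeps those that reduce the sampled AFR below 60% of its
# wild-type level. An optional normal cohort must also retain growth.

#' Screen configuration
#'
#' @param growth_fraction_threshold knockout growth must exceed this
#'   fraction of wild type (strictly; default 0.10).
#' @param afr_fraction_threshold knockout AFR must fall strictly below this
#'   fraction of wild type (default 0.60).
#' @param lactate_zero_tolerance absolute flux below which the minimal
#'   lactate secretion counts as abolished.
#' @param require_all_lines stage-2 growth sparing required in every line
#'   (`TRUE`, default) or on average.
#' @param afr_mode stage-3 uses the mean AFR fraction across lines
#'   (`"mean"`, default) or per-line unanimity (`"all"`).
#' @param exclude_exchanges drop exchange reactions from the candidate set.
#' @param normal_cohort optional list of normal-cohort models (or
#'   `cell_line_model`s); survivors must also spare their growth.
#' @return list of class `screen_config`.
#' @export
screen_config <- function(growth_fraction_threshold = 0.10,
                          afr_fraction_threshold = 0.60,
                          lactate_zero_tolerance = 1e-6,
                          require_all_lines = TRUE,
                          afr_mode = c("mean", "all"),
                          exclude_exchanges = FALSE,
                          normal_cohort = NULL) {
  stopifnot(growth_fraction_threshold > 0, growth_fraction_threshold <= 1,
            afr_fraction_threshold > 0, afr_fraction_threshold <= 1)
  structure(list(growth_fraction_threshold = growth_fraction_threshold,
                 afr_fraction_threshold = afr_fraction_threshold,
                 lactate_zero_tolerance = lactate_zero_tolerance,
                 require_all_lines = require_all_lines,
                 afr_mode = match.arg(afr_mode),
                 exclude_exchanges = exclude_exchanges,
                 normal_cohort = normal_cohort),
            class = "screen_config")
}

as_model_list <- function(cohort) {
  if (inherits(cohort, "flux_model")) cohort <- list(cohort)
  models <- lapply(cohort, function(x) if (inherits(x, "cell_line_model")) x$model else x)
  nm <- vapply(seq_along(models), function(i) {
    ln <- attr(models[[i]], "line_id")
    if (!is.null(ln)) ln else models[[i]]$id
  }, character(1))
  stats::setNames(models, make.unique(nm))
}

#' Run the three-filter knockout screen
#'
#' @param cohort a `flux_model`, a list of them, or a list of
#'   `cell_line_model`s. Every model must have positive wild-type growth
#'   and positive forced lactate secretion.
#' @param config a [screen_config()].
#' @param reactions candidate reaction ids; default: every reaction except
#'   the objective (and exchanges, if excluded by config).
#' @param n_samples flux samples per AFR evaluation.
#' @param seed RNG seed for the sampling.
#' @param metric_config a [metric_config()]; defaults to each model's
#'   annotations.
#' @return object of class `warburg_screen`: list with `records` (one row
#'   per reaction x line), `summary` (one row per reaction with stage
#'   verdicts), `survivors` (final reaction ids) and `config`.
#' @export
run_screen <- function(cohort, config = screen_config(), reactions = NULL,
                       n_samples = 1000L, seed = 1L, metric_config = NULL) {
  models <- as_model_list(cohort)
  tol <- config$lactate_zero_tolerance

  wt <- lapply(names(models), function(ln) {
    m <- models[[ln]]
    cfg <- metric_config %||% m$annotations$metric_config
    if (is.null(cfg)) stop("no metric_config for line ", ln, call. = FALSE)
    fl <- forced_lactate(m, config = cfg)
    if (fl$max_biomass <= 0)
      stop("wild-type growth is zero for line ", ln, call. = FALSE)
    if (fl$min_lactate <= tol)
      stop("wild type of line ", ln, " shows no forced lactate secretion", call. = FALSE)
    list(line = ln, model = m, cfg = cfg, growth = fl$max_biomass,
         min_lactate = fl$min_lactate)
  })
  names(wt) <- names(models)

  if (is.null(reactions)) {
    m1 <- models[[1]]
    keep <- m1$reactions$id != m1$objective
    if (config$exclude_exchanges) keep <- keep & !m1$reactions$is_exchange
    reactions <- m1$reactions$id[keep]
  }
  reactions <- setdiff(reactions, vapply(models, `[[`, "", "objective"))

  # stages 1-2: deterministic LP quantities for every (reaction, line)
  records <- do.call(rbind, lapply(reactions, function(r) {
    do.call(rbind, lapply(wt, function(w) {
      km <- knockout_reaction(w$model, r)
      s <- solve_fba(km)
      g <- if (s$status == "optimal") s$objective_value else 0
      lac <- if (g > tol) {
        flux_extremum(km, w$cfg$lactate_export, "min",
                      fixed = stats::setNames(list(c(g, 1e-9)), km$objective))
      } else 0
      data.frame(reaction = r, line = w$line, wt_growth = w$growth,
                 ko_growth = g, growth_fraction = g / w$growth,
                 ko_min_lactate = lac, stringsAsFactors = FALSE)
    }))
  }))
  rownames(records) <- NULL

  agg <- function(x, all_lines) if (all_lines) all(x) else mean(x) > 0.5
  by_rxn <- split(records, records$reaction)[reactions]
  lactate_abolished <- vapply(by_rxn, function(d) all(d$ko_min_lactate <= tol), logical(1))
  growth_spared <- vapply(by_rxn, function(d) {
    ok <- d$growth_fraction > config$growth_fraction_threshold
    if (config$require_all_lines) all(ok)
    else mean(d$growth_fraction) > config$growth_fraction_threshold
  }, logical(1))
  stage1 <- reactions[lactate_abolished]
  stage2 <- reactions[lactate_abolished & growth_spared]

  # stage 3: sampled AFR for the remaining candidates only
  wt_afr <- NULL
  afr_frac <- stats::setNames(rep(NA_real_, length(reactions)), reactions)
  afr_pass <- stats::setNames(rep(FALSE, length(reactions)), reactions)
  if (length(stage2)) {
    wt_afr <- vapply(seq_along(wt), function(k) {
      w <- wt[[k]]
      fs <- sample_optimal_face(w$model, n = n_samples, seed = seed + k - 1L)
      compute_metrics(fs, w$model, config = w$cfg)$afr
    }, numeric(1))
    names(wt_afr) <- names(wt)
    for (r in stage2) {
      fr <- vapply(seq_along(wt), function(k) {
        w <- wt[[k]]
        km <- knockout_reaction(w$model, r)
        s <- solve_fba(km)
        if (s$status != "optimal" || s$objective_value <= tol) return(0)
        fs <- sample_optimal_face(km, n = n_samples, seed = seed + k - 1L)
        compute_metrics(fs, km, config = w$cfg)$afr / wt_afr[k]
      }, numeric(1))
      afr_frac[r] <- mean(fr)
      afr_pass[r] <- if (config$afr_mode == "all")
        all(fr < config$afr_fraction_threshold)
      else mean(fr) < config$afr_fraction_threshold
    }
  }
  stage3 <- stage2[afr_pass[stage2]]

  # optional normal-cohort growth sparing
  normal_spared <- stats::setNames(rep(NA, length(reactions)), reactions)
  if (!is.null(config$normal_cohort) && length(stage3)) {
    nm <- as_model_list(config$normal_cohort)
    nwt <- vapply(nm, function(m) solve_fba(m)$objective_value, numeric(1))
    for (r in stage3) {
      fr <- vapply(seq_along(nm), function(k) {
        s <- solve_fba(knockout_reaction(nm[[k]], r))
        (if (s$status == "optimal") s$objective_value else 0) / nwt[k]
      }, numeric(1))
      normal_spared[r] <- all(fr > config$growth_fraction_threshold)
    }
    stage3 <- stage3[normal_spared[stage3]]
  }

  summary <- data.frame(
    reaction = reactions,
    lactate_abolished = lactate_abolished,
    growth_spared = lactate_abolished & growth_spared,
    mean_afr_fraction = unname(afr_frac),
    afr_reduced = unname(afr_pass),
    normal_spared = unname(normal_spared),
    survives = reactions %in% stage3,
    stringsAsFactors = FALSE)

  structure(list(records = records, summary = summary,
                 stage1 = stage1, stage2 = stage2, survivors = stage3,
                 wt_afr = wt_afr, config = config),
            class = "warburg_screen")
}

#' @export
print.warburg_screen <- function(x, ...) {
  cat(sprintf("<warburg_screen> %d reactions tested: %d abolish lactate -> %d spare growth -> %d reduce AFR\n",
              nrow(x$summary), length(x$stage1), length(x$stage2), length(x$survivors)))
  if (length(x$survivors)) cat("  survivors:", paste(x$survivors, collapse = ", "), "\n")
  invisible(x)
}

#' Map surviving reactions to candidate target genes
#'
#' Collects the genes in the survivors' rules and annotates, per gene,
#' whether knocking it down alone suffices to close at least one of its
#' reactions (it sits in an AND position) or whether an isoenzyme backup
#' (OR sibling) keeps the reaction open.
#'
#' @param model a [flux_model()] (gene rules are read from it).
#' @param survivors surviving reaction ids.
#' @return data.frame: `gene`, `reactions` (";"-joined), `n_reactions`,
#'   `knockdown_sufficient`.
#' @export
map_targets_to_genes <- function(model, survivors) {
  i <- rxn_index(model, survivors)
  rows <- list()
  for (k in seq_along(survivors)) {
    ast <- parse_gene_rule(model$reactions$gene_rule[i[k]])
    if (is.null(ast)) {
      warning("surviving reaction ", survivors[k], " has no gene rule")
      next
    }
    for (g in rule_genes(ast)) {
      suff <- !eval_rule_knockout(ast, g)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, reaction = survivors[k], sufficient = suff,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(gene = character(0), reactions = character(0),
                      n_reactions = integer(0), knockdown_sufficient = logical(0)))
  long <- do.call(rbind, rows)
  out <- do.call(rbind, lapply(split(long, long$gene), function(d)
    data.frame(gene = d$gene[1], reactions = paste(sort(unique(d$reaction)), collapse = ";"),
               n_reactions = length(unique(d$reaction)),
               knockdown_sufficient = any(d$sufficient),
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out[order(-out$n_reactions, out$gene), ]
}

#' One-sided expression test of target genes against background
#'
#' Pools the expression of the target genes across all lines and compares
#' it against the pooled background-gene expression with a one-sided
#' Wilcoxon rank-sum test (alternative: targets higher).
#'
#' @param expression genes x lines matrix.
#' @param target_genes,background_genes disjoint, non-empty gene sets.
#' @return one-sided p-value.
#' @export
target_expression_test <- function(expression, target_genes, background_genes) {
  if (!length(target_genes) || !length(background_genes))
    stop("both gene sets must be non-empty", call. = FALSE)
  if (length(intersect(target_genes, background_genes)))
    stop("target and background gene sets overlap", call. = FALSE)
  missing <- setdiff(c(target_genes, background_genes), rownames(expression))
  if (length(missing)) stop("genes not in expression matrix: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  tv <- as.numeric(expression[target_genes, , drop = FALSE])
  bv <- as.numeric(expression[background_genes, , drop = FALSE])
  stats::wilcox.test(tv, bv, alternative = "greater", exact = FALSE)$p.value
}

#' Write screen outputs as TSV
#'
#' @param screen a [run_screen()] result.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_screen_tsv <- function(screen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(screen$records, file.path(dir, "screen_records.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(screen$summary, file.path(dir, "screen_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
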