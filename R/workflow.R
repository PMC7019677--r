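#' Stratum specification for subgroup re-analysis
#'
#' @param variable Metadata column to stratify on (default `"age"`).
#' @param cutpoint Numeric cutpoint (default 60 years). The younger/lower
#'   stratum is `variable < cutpoint`; the other is `variable >= cutpoint`,
#'   so the two strata partition the cohort.
#' @return A `stratum_spec`.
#' @export
stratum_spec <- function(variable = "age", cutpoint = 60) {
  structure(list(variable = variable, cutpoint = as.numeric(cutpoint)),
            class = "stratum_spec")
}

# shared per-stratum / overall analysis core
.analyze_block <- function(expr, groups, candidates, pairs, direction,
                           log2_transform, B, seed, case_label, verbose) {
  summaries <- summarize_genes(expr, groups,
                               genes = candidates, case_label = case_label)
  calls <- call_low_high(expr[c("sample_id", candidates)], summaries)
  call_counts <- low_call_counts(calls, groups)
  roc <- roc_table(expr, groups, markers = candidates, direction = direction,
                   B = B, seed = seed, case_label = case_label)
  greedy <- greedy_combine(expr, groups, candidates, direction = direction,
                           log2_transform = log2_transform,
                           case_label = case_label)
  panels <- evaluate_panels(greedy, B = B, seed = seed)
  pair_panels <- NULL
  if (!is.null(pairs)) {
    pair_panels <- evaluate_panels(
      fit_marker_sets(expr, groups, pairs, log2_transform = log2_transform,
                      case_label = case_label),
      B = B, seed = seed)
  }
  if (verbose) {
    message(sprintf("  analysed %d genes on %d samples; greedy sequence of %d panels",
                    length(candidates), nrow(expr), length(greedy$panels)))
  }
  list(gene_summaries = summaries, calls = calls, call_counts = call_counts,
       roc = roc, greedy = greedy, panels = panels, pair_panels = pair_panels)
}

# Drop genes that cannot be summarised (fewer than 2 non-missing values in
# either class); returns the usable gene set, messaging exclusions.
.usable_genes <- function(expr, groups, genes, control_label, case_label,
                          verbose) {
  grp <- as.character(groups)
  ok <- vapply(genes, function(g) {
    v <- expr[[g]]
    sum(!is.na(v[grp == control_label])) >= 2L &&
      sum(!is.na(v[grp == case_label])) >= 2L
  }, logical(1))
  if (any(!ok) && verbose) {
    message("excluding gene(s) with fewer than 2 values in a class: ",
            paste(genes[!ok], collapse = ", "))
  }
  genes[ok]
}

#' Run the full diagnostic-marker analysis pipeline
#'
#' Orchestrates quantify -> summarise -> call -> ROC -> panels (-> strata):
#' optional ddCt quantification of raw Ct input, per-gene group summaries
#' with fold changes and mean-minus-SD diagnostic cut-offs, low/high calls,
#' univariate ROC/AUC with bootstrap CIs and Youden operating points, the
#' greedy AUC-ordered logistic panel sequence (plus any explicitly requested
#' marker sets), and an age-stratified re-analysis in which cut-offs, ROC
#' and panels are recomputed within each stratum. Deterministic given
#' `seed`.
#'
#' @param x Input data: a `saliva_cohort`, a wide expression data.frame
#'   (`sample_id` + gene columns), or a long Ct data.frame (`sample_id`,
#'   `gene`, `replicate`, `ct`), which is first quantified with
#'   [quantify_table()].
#' @param metadata Data.frame with `sample_id`, `group` and any stratifying
#'   covariates; unneeded when `x` is a `saliva_cohort`.
#' @param reference_gene Housekeeping gene for Ct input (default `"GAPDH"`).
#' @param calibrator Calibrator policy for Ct input (default
#'   [calibrator_control_mean()]).
#' @param candidates Genes to analyse (default: all usable gene columns).
#' @param pairs Optional list of explicit marker sets to evaluate alongside
#'   the greedy sequence.
#' @param stratify_by A [stratum_spec()], or `NULL` to skip stratified
#'   re-analysis. Default: age at 60 years when an `age` column is present.
#' @param direction `"low"`: low expression indicates disease (default).
#' @param log2_transform Fit logistic panels on `log2` expression?
#' @param B Bootstrap replicates for AUC CIs (default 2000).
#' @param seed Master seed for all bootstrap resampling.
#' @param control_label,case_label Group labels.
#' @param verbose Emit one progress message per stage (default `TRUE`).
#' @return An `analysis_report`: `gene_summaries`, `calls`, `call_counts`,
#'   `roc`, `greedy`, `panels`, `pair_panels`, `strata` (named list of
#'   per-stratum blocks plus `n`), and `provenance` (`hash`, `seed`,
#'   `package_version`, `params`).
#' @examples
#' cohort <- simulate_cohort(table2_defaults(seed = 7))
#' report <- run_pipeline(cohort, B = 200, verbose = FALSE)
#' report$gene_summaries
#' @export
run_pipeline <- function(x, metadata = NULL, reference_gene = "GAPDH",
                         calibrator = calibrator_control_mean(),
                         candidates = NULL, pairs = NULL,
                         stratify_by = stratum_spec("age", 60),
                         direction = c("low", "high"),
                         log2_transform = FALSE,
                         B = 2000L, seed = 1L,
                         control_label = "control", case_label = "case",
                         verbose = TRUE) {
  direction <- match.arg(direction)

  if (inherits(x, "saliva_cohort")) {
    expr <- x$expression
    metadata <- metadata %||% x$metadata
  } else if (is.data.frame(x) &&
             all(c("sample_id", "gene", "replicate", "ct") %in% names(x))) {
    if (is.null(metadata)) {
      stop("`metadata` (sample_id, group) is required with Ct input",
           call. = FALSE)
    }
    if (verbose) message("quantifying Ct input (reference ", reference_gene, ")")
    expr <- quantify_table(x, reference_gene, calibrator, groups = metadata)
  } else if (is.data.frame(x)) {
    if (is.null(metadata)) {
      stop("`metadata` (sample_id, group) is required with expression input",
           call. = FALSE)
    }
    expr <- x
  } else {
    stop("unsupported input type for `x`", call. = FALSE)
  }

  metadata <- metadata[match(expr$sample_id, metadata$sample_id), , drop = FALSE]
  if (anyNA(metadata$sample_id)) {
    stop("every sample in the expression table must appear in `metadata`",
         call. = FALSE)
  }
  groups <- metadata$group
  grp_chr <- as.character(groups)
  if (!all(grp_chr %in% c(control_label, case_label))) {
    stop("`group` must be binary with labels '", control_label, "'/'",
         case_label, "'", call. = FALSE)
  }
  genes <- setdiff(names(expr), "sample_id")
  candidates <- candidates %||% genes
  candidates <- .usable_genes(expr, groups, candidates,
                              control_label, case_label, verbose)
  if (length(candidates) < 2L) {
    stop("fewer than 2 usable genes; nothing to analyse", call. = FALSE)
  }
  if (verbose) {
    message(sprintf("pipeline input: %d samples (%d %s, %d %s), %d genes",
                    nrow(expr), sum(grp_chr == control_label), control_label,
                    sum(grp_chr == case_label), case_label, length(candidates)))
  }

  overall <- .analyze_block(expr, groups, candidates, pairs, direction,
                            log2_transform, B, substream_seed(seed, "overall"),
                            case_label, verbose)

  strata <- NULL
  if (!is.null(stratify_by) && stratify_by$variable %in% names(metadata)) {
    strata <- stratified_analysis(expr, metadata, spec = stratify_by,
                                  candidates = candidates, pairs = pairs,
                                  direction = direction,
                                  log2_transform = log2_transform,
                                  B = B, seed = seed,
                                  control_label = control_label,
                                  case_label = case_label, verbose = verbose)
  }

  params <- list(reference_gene = reference_gene, direction = direction,
                 log2_transform = log2_transform, B = B,
                 candidates = candidates,
                 stratify_by = stratify_by, pairs = pairs)
  structure(
    c(overall,
      list(strata = strata,
           provenance = list(
             hash = provenance_hash(list(expr, metadata, params, seed)),
             seed = seed,
             package_version = as.character(utils::packageVersion("salivadx")),
             params = params))),
    class = "analysis_report"
  )
}

#' Stratified re-analysis of the marker pipeline
#'
#' Splits the cohort on a numeric metadata variable (default age at 60
#' years: `age < 60` vs `age >= 60`) and reruns summaries, calls, ROC and
#' panel building within each stratum. Diagnostic cut-offs are recomputed
#' from each stratum's own control subjects, so stratum cut-offs generally
#' differ from the overall ones. A stratum that is empty or retains only one
#' class is skipped with a warning.
#'
#' @inheritParams run_pipeline
#' @param spec A [stratum_spec()].
#' @return Named list (e.g. `"age<60"`, `"age>=60"`) of per-stratum analysis
#'   blocks (`n`, `gene_summaries`, `calls`, `call_counts`, `roc`, `greedy`,
#'   `panels`), skipped strata omitted.
#' @export
stratified_analysis <- function(x, metadata = NULL, spec = stratum_spec(),
                                candidates = NULL, pairs = NULL,
                                direction = c("low", "high"),
                                log2_transform = FALSE,
                                B = 2000L, seed = 1L,
                                control_label = "control",
                                case_label = "case", verbose = TRUE) {
  direction <- match.arg(direction)
  if (inherits(x, "saliva_cohort")) {
    metadata <- metadata %||% x$metadata
    expr <- x$expression
  } else {
    expr <- x
  }
  if (is.null(metadata) || !spec$variable %in% names(metadata)) {
    stop("stratifying variable '", spec$variable, "' not found in metadata",
         call. = FALSE)
  }
  v <- metadata[match(expr$sample_id, metadata$sample_id), spec$variable]
  if (!is.numeric(v)) {
    stop("stratifying variable '", spec$variable, "' must be numeric",
         call. = FALSE)
  }
  groups <- metadata$group[match(expr$sample_id, metadata$sample_id)]
  membership <- list(v < spec$cutpoint, v >= spec$cutpoint)
  names(membership) <- c(sprintf("%s<%g", spec$variable, spec$cutpoint),
                         sprintf("%s>=%g", spec$variable, spec$cutpoint))

  out <- list()
  for (nm in names(membership)) {
    idx <- membership[[nm]]
    grp <- as.character(groups[idx])
    if (!any(idx)) {
      warning("stratum ", nm, " is empty; skipped")
      next
    }
    if (length(unique(grp)) < 2L) {
      warning("stratum ", nm, " retains a single class; skipped")
      next
    }
    sub_expr <- expr[idx, , drop = FALSE]
    sub_groups <- groups[idx]
    cand <- .usable_genes(sub_expr, sub_groups,
                          candidates %||% setdiff(names(expr), "sample_id"),
                          control_label, case_label, verbose)
    if (length(cand) < 2L) {
      warning("stratum ", nm, " has fewer than 2 usable genes; skipped")
      next
    }
    if (verbose) message("stratum ", nm, ": n = ", sum(idx))
    block <- .analyze_block(sub_expr, sub_groups, cand, pairs, direction,
                            log2_transform, B, substream_seed(seed, nm),
                            case_label, verbose)
    out[[nm]] <- c(list(n = sum(idx)), block)
  }
  out
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("salivadx analysis report\n")
  cat("  genes:", paste(x$gene_summaries$gene, collapse = ", "), "\n")
  cat("  samples:", sum(x$gene_summaries$n_control[1],
                        x$gene_summaries$n_case[1]), "\n")
  cat("\nGene summaries (two-decimal report):\n")
  print(format_gene_summary(x$gene_summaries))
  cat("\nUnivariate ROC:\n")
  print(transform(x$roc, sensitivity = round(sensitivity, 2),
                  specificity = round(specificity, 2), auc = round(auc, 2),
                  ci_low = round(ci_low, 2), ci_high = round(ci_high, 2)))
  cat("\nGreedy panel sequence:\n")
  print(transform(x$panels, sensitivity = round(sensitivity, 2),
                  specificity = round(specificity, 2), auc = round(auc, 2),
                  ci_low = round(ci_low, 2), ci_high = round(ci_high, 2)))
  if (!is.null(x$strata)) {
    cat("\nStrata analysed:", paste(names(x$strata), collapse = ", "), "\n")
  }
  cat("\nprovenance hash:", x$provenance$hash,
      "| seed:", x$provenance$seed, "\n")
  invisible(x)
}

#' Write an analysis report to TSV/JSON files
#'
#' Emits `gene_summary.tsv`, `calls.tsv`, `roc.tsv`, `panels.tsv` (and
#' per-stratum variants), plus `provenance.json`.
#'
#' @param report An `analysis_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  wt(as.data.frame(report$gene_summaries), "gene_summary.tsv")
  wt(as.data.frame(report$calls), "calls.tsv")
  wt(report$roc, "roc.tsv")
  wt(report$panels, "panels.tsv")
  if (!is.null(report$pair_panels)) wt(report$pair_panels, "pair_panels.tsv")
  for (nm in names(report$strata)) {
    tag <- gsub("[^A-Za-z0-9]+", "_",
                gsub(">=", "_ge_", gsub("<", "_lt_", nm, fixed = TRUE),
                     fixed = TRUE))
    s <- report$strata[[nm]]
    wt(as.data.frame(s$gene_summaries), paste0("gene_summary_", tag, ".tsv"))
    wt(s$roc, paste0("roc_", tag, ".tsv"))
    wt(s$panels, paste0("panels_", tag, ".tsv"))
  }
  jsonlite::write_json(report$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
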