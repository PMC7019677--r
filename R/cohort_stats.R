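#' Per-gene group summary with fold change and diagnostic cut-off
#'
#' For each gene: control/case means and sample SDs (n-1 denominator), the
#' fold change (case mean / control mean), a two-sided rank-sum p-value, and
#' the diagnostic cut-off `control mean - control SD` under which a sample is
#' called "low level" (cancer). Computation is at full precision; use
#' [format_gene_summary()] for two-decimal reporting.
#'
#' @param x A `saliva_cohort` or a wide expression data.frame (`sample_id`
#'   plus gene columns).
#' @param groups Group labels (vector aligned with rows of the expression
#'   table); taken from the cohort metadata when `x` is a `saliva_cohort`.
#' @param genes Genes to summarise (default: all gene columns).
#' @param control_label,case_label Labels identifying the two groups.
#' @return A `gene_summary` data.frame with one row per gene: `gene`,
#'   `n_control`, `n_case`, `control_mean`, `control_sd`, `case_mean`,
#'   `case_sd`, `fold_change`, `p_value`, `cutoff`.
#' @export
summarize_genes <- function(x, groups = NULL, genes = NULL,
                            control_label = "control", case_label = "case") {
  rx <- resolve_expression(x, groups)
  expr <- rx$expression
  groups <- rx$groups
  genes <- genes %||% rx$genes
  if (is.null(groups)) stop("`groups` is required", call. = FALSE)
  grp <- as.character(groups)

  rows <- lapply(genes, function(g) {
    if (!g %in% names(expr)) stop("gene '", g, "' not in expression table",
                                  call. = FALSE)
    xc <- expr[[g]][grp == control_label]
    xk <- expr[[g]][grp == case_label]
    xc <- xc[!is.na(xc)]; xk <- xk[!is.na(xk)]
    if (length(xc) < 2L) {
      stop("gene '", g, "': fewer than 2 non-missing values in group '",
           control_label, "'", call. = FALSE)
    }
    if (length(xk) < 2L) {
      stop("gene '", g, "': fewer than 2 non-missing values in group '",
           case_label, "'", call. = FALSE)
    }
    mc <- mean(xc); mk <- mean(xk)
    data.frame(
      gene = g, n_control = length(xc), n_case = length(xk),
      control_mean = mc, control_sd = stats::sd(xc),
      case_mean = mk, case_sd = stats::sd(xk),
      fold_change = mk / mc,
      p_value = rank_sum_test(xc, xk)$p_value,
      cutoff = mc - stats::sd(xc),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("gene_summary", "data.frame")
  out
}

#' @rdname summarize_genes
#' @param gene A single gene name.
#' @export
group_summary <- function(x, groups = NULL, gene,
                          control_label = "control", case_label = "case") {
  summarize_genes(x, groups, genes = gene,
                  control_label = control_label, case_label = case_label)
}

#' Format a gene summary for reporting
#'
#' Two-decimal "mean +/- SD" presentation mirroring how such panels are
#' published; the underlying [summarize_genes()] values stay full precision.
#'
#' @param summaries A `gene_summary`.
#' @param digits Decimal places (default 2).
#' @return A character data.frame.
#' @export
format_gene_summary <- function(summaries, digits = 2) {
  f <- function(v) formatC(v, format = "f", digits = digits)
  data.frame(
    gene = summaries$gene,
    control = paste0(f(summaries$control_mean), " ± ", f(summaries$control_sd)),
    case = paste0(f(summaries$case_mean), " ± ", f(summaries$case_sd)),
    fold_change = f(summaries$fold_change),
    p_value = format.pval(summaries$p_value, digits = 2),
    cutoff = paste("below", f(summaries$cutoff)),
    stringsAsFactors = FALSE
  )
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact enumeration when the combined sample size is at most 12 and there
#' are no ties; otherwise the normal approximation with tie correction and
#' continuity correction. If every value in both samples is identical the
#' test is degenerate and `p = 1` is returned with a warning.
#'
#' @param x,y Numeric vectors (each non-empty).
#' @return List with `statistic` (Mann-Whitney W), `p_value`, and `method`
#'   (`"exact"` or `"normal_approx"`).
#' @export
rank_sum_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must contain at least one value", call. = FALSE)
  }
  all_vals <- c(x, y)
  if (all(all_vals == all_vals[1])) {
    warning("all values identical across both samples; rank-sum test is degenerate")
    return(list(statistic = length(x) * length(y) / 2, p_value = 1,
                method = "degenerate"))
  }
  ties <- anyDuplicated(all_vals) > 0L
  exact <- (length(x) + length(y) <= 12L) && !ties
  res <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  )
  list(statistic = unname(res$statistic),
       p_value = min(res$p.value, 1),
       method = if (exact) "exact" else "normal_approx")
}

#' Shapiro-Wilk normality test
#'
#' Used for reporting which distributional branch the data support; the
#' pipeline's group comparisons always use the rank-sum test regardless,
#' since salivary relative-expression values are right-skewed.
#'
#' @param values Numeric vector, 3 <= n <= 5000 after removing `NA`.
#' @return List with `statistic` (W) and `p_value`.
#' @export
normality_test <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3L || n > 5000L) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000 (got n = ", n, ")", call. = FALSE)
  }
  res <- stats::shapiro.test(values)
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

#' Call samples low/high against per-gene diagnostic cut-offs
#'
#' A sample is called `low` (suggestive of cancer) for a gene when its
#' relative expression is strictly below that gene's cut-off (control mean
#' minus control SD); values equal to the cut-off are `high`. Ties at the
#' boundary are measure-zero on continuous data, so the strict reading of
#' "below" is used.
#'
#' @param x A `saliva_cohort` or wide expression data.frame.
#' @param summaries A `gene_summary` covering every gene to call (e.g. from
#'   [summarize_genes()]).
#' @return A `call_matrix` data.frame (`sample_id` plus one factor column per
#'   gene with levels `low`, `high`), with the per-gene cut-offs in the
#'   `cutoffs` attribute.
#' @export
call_low_high <- function(x, summaries) {
  rx <- resolve_expression(x)
  expr <- rx$expression
  genes <- intersect(rx$genes, summaries$gene)
  missing_g <- setdiff(rx$genes, summaries$gene)
  if (length(missing_g)) {
    stop("no cut-off available for gene(s): ",
         paste(missing_g, collapse = ", "), call. = FALSE)
  }
  cutoffs <- stats::setNames(summaries$cutoff, summaries$gene)[genes]
  out <- data.frame(sample_id = expr$sample_id, stringsAsFactors = FALSE)
  for (g in genes) {
    out[[g]] <- factor(ifelse(expr[[g]] < cutoffs[[g]], "low", "high"),
                       levels = c("low", "high"))
  }
  structure(out, cutoffs = cutoffs, class = c("call_matrix", "data.frame"))
}

#' Count low calls per gene and group
#'
#' @param calls A `call_matrix` from [call_low_high()].
#' @param groups Group labels aligned with the call matrix rows.
#' @return Data.frame: `gene`, one count column per group level, `n_low`.
#' @export
low_call_counts <- function(calls, groups) {
  genes <- setdiff(names(calls), "sample_id")
  grp <- factor(groups)
  rows <- lapply(genes, function(g) {
    low <- calls[[g]] == "low"
    counts <- tapply(low, grp, sum)
    cbind(data.frame(gene = g, stringsAsFactors = FALSE),
          as.data.frame(as.list(counts)),
          data.frame(n_low = sum(low)))
  })
  do.call(rbind, rows)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Uncorrected by default (`correct = FALSE`): the continuity-corrected
#' variant is available via `correct = TRUE` but the package's cohort-balance
#' tables use the plain Pearson statistic.
#'
#' @param table 2x2 matrix of non-negative integer counts with non-zero
#'   margins.
#' @param correct Apply Yates continuity correction? Default `FALSE`.
#' @return List with `statistic` (chi-square), `df`, `p_value`.
#' @export
contingency_test <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) {
    stop("`table` must be a 2x2 matrix of counts", call. = FALSE)
  }
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("every row and column margin must be non-zero", call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(table, correct = correct))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value)
}
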