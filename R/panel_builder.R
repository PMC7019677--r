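#' Fit a logistic risk score over a marker panel
#'
#' Maximum-likelihood logistic regression of case status on the panel's
#' relative-expression values (intercept included; convergence when the
#' log-likelihood change falls below 1e-8, at most 100 iterations). The
#' per-sample risk score is the linear predictor, and the panel AUC is the
#' empirical AUC of that score with high risk indicating disease. Complete or
#' quasi-complete separation is flagged with a warning and the final-iterate
#' coefficients are reported — the risk score's ranking, and hence its AUC,
#' remains well-defined.
#'
#' @param x A `saliva_cohort` or wide expression data.frame.
#' @param groups Class labels (from cohort metadata when omitted).
#' @param markers Character vector of marker columns entering the model.
#' @param log2_transform Model `log2(expression)` instead of the raw scale?
#'   Default `FALSE`.
#' @param ridge Ridge penalty (glmnet `lambda`, `alpha = 0`); default 0 =
#'   plain maximum likelihood. Useful for separation-prone small panels.
#' @param case_label Label identifying diseased samples.
#' @return A `panel_model`: `markers`, `coefficients` (named, log-odds
#'   units), `risk_scores` (named by sample id), `auc`, `separation`,
#'   `converged`, `is_case`, `step`.
#' @export
fit_risk_score <- function(x, groups = NULL, markers,
                           log2_transform = FALSE, ridge = 0,
                           case_label = "case") {
  rx <- resolve_expression(x, groups)
  expr <- rx$expression
  is_case <- as_case_labels(rx$groups, case_label)
  if (sum(is_case) < 2L || sum(!is_case) < 2L) {
    stop("need at least 2 samples per class", call. = FALSE)
  }
  missing_m <- setdiff(markers, names(expr))
  if (length(missing_m)) {
    stop("marker(s) not in expression table: ",
         paste(missing_m, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(expr[markers])
  if (anyNA(X)) {
    keep <- stats::complete.cases(X)
    message("dropping ", sum(!keep), " sample(s) with missing marker values")
    X <- X[keep, , drop = FALSE]
    is_case <- is_case[keep]
    expr <- expr[keep, , drop = FALSE]
  }
  const <- apply(X, 2, function(v) max(v) == min(v))
  if (any(const)) {
    stop("constant-valued marker(s): ",
         paste(markers[const], collapse = ", "), call. = FALSE)
  }
  if (log2_transform) X <- log2(X)

  if (ridge > 0) {
    if (!requireNamespace("glmnet", quietly = TRUE)) {
      stop("`ridge > 0` requires the glmnet package", call. = FALSE)
    }
    # ridge needs >= 2 columns in glmnet; duplicate-column trick not needed
    # for the panels this package builds (>= 2 markers when ridge is useful)
    fit <- glmnet::glmnet(X, as.integer(is_case), family = "binomial",
                          alpha = 0, lambda = ridge, standardize = FALSE)
    beta <- as.numeric(stats::coef(fit))
    names(beta) <- c("(Intercept)", markers)
    eta <- drop(cbind(1, X) %*% beta)
    separation <- FALSE
    converged <- TRUE
  } else {
    dat <- data.frame(.y = as.integer(is_case), X, check.names = FALSE)
    fml <- stats::reformulate(sprintf("`%s`", markers), response = ".y")
    separation <- FALSE
    fit <- withCallingHandlers(
      stats::glm(fml, family = stats::binomial(), data = dat,
                 control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
          separation <<- TRUE
          invokeRestart("muffleWarning")
        }
      }
    )
    converged <- fit$converged
    beta <- stats::coef(fit)
    names(beta) <- c("(Intercept)", markers)
    eta <- unname(stats::predict(fit, type = "link"))
    if (separation || !converged) {
      warning("possible complete or quasi-complete separation for panel ",
              paste(markers, collapse = " + "),
              "; coefficients taken from the final iterate")
    }
  }
  structure(
    list(markers = markers, coefficients = beta,
         risk_scores = stats::setNames(eta, expr$sample_id),
         auc = .auc_oriented(eta, is_case),
         separation = separation, converged = converged,
         is_case = is_case, log2_transform = log2_transform,
         step = NA_integer_),
    class = "panel_model"
  )
}

#' @export
print.panel_model <- function(x, ...) {
  cat("Logistic risk-score panel:", paste(x$markers, collapse = " + "), "\n")
  cat(sprintf("  n = %d (%d cases); in-sample AUC = %.3f%s\n",
              length(x$risk_scores), sum(x$is_case), x$auc,
              if (x$separation) " [separation flagged]" else ""))
  print(round(x$coefficients, 4))
  invisible(x)
}

# Standardised effect size used only to break univariate-AUC ties:
# |case mean - control mean| / pooled SD.
.std_effect <- function(values, is_case) {
  x1 <- values[is_case]; x0 <- values[!is_case]
  sp <- sqrt(((length(x0) - 1) * stats::var(x0) +
                (length(x1) - 1) * stats::var(x1)) /
               (length(x0) + length(x1) - 2))
  if (sp == 0) return(0)
  abs(mean(x1) - mean(x0)) / sp
}

#' Greedy AUC-ordered logistic marker combination
#'
#' The panel-combination algorithm: compute each candidate's univariate
#' empirical AUC; order candidates from largest to smallest AUC; combine the
#' first two into a logistic risk score; then repeatedly add the next-ranked
#' candidate and rebuild the risk score, until all candidates are included.
#' All intermediate panels are returned with their in-sample AUCs. The
#' ordering is recomputed internally, so the output is invariant to the
#' order in which candidates are supplied. Univariate-AUC ties are broken by
#' larger standardised effect size, then by gene name, and reported via a
#' message.
#'
#' @inheritParams fit_risk_score
#' @param candidates Candidate marker names (default: all gene columns;
#'   at least 2).
#' @param direction Orientation for the univariate AUC ranking (`"low"`:
#'   low expression indicates disease, the default for these markers).
#' @param method `"refit"` (default): each step refits the enlarged logistic
#'   model jointly. `"frozen"`: each step fits only (previous risk score,
#'   new marker), keeping earlier coefficients frozen inside the score.
#' @return A `greedy_panels`: list with `ranking` (data.frame `gene`, `auc`,
#'   `effect_size`, `rank`), `panels` (list of `panel_model`, sizes 2..K,
#'   `step` = 1..K-1), `method`, `direction`.
#' @export
greedy_combine <- function(x, groups = NULL, candidates = NULL,
                           direction = c("low", "high"),
                           method = c("refit", "frozen"),
                           log2_transform = FALSE, case_label = "case") {
  direction <- match.arg(direction)
  method <- match.arg(method)
  rx <- resolve_expression(x, groups)
  candidates <- candidates %||% rx$genes
  if (length(candidates) < 2L) {
    stop("need at least 2 candidate markers", call. = FALSE)
  }
  is_case <- as_case_labels(rx$groups, case_label)

  aucs <- vapply(candidates, function(g)
    .auc_oriented(.orient(rx$expression[[g]], direction), is_case), numeric(1))
  effects <- vapply(candidates, function(g)
    .std_effect(rx$expression[[g]], is_case), numeric(1))
  if (anyDuplicated(aucs)) {
    message("univariate AUC ties broken by standardised effect size, then gene name")
  }
  ord <- order(-aucs, -effects, candidates)
  ranked <- candidates[ord]
  ranking <- data.frame(gene = ranked, auc = aucs[ord],
                        effect_size = effects[ord],
                        rank = seq_along(ranked), stringsAsFactors = FALSE)

  panels <- vector("list", length(ranked) - 1L)
  if (method == "refit") {
    for (k in 2:length(ranked)) {
      pm <- fit_risk_score(rx$expression, rx$groups, ranked[seq_len(k)],
                           log2_transform = log2_transform,
                           case_label = case_label)
      pm$step <- k - 1L
      panels[[k - 1L]] <- pm
    }
  } else {
    pm <- fit_risk_score(rx$expression, rx$groups, ranked[1:2],
                         log2_transform = log2_transform,
                         case_label = case_label)
    pm$step <- 1L
    panels[[1L]] <- pm
    score <- unname(pm$risk_scores)
    for (k in 3:max(3L, length(ranked))) {
      if (k > length(ranked)) break
      newx <- rx$expression[[ranked[k]]]
      if (log2_transform) newx <- log2(newx)
      dat <- data.frame(.y = as.integer(is_case), score = score, newx = newx)
      sep <- FALSE
      fit <- withCallingHandlers(
        stats::glm(.y ~ score + newx, stats::binomial(), dat,
                   control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
        warning = function(w) {
          if (grepl("fitted probabilities numerically 0 or 1",
                    conditionMessage(w))) {
            sep <<- TRUE; invokeRestart("muffleWarning")
          }
        }
      )
      score <- unname(stats::predict(fit, type = "link"))
      panels[[k - 1L]] <- structure(
        list(markers = ranked[seq_len(k)],
             coefficients = stats::coef(fit),
             risk_scores = stats::setNames(score, rx$expression$sample_id),
             auc = .auc_oriented(score, is_case),
             separation = sep, converged = fit$converged,
             is_case = is_case, log2_transform = log2_transform,
             step = k - 1L),
        class = "panel_model")
    }
  }
  structure(list(ranking = ranking, panels = panels,
                 method = method, direction = direction),
            class = "greedy_panels")
}

#' @export
print.greedy_panels <- function(x, ...) {
  cat("Greedy AUC-ordered panel sequence (", x$method, " coefficients)\n", sep = "")
  cat("Univariate ranking:\n")
  print(transform(x$ranking, auc = round(auc, 3),
                  effect_size = round(effect_size, 3)))
  cat("Panels:\n")
  for (pm in x$panels) {
    cat(sprintf("  step %d: %s  (AUC %.3f)\n", pm$step,
                paste(pm$markers, collapse = " + "), pm$auc))
  }
  invisible(x)
}

#' Fit an explicit list of marker pairs (or larger sets)
#'
#' Convenience wrapper when specific combinations are of interest
#' (e.g. `list(c("CYP27A1", "SIAE"), c("MAOB", "NAB2"))`) rather than the
#' greedy sequence.
#'
#' @inheritParams fit_risk_score
#' @param sets List of character vectors of marker names.
#' @return Named list of `panel_model` objects (names like
#'   `"CYP27A1 + SIAE"`).
#' @export
fit_marker_sets <- function(x, groups = NULL, sets,
                            log2_transform = FALSE, case_label = "case") {
  out <- lapply(sets, function(m)
    fit_risk_score(x, groups, m, log2_transform = log2_transform,
                   case_label = case_label))
  names(out) <- vapply(sets, paste, character(1), collapse = " + ")
  out
}

#' Evaluate fitted panels: ROC, AUC, CI, operating point
#'
#' In-sample evaluation of each panel's risk score (apparent performance,
#' matching how such panels are usually first reported). Sensitivity and
#' specificity come from the Youden-optimal threshold on the risk score;
#' the 95% CI from the stratified percentile bootstrap.
#'
#' @param panels A `greedy_panels`, a list of `panel_model`s, or a single
#'   `panel_model`.
#' @param B Bootstrap replicates for [auc_ci()].
#' @param seed Master seed; each panel gets a deterministic substream.
#' @return A data.frame: `panel`, `n_markers`, `sensitivity`, `specificity`,
#'   `auc`, `ci_low`, `ci_high`, `separation`.
#' @export
evaluate_panels <- function(panels, B = 2000L, seed = 1L) {
  if (inherits(panels, "greedy_panels")) panels <- panels$panels
  if (inherits(panels, "panel_model")) panels <- list(panels)
  rows <- lapply(panels, function(pm) {
    nm <- paste(pm$markers, collapse = " + ")
    r <- empirical_roc(unname(pm$risk_scores), pm$is_case,
                       direction = "high", case_label = NA, name = nm)
    yp <- youden_point(r)
    ci <- auc_ci(unname(pm$risk_scores), pm$is_case, direction = "high",
                 B = B, seed = substream_seed(seed, "panel_ci", nm))
    data.frame(panel = nm, n_markers = length(pm$markers),
               sensitivity = yp$sensitivity, specificity = yp$specificity,
               auc = r$auc, ci_low = ci$ci_low, ci_high = ci$ci_high,
               separation = pm$separation, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
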