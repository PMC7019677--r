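# Empirical ROC machinery.
#
# Scores are oriented internally so that larger oriented scores indicate
# disease; `direction = "low"` (the package default for these markers, whose
# expression falls in cancer) negates the score. Thresholds are midpoints
# between consecutive distinct scores, with +/-Inf sentinels; tied scores
# collapse onto a single ROC point, which gives the trapezoidal area the
# standard half-credit for ties.

# ROC coordinates from oriented scores. Returns fpr/tpr including the (0,0)
# origin, plus thresholds on the oriented scale.
.roc_points <- function(oriented, is_case) {
  n1 <- sum(is_case); n0 <- sum(!is_case)
  ord <- order(oriented, decreasing = TRUE)
  os <- oriented[ord]
  y <- is_case[ord]
  last <- c(os[-1L] != os[-length(os)], TRUE)  # last index of each tie group
  tp <- cumsum(y)[last]
  fp <- cumsum(!y)[last]
  u <- os[last]
  k <- length(u)
  mid <- if (k > 1L) (u[-k] + u[-1L]) / 2 else numeric(0)
  list(fpr = c(0, fp / n0), tpr = c(0, tp / n1),
       threshold = c(Inf, mid, -Inf)[seq_len(k + 1L)])
}

.trapezoid <- function(fpr, tpr) {
  sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
}

.auc_oriented <- function(oriented, is_case) {
  pts <- .roc_points(oriented, is_case)
  .trapezoid(pts$fpr, pts$tpr)
}

.orient <- function(scores, direction) {
  if (direction == "low") -scores else scores
}

.check_scores <- function(scores, labels, case_label) {
  is_case <- as_case_labels(labels, case_label)
  ok <- !is.na(scores)
  if (!all(ok)) {
    message("dropping ", sum(!ok), " sample(s) with missing scores")
    scores <- scores[ok]; is_case <- is_case[ok]
  }
  if (!any(is_case) || all(is_case)) {
    stop("both classes must remain after removing missing scores", call. = FALSE)
  }
  list(scores = scores, is_case = is_case)
}

#' Empirical ROC curve
#'
#' One point per distinct score threshold (ties grouped), plus the (0,0) and
#' (1,1) endpoints. With `direction = "low"`, lower scores indicate disease
#' and a sample is called positive when its score is *below* the reported
#' threshold; with `"high"`, above.
#'
#' @param scores Numeric marker values or risk scores.
#' @param labels Class labels (see `case_label`); both classes required.
#' @param direction `"low"` if low scores indicate disease (default, the
#'   orientation of down-regulated salivary markers) or `"high"`.
#' @param case_label Label identifying diseased samples (default `"case"`).
#' @param name Optional marker/panel name carried into the result.
#' @return A `roc_result`: list with `points` (data.frame `threshold`
#'   (original score scale), `fpr`, `sensitivity`, `specificity`), `auc`,
#'   `direction`, `n_control`, `n_case`, `name`.
#' @export
empirical_roc <- function(scores, labels, direction = c("low", "high"),
                          case_label = "case", name = NULL) {
  direction <- match.arg(direction)
  cs <- .check_scores(scores, labels, case_label)
  pts <- .roc_points(.orient(cs$scores, direction), cs$is_case)
  thr <- if (direction == "low") -pts$threshold else pts$threshold
  points <- data.frame(threshold = thr, fpr = pts$fpr,
                       sensitivity = pts$tpr, specificity = 1 - pts$fpr)
  structure(
    list(points = points, auc = .trapezoid(pts$fpr, pts$tpr),
         direction = direction, n_control = sum(!cs$is_case),
         n_case = sum(cs$is_case), name = name),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat("Empirical ROC", if (!is.null(x$name)) paste0("for ", x$name), "\n")
  cat(sprintf("  %d controls, %d cases; direction: %s scores indicate disease\n",
              x$n_control, x$n_case, x$direction))
  cat(sprintf("  AUC = %.3f (%d curve points)\n", x$auc, nrow(x$points)))
  invisible(x)
}

#' Area under the empirical ROC curve
#'
#' Trapezoidal area of [empirical_roc()]; numerically identical to the
#' Mann-Whitney probability that a random case/control pair is correctly
#' ordered, with half credit for ties.
#'
#' @inheritParams empirical_roc
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels, direction = c("low", "high"),
                case_label = "case") {
  direction <- match.arg(direction)
  cs <- .check_scores(scores, labels, case_label)
  .auc_oriented(.orient(cs$scores, direction), cs$is_case)
}

#' Youden-optimal operating point
#'
#' Maximises Youden's J = sensitivity + specificity - 1 over the empirical
#' curve. Ties in J are broken toward higher sensitivity, then toward the
#' lower threshold.
#'
#' @param roc A `roc_result`.
#' @return List with `sensitivity`, `specificity`, `threshold`, `j`.
#' @export
youden_point <- function(roc) {
  if (!inherits(roc, "roc_result")) {
    stop("`roc` must be an empirical_roc() result", call. = FALSE)
  }
  p <- roc$points
  j <- p$sensitivity + p$specificity - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[p$sensitivity[best] >= max(p$sensitivity[best]) - 1e-12]
  best <- best[which.min(p$threshold[best])]
  list(sensitivity = p$sensitivity[best], specificity = p$specificity[best],
       threshold = p$threshold[best], j = j[best])
}

#' Stratified percentile bootstrap confidence interval for the AUC
#'
#' Resamples cases and controls independently with replacement (so no
#' resample can lose a class), recomputes the empirical AUC, and takes
#' percentile quantiles. Seeded and reproducible; the caller's RNG state is
#' left untouched.
#'
#' @inheritParams empirical_roc
#' @param B Bootstrap replicates (at least 100; default 2000).
#' @param seed Integer seed (default 1).
#' @param level Confidence level (default 0.95).
#' @return List with `ci_low`, `ci_high`, `auc` (point estimate), `B`,
#'   `level`.
#' @export
auc_ci <- function(scores, labels, direction = c("low", "high"),
                   B = 2000L, seed = 1L, level = 0.95,
                   case_label = "case") {
  direction <- match.arg(direction)
  if (B < 100L) stop("`B` must be at least 100", call. = FALSE)
  cs <- .check_scores(scores, labels, case_label)
  if (sum(cs$is_case) < 2L || sum(!cs$is_case) < 2L) {
    stop("need at least 2 samples per class for the bootstrap", call. = FALSE)
  }
  o <- .orient(cs$scores, direction)
  i1 <- which(cs$is_case); i0 <- which(!cs$is_case)
  point <- .auc_oriented(o, cs$is_case)
  aucs <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- c(sample(i0, length(i0), replace = TRUE),
               sample(i1, length(i1), replace = TRUE))
      .auc_oriented(o[idx], cs$is_case[idx])
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  q <- stats::quantile(aucs, c(alpha, 1 - alpha), names = FALSE)
  list(ci_low = q[1], ci_high = q[2], auc = point, B = B, level = level)
}

#' Univariate ROC performance table
#'
#' One row per marker: AUC, bootstrap 95% CI and the Youden operating
#' point's sensitivity/specificity — the shape in which single-marker
#' diagnostic performance is usually tabulated.
#'
#' @param x A `saliva_cohort` or wide expression data.frame.
#' @param groups Group labels (from cohort metadata when omitted).
#' @param markers Marker columns to evaluate (default: all genes).
#' @inheritParams auc_ci
#' @return A data.frame: `marker`, `sensitivity`, `specificity`, `auc`,
#'   `ci_low`, `ci_high`, `direction`.
#' @export
roc_table <- function(x, groups = NULL, markers = NULL,
                      direction = c("low", "high"), B = 2000L, seed = 1L,
                      case_label = "case") {
  direction <- match.arg(direction)
  rx <- resolve_expression(x, groups)
  markers <- markers %||% rx$genes
  rows <- lapply(markers, function(g) {
    sc <- rx$expression[[g]]
    r <- empirical_roc(sc, rx$groups, direction, case_label, name = g)
    yp <- youden_point(r)
    ci <- auc_ci(sc, rx$groups, direction, B = B,
                 seed = substream_seed(seed, "roc_ci", g),
                 case_label = case_label)
    data.frame(marker = g, sensitivity = yp$sensitivity,
               specificity = yp$specificity, auc = r$auc,
               ci_low = ci$ci_low, ci_high = ci$ci_high,
               direction = direction, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
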