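# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: AUC by brute-force pairwise counting, exact
# rank-sum p by exhaustive enumeration, and the greedy combination loop
# re-implemented from the algorithm statement.

# Mann-Whitney probability by O(n^2) pairwise counting with half credit for
# ties, after orienting scores so larger values indicate disease.
oracle_auc <- function(scores, is_case, direction = "low") {
  o <- if (direction == "low") -scores else scores
  case <- o[is_case]
  ctrl <- o[!is_case]
  cmp <- outer(case, ctrl, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Exact two-sided Wilcoxon rank-sum p-value by enumerating every assignment
# of the pooled observations to the x-sample (tie-free data only). Two-sided
# p follows the doubled one-tail convention, capped at 1.
oracle_ranksum_exact <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  nx <- length(x)
  u_of <- function(xs, ys) sum(outer(xs, ys, ">"))
  u_obs <- u_of(x, y)
  idx <- utils::combn(n, nx)
  us <- apply(idx, 2, function(i) u_of(pooled[i], pooled[-i]))
  p_lo <- mean(us <= u_obs)
  p_hi <- mean(us >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# The greedy combination loop, re-implemented independently: rank candidates
# by pairwise-count AUC (ties: larger |standardised effect|, then name),
# then refit the logistic model on the top-k set at each step and score the
# linear predictor by pairwise counting.
oracle_greedy <- function(expr, is_case, direction = "low") {
  genes <- setdiff(names(expr), "sample_id")
  aucs <- vapply(genes, function(g) oracle_auc(expr[[g]], is_case, direction),
                 numeric(1))
  eff <- vapply(genes, function(g) {
    x1 <- expr[[g]][is_case]; x0 <- expr[[g]][!is_case]
    sp <- sqrt(((length(x0) - 1) * var(x0) + (length(x1) - 1) * var(x1)) /
                 (length(x0) + length(x1) - 2))
    abs(mean(x1) - mean(x0)) / sp
  }, numeric(1))
  ranked <- genes[order(-aucs, -eff, genes)]
  steps <- lapply(2:length(ranked), function(k) {
    X <- as.matrix(expr[ranked[seq_len(k)]])
    fit <- suppressWarnings(glm.fit(cbind(1, X), as.integer(is_case),
                                    family = binomial(),
                                    control = glm.control(epsilon = 1e-8,
                                                          maxit = 100)))
    eta <- drop(cbind(1, X) %*% fit$coefficients)
    list(markers = ranked[seq_len(k)],
         auc = oracle_auc(eta, is_case, direction = "high"))
  })
  list(ranking = ranked, steps = steps)
}

# A small cohort with tunable separation, for quick fixtures.
make_binormal <- function(n0, n1, delta, seed) {
  set.seed(seed)
  list(scores = c(rnorm(n0, 0, 1), rnorm(n1, delta, 1)),
       is_case = rep(c(FALSE, TRUE), c(n0, n1)))
}

# Exact two-point samples realising a given mean and sample SD (n = 2).
two_point <- function(mean, sd) mean + c(-1, 1) * sd / sqrt(2)

# Wide expression table whose per-group sample moments equal the supplied
# values exactly (two samples per group).
moment_exact_expression <- function(genes, control_mean, control_sd,
                                    case_mean, case_sd) {
  expr <- data.frame(sample_id = c("c1", "c2", "k1", "k2"),
                     stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    expr[[genes[i]]] <- c(two_point(control_mean[i], control_sd[i]),
                          two_point(case_mean[i], case_sd[i]))
  }
  expr
}

moment_groups <- c("control", "control", "case", "case")
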