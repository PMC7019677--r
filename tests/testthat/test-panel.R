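test_that("an uninformative marker gets a near-zero coefficient and AUC near 0.5", {
  set.seed(61)
  n <- 2000
  expr <- data.frame(sample_id = paste0("s", 1:(2 * n)), G = rnorm(2 * n, 5, 1))
  groups <- rep(c("control", "case"), each = n)
  pm <- fit_risk_score(expr, groups, "G")
  expect_lt(abs(pm$coefficients[["G"]]), 0.1)
  expect_lt(abs(pm$auc - 0.5), 0.03)
})

test_that("a single-marker risk score has the marker's own AUC", {
  cohort <- simulate_cohort(table2_defaults(seed = 44))
  for (g in c("SIAE", "MAOB")) {
    pm <- suppressWarnings(fit_risk_score(cohort, markers = g))
    uni <- auc(cohort$expression[[g]], cohort$metadata$group, "low")
    expect_equal(pm$auc, max(uni, 1 - uni), tolerance = 1e-12)
  }
})

test_that("logistic coefficients are recovered within 10% at n = 5000", {
  set.seed(73)
  n <- 5000
  x1 <- rnorm(n); x2 <- rnorm(n)
  truth <- c(`(Intercept)` = -0.8, m1 = 0.9, m2 = -0.6)
  eta <- truth[1] + truth[2] * x1 + truth[3] * x2
  y <- rbinom(n, 1, plogis(eta))
  expr <- data.frame(sample_id = paste0("s", 1:n), m1 = x1, m2 = x2)
  pm <- fit_risk_score(expr, ifelse(y == 1, "case", "control"), c("m1", "m2"))
  expect_true(all(abs(pm$coefficients / truth - 1) < 0.10))
})

test_that("constant markers and missing markers are input errors", {
  expr <- data.frame(sample_id = paste0("s", 1:8),
                     A = rep(1, 8), B = rnorm(8))
  groups <- rep(c("control", "case"), 4)
  expect_error(fit_risk_score(expr, groups, "A"), "constant")
  expect_error(fit_risk_score(expr, groups, "ZZ"), "not in expression")
})

test_that("complete separation is flagged but still yields a usable risk score", {
  expr <- data.frame(sample_id = paste0("s", 1:10),
                     G = c(1:5, 11:15) + 0.1)
  groups <- rep(c("case", "control"), each = 5)
  expect_warning(pm <- fit_risk_score(expr, groups, "G"), "separation")
  expect_true(pm$separation)
  expect_equal(pm$auc, 1)
})

test_that("greedy combination follows the AUC ordering on constructed data", {
  set.seed(301)
  n0 <- 40; n1 <- 40
  is_case <- rep(c(FALSE, TRUE), c(n0, n1))
  make_marker <- function(delta) c(rnorm(n0, delta), rnorm(n1))  # lower in cases
  expr <- data.frame(sample_id = paste0("s", 1:(n0 + n1)),
                     weak = make_marker(0.4),
                     strong = make_marker(2.5),
                     mid = make_marker(1.2))
  groups <- ifelse(is_case, "case", "control")
  g <- greedy_combine(expr, groups)
  expect_equal(g$ranking$gene, c("strong", "mid", "weak"))
  expect_equal(g$panels[[1]]$markers, c("strong", "mid"))
  expect_equal(g$panels[[2]]$markers, c("strong", "mid", "weak"))
  expect_equal(vapply(g$panels, function(p) p$step, integer(1)), 1:2)
})

test_that("two candidates yield exactly one combined panel", {
  cohort <- simulate_cohort(table2_defaults(seed = 52))
  g <- suppressWarnings(greedy_combine(cohort, candidates = c("SIAE", "MAOB")))
  expect_length(g$panels, 1)
  expect_equal(nrow(g$ranking), 2)
})

test_that("greedy output is invariant to candidate input order", {
  cohort <- simulate_cohort(table2_defaults(seed = 15))
  cand <- c("MAOB", "NAB2", "COL3A1", "NPIPB4", "CYP27A1", "SIAE")
  g1 <- suppressWarnings(greedy_combine(cohort, candidates = cand))
  g2 <- suppressWarnings(greedy_combine(cohort, candidates = rev(cand)))
  expect_identical(g1$ranking, g2$ranking)
  expect_identical(lapply(g1$panels, `[[`, "markers"),
                   lapply(g2$panels, `[[`, "markers"))
  expect_equal(vapply(g1$panels, `[[`, numeric(1), "auc"),
               vapply(g2$panels, `[[`, numeric(1), "auc"))
})

test_that("greedy sequence matches an independent re-implementation", {
  for (seed in c(101, 202, 303)) {
    cohort <- simulate_cohort(table2_defaults(seed = seed))
    is_case <- cohort$metadata$group == "case"
    g <- suppressWarnings(greedy_combine(cohort))
    ref <- oracle_greedy(cohort$expression, is_case)
    expect_equal(g$ranking$gene, ref$ranking)
    for (k in seq_along(g$panels)) {
      expect_equal(g$panels[[k]]$markers, ref$steps[[k]]$markers)
      expect_equal(g$panels[[k]]$auc, ref$steps[[k]]$auc, tolerance = 1e-8)
    }
  }
})

test_that("panel AUC is invariant to affine rescaling of a marker", {
  set.seed(640)
  n <- 60
  expr <- data.frame(sample_id = paste0("s", 1:n),
                     A = rnorm(n, rep(c(2, 1), each = n / 2), 0.8),
                     B = rnorm(n, rep(c(3, 2), each = n / 2), 1.2))
  groups <- rep(c("control", "case"), each = n / 2)
  pm1 <- fit_risk_score(expr, groups, c("A", "B"))
  expr2 <- expr
  expr2$A <- 100 * expr2$A - 7
  pm2 <- fit_risk_score(expr2, groups, c("A", "B"))
  expect_equal(pm1$auc, pm2$auc, tolerance = 1e-9)
  expect_equal(pm1$coefficients[["A"]], 100 * pm2$coefficients[["A"]],
               tolerance = 1e-6)
})

test_that("in-sample AUC is nondecreasing with panel size under the true model", {
  set.seed(55)
  n <- 10000
  X <- matrix(rnorm(3 * n), ncol = 3)
  eta <- -0.2 + X %*% c(1.2, 0.8, 0.5)
  y <- rbinom(n, 1, plogis(eta))
  expr <- data.frame(sample_id = paste0("s", 1:n), X)
  names(expr)[2:4] <- c("m1", "m2", "m3")
  groups <- ifelse(y == 1, "case", "control")
  aucs <- vapply(1:3, function(k)
    fit_risk_score(expr, groups, paste0("m", 1:k))$auc, numeric(1))
  expect_true(all(diff(aucs) >= 0))
})

test_that("two-marker in-sample AUC approaches the closed-form binormal value", {
  set.seed(83)
  n <- 10000
  delta <- c(0.9, 0.6)  # independent unit-variance markers, shifted in cases
  is_case <- rep(c(FALSE, TRUE), each = n)
  expr <- data.frame(
    sample_id = paste0("s", 1:(2 * n)),
    A = rnorm(2 * n) + ifelse(is_case, delta[1], 0),
    B = rnorm(2 * n) + ifelse(is_case, delta[2], 0)
  )
  groups <- ifelse(is_case, "case", "control")
  pm <- fit_risk_score(expr, groups, c("A", "B"))
  # optimal combination of independent binormal markers: AUC = Phi(|delta|/sqrt(2))
  expect_lt(abs(pm$auc - pnorm(sqrt(sum(delta^2)) / sqrt(2))), 0.01)
})

test_that("evaluate_panels reports deterministic Table-3-shaped rows", {
  cohort <- simulate_cohort(table2_defaults(seed = 66))
  sets <- suppressWarnings(fit_marker_sets(
    cohort, sets = list(c("CYP27A1", "SIAE"), c("MAOB", "NAB2"))))
  t1 <- evaluate_panels(sets, B = 300, seed = 5)
  t2 <- evaluate_panels(sets, B = 300, seed = 5)
  expect_identical(t1, t2)
  expect_equal(t1$panel, c("CYP27A1 + SIAE", "MAOB + NAB2"))
  expect_true(all(t1$ci_low <= t1$auc & t1$auc <= t1$ci_high))
  perfect <- suppressWarnings(fit_risk_score(
    data.frame(sample_id = paste0("s", 1:10), G = c(1:5, 11:15)),
    rep(c("case", "control"), each = 5), "G"))
  expect_equal(evaluate_panels(perfect, B = 200)$auc, 1)
})

test_that("the frozen-score variant also walks the full inclusion sequence", {
  cohort <- simulate_cohort(table2_defaults(seed = 29))
  g <- suppressWarnings(greedy_combine(cohort, method = "frozen"))
  expect_length(g$panels, 5)
  expect_equal(length(g$panels[[5]]$markers), 6)
  expect_true(all(vapply(g$panels, function(p) p$auc, numeric(1)) > 0.5))
})
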