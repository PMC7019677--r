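# Pipeline-level tests run with a reduced bootstrap (B = 200) to keep the
# suite quick; the bootstrap itself is exercised in test-roc.R.

quiet_pipeline <- function(...) {
  suppressWarnings(suppressMessages(run_pipeline(..., verbose = FALSE)))
}

test_that("the default pipeline report has the full structural contract", {
  cohort <- simulate_cohort(table2_defaults(seed = 14))
  report <- quiet_pipeline(cohort, B = 200, seed = 4)
  expect_s3_class(report, "analysis_report")
  expect_equal(nrow(report$gene_summaries), 6)
  expect_gte(nrow(report$roc), 6)
  expect_length(report$greedy$panels, 5)
  expect_equal(nrow(report$panels), 5)
  expect_equal(nrow(report$calls), 67)
  expect_setequal(names(report$strata), c("age<60", "age>=60"))
  expect_true(nzchar(report$provenance$hash))
})

test_that("the same invocation twice gives an identical report", {
  cohort <- simulate_cohort(table2_defaults(seed = 25))
  r1 <- quiet_pipeline(cohort, B = 150, seed = 9)
  r2 <- quiet_pipeline(cohort, B = 150, seed = 9)
  expect_identical(r1, r2)
})

test_that("provenance hash changes iff inputs or parameters change", {
  cohort <- simulate_cohort(table2_defaults(seed = 25))
  r1 <- quiet_pipeline(cohort, B = 150, seed = 9)
  r2 <- quiet_pipeline(cohort, B = 150, seed = 9)
  expect_identical(r1$provenance$hash, r2$provenance$hash)
  r3 <- quiet_pipeline(cohort, B = 151, seed = 9)
  expect_false(identical(r1$provenance$hash, r3$provenance$hash))
  cohort2 <- simulate_cohort(table2_defaults(seed = 26))
  r4 <- quiet_pipeline(cohort2, B = 150, seed = 9)
  expect_false(identical(r1$provenance$hash, r4$provenance$hash))
})

test_that("a gene missing for all cases is excluded and the run completes", {
  cohort <- simulate_cohort(table2_defaults(seed = 33))
  cohort$expression$MAOB[cohort$metadata$group == "case"] <- NA
  expect_message(
    report <- suppressWarnings(run_pipeline(cohort, B = 150, seed = 2,
                                            stratify_by = NULL)),
    "excluding gene"
  )
  expect_false("MAOB" %in% report$gene_summaries$gene)
  expect_equal(nrow(report$gene_summaries), 5)
})

test_that("Ct input is quantified before analysis", {
  cohort <- simulate_cohort(table2_defaults(seed = 18))
  plate <- simulate_ct_plate(cohort, replicate_sd = 0)
  report <- quiet_pipeline(
    plate, metadata = cohort$metadata,
    calibrator = calibrator_fixed(attr(plate, "calibrator_delta_ct")),
    B = 150, seed = 3, stratify_by = NULL)
  direct <- quiet_pipeline(cohort, B = 150, seed = 3, stratify_by = NULL)
  expect_equal(report$gene_summaries$fold_change,
               direct$gene_summaries$fold_change, tolerance = 1e-9)
})

test_that("strata partition the cohort exactly", {
  cohort <- simulate_cohort(table2_defaults(seed = 47))
  report <- quiet_pipeline(cohort, B = 150, seed = 5)
  ids <- unlist(lapply(report$strata, function(s) s$calls$sample_id))
  expect_setequal(ids, cohort$expression$sample_id)
  expect_equal(sum(vapply(report$strata, `[[`, numeric(1), "n")), 67)
})

test_that("stratum cut-offs are recomputed from stratum controls", {
  cfg <- table2_defaults(n_control = 400, n_case = 400, seed = 58)
  cfg$genes$age_effect <- 0.02  # expression rises with age in both groups
  cohort <- suppressWarnings(simulate_cohort(cfg))
  strata <- suppressWarnings(suppressMessages(
    stratified_analysis(cohort, spec = stratum_spec("age", 60),
                        B = 150, seed = 5, verbose = FALSE)))
  young <- strata$`age<60`$gene_summaries
  old <- strata$`age>=60`$gene_summaries
  # positive age slope: older controls sit higher, so their cut-offs are higher
  expect_true(mean(old$cutoff - young$cutoff > 0) > 0.8)
})

test_that("with no age effect, stratum AUCs track the overall AUC at large n", {
  cfg <- table2_defaults(n_control = 3000, n_case = 3000, seed = 71)
  cohort <- simulate_cohort(cfg)
  overall <- auc(cohort$expression$SIAE, cohort$metadata$group, "low")
  strata <- suppressWarnings(suppressMessages(
    stratified_analysis(cohort, spec = stratum_spec("age", 60),
                        candidates = c("SIAE", "MAOB"),
                        B = 150, seed = 5, verbose = FALSE)))
  for (s in strata) {
    a <- s$roc$auc[s$roc$marker == "SIAE"]
    expect_lt(abs(a - overall), 0.03)
  }
})

test_that("a cutpoint outside the age range leaves one full analysis", {
  cohort <- simulate_cohort(table2_defaults(seed = 62))
  w <- capture_warnings(
    strata <- suppressMessages(
      stratified_analysis(cohort, spec = stratum_spec("age", 5),
                          B = 150, seed = 5, verbose = FALSE)))
  expect_true(any(grepl("empty", w)))
  expect_length(strata, 1)
  expect_equal(strata[[1]]$n, 67)
})

test_that("explicitly requested marker pairs are evaluated alongside the greedy path", {
  cohort <- simulate_cohort(table2_defaults(seed = 77))
  report <- quiet_pipeline(cohort, B = 150, seed = 6, stratify_by = NULL,
                           pairs = list(c("CYP27A1", "SIAE"),
                                        c("MAOB", "NAB2")))
  expect_equal(report$pair_panels$panel, c("CYP27A1 + SIAE", "MAOB + NAB2"))
  expect_true(all(report$pair_panels$auc >= 0 & report$pair_panels$auc <= 1))
})

test_that("reports are written as TSV/JSON files", {
  cohort <- simulate_cohort(table2_defaults(seed = 91))
  report <- quiet_pipeline(cohort, B = 150, seed = 7)
  dir <- withr::local_tempdir()
  write_report(report, dir)
  expect_true(file.exists(file.path(dir, "gene_summary.tsv")))
  expect_true(file.exists(file.path(dir, "roc.tsv")))
  expect_true(file.exists(file.path(dir, "panels.tsv")))
  expect_true(file.exists(file.path(dir, "provenance.json")))
  expect_true(file.exists(file.path(dir, "roc_age_lt_60.tsv")))
  expect_true(file.exists(file.path(dir, "roc_age_ge_60.tsv")))
  back <- read.delim(file.path(dir, "gene_summary.tsv"))
  expect_equal(back$gene, report$gene_summaries$gene)
})

test_that("schema violations are itemised errors", {
  cohort <- simulate_cohort(table2_defaults(seed = 2))
  md <- cohort$metadata
  md$group <- as.character(md$group)
  md$group[1] <- "mystery"
  expect_error(quiet_pipeline(cohort$expression, metadata = md, B = 150),
               "binary")
  expect_error(quiet_pipeline(cohort$expression, B = 150), "metadata")
})
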