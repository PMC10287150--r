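expected_test_names <- c(
  "evaluator_kw", "taxon_kw", "region_kw", "populations_kw", "populations_tau",
  "translocation_kw", "translocation_dunn", "status_mw", "lifehistory_mw",
  "taxon_translocation_fisher", "missing_tau", "priority_tau",
  "popsremaining_by_translocation_kw", "popsremaining_by_translocation_dunn")

test_that("fixture report contains every test, computed or skipped with reason", {
  report <- run_full_analysis(make_fixture_cohort())
  expect_named(report$tests, expected_test_names)
  for (nm in names(report$tests)) {
    t <- report$tests[[nm]]
    if (t$skipped) {
      expect_true(is.character(t$reason) && nzchar(t$reason), label = nm)
    } else {
      expect_true(inherits(t$result, "gr_test") || inherits(t$result, "gr_dunn"),
                  label = nm)
    }
    # dropped-record accounting
    expect_equal(t$n_effective + t$n_dropped, report$n, label = nm)
  }
  expect_equal(report$candidate_fraction, mean(fixture_expected_gr >= 2))
})

test_that("per-test complete cases drive the effective n", {
  fx <- make_fixture_cohort()
  report <- run_full_analysis(fx)
  expect_equal(report$tests$populations_kw$n_effective,
               sum(!is.na(fx$populations_remaining)))
  expect_equal(report$tests$lifehistory_mw$n_effective,
               sum(!is.na(fx$age_at_maturity_years)))
  expect_equal(report$tests$priority_tau$n_effective,
               sum(!is.na(fx$recovery_priority_number)))
})

test_that("degenerate grouping variables skip tests instead of failing", {
  fx <- make_fixture_cohort()
  fx$listing_status <- "Endangered"
  fx$evaluator_id <- NA_character_
  fx <- species_cohort(fx)
  report <- run_full_analysis(fx)
  expect_true(report$tests$status_mw$skipped)
  expect_true(report$tests$evaluator_kw$skipped)
  expect_match(report$tests$evaluator_kw$reason, "absent")
  # the rest of the battery still ran
  expect_false(report$tests$taxon_kw$skipped)
})

test_that("Dunn runs only under a significant parent Kruskal-Wallis", {
  co <- generate_cohort(cohort_config(n_species = 300, seed = 31,
                                      translocation_assoc = 2))
  report <- run_full_analysis(co)
  expect_lt(report$tests$translocation_kw$result$p_value, 0.05)
  expect_false(report$tests$translocation_dunn$skipped)
  expect_equal(nrow(report$tests$translocation_dunn$result), 3)

  co0 <- generate_cohort(cohort_config(n_species = 100, seed = 8,
                                       translocation_assoc = 0))
  report0 <- run_full_analysis(co0)
  if (report0$tests$translocation_kw$result$p_value >= 0.05) {
    expect_true(report0$tests$translocation_dunn$skipped)
    expect_match(report0$tests$translocation_dunn$reason, "not significant")
  }
})

test_that("candidate fraction is monotone non-increasing in the threshold", {
  co <- generate_cohort(cohort_config(n_species = 200, seed = 17))
  fractions <- vapply(-5:6, function(th) {
    run_full_analysis(co, analysis_config(threshold = th))$candidate_fraction
  }, numeric(1))
  expect_true(all(diff(fractions) <= 0))
  expect_equal(fractions[1], 1)
})

test_that("re-running the pipeline is bit-identical", {
  co <- generate_cohort(cohort_config(n_species = 150, seed = 23))
  cfg <- analysis_config(seed = 99)
  expect_identical(run_full_analysis(co, cfg), run_full_analysis(co, cfg))
})

test_that("render_report writes lossless JSON, a csv bundle, and markdown", {
  report <- run_full_analysis(generate_cohort(cohort_config(n_species = 80, seed = 4)))
  json <- withr::local_tempfile(fileext = ".json")
  render_report(report, "json", json)
  parsed <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  expect_equal(parsed$n, report$n)
  expect_equal(parsed$candidate_fraction, report$candidate_fraction)
  expect_named(parsed$tests, names(report$tests))
  for (nm in names(report$tests)) {
    t <- report$tests[[nm]]
    p <- parsed$tests[[nm]]
    expect_equal(p$skipped, t$skipped, label = nm)
    if (!t$skipped && inherits(t$result, "gr_test")) {
      expect_equal(p$result$statistic, t$result$statistic, label = nm)
      expect_equal(p$result$p_value, t$result$p_value, label = nm)
      expect_equal(p$result$method, t$result$method, label = nm)
    }
    expect_equal(p$n_effective, t$n_effective, label = nm)
  }

  bundle <- withr::local_tempdir()
  render_report(report, "csv_bundle", bundle)
  expect_true(all(file.exists(file.path(bundle,
    c("gr_distribution.csv", "gr_by_taxonomic_group.csv", "gr_by_lead_region.csv",
      "gr_by_translocation_status.csv", "species_results.csv", "tests.csv")))))
  tests_tab <- read.csv(file.path(bundle, "tests.csv"))
  expect_setequal(tests_tab$test, names(report$tests))

  md <- withr::local_tempfile(fileext = ".md")
  render_report(report, "markdown", md)
  lines <- readLines(md)
  for (nm in names(report$tests)) expect_true(any(lines == paste("##", nm)))

  expect_error(render_report(report, "xlsx", md))
})

test_that("a skip-heavy report still renders", {
  fx <- make_fixture_cohort()[1:3, ]
  fx$evaluator_id <- NA_character_
  report <- run_full_analysis(species_cohort(fx))
  json <- withr::local_tempfile(fileext = ".json")
  render_report(report, "json", json)
  parsed <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  expect_true(parsed$tests$evaluator_kw$skipped)
  md <- withr::local_tempfile(fileext = ".md")
  render_report(report, "markdown", md)
  expect_match(readLines(md), "Skipped", all = FALSE)
})

test_that("the CLI scores, simulates and analyzes end to end", {
  out_dir <- withr::local_tempdir()
  synth <- file.path(out_dir, "synth.csv")
  suppressMessages(gr_cli(c("simulate", "--seed", "42", "--n", "60", "--out", synth)))
  expect_true(file.exists(synth))
  co <- read_species_table(synth)
  expect_equal(nrow(co), 60)
  expect_identical(as.data.frame(co),
                   as.data.frame(generate_cohort(cohort_config(n_species = 60, seed = 42))))

  score_dir <- file.path(out_dir, "scores")
  suppressMessages(gr_cli(c("score", "--in", synth, "--out", score_dir)))
  results <- read.csv(file.path(score_dir, "gr_results.csv"))
  expect_equal(results$gr_index, compute_gr_index(co[question_columns()]))

  cfg_file <- file.path(out_dir, "cfg.yaml")
  writeLines(c("analysis:", "  threshold: 3"), cfg_file)
  report_file <- file.path(out_dir, "report.json")
  suppressMessages(gr_cli(c("analyze", "--in", synth, "--config", cfg_file,
                            "--seed", "17", "--out", report_file)))
  parsed <- jsonlite::fromJSON(report_file, simplifyVector = FALSE)
  expect_equal(parsed$threshold, 3)
  expect_named(parsed$tests, expected_test_names)

  expect_error(suppressMessages(gr_cli(c("analyze", "--in", synth))), "--in and --out")
  expect_error(suppressMessages(gr_cli("frobnicate")), "unknown subcommand")
  expect_error(suppressMessages(gr_cli(c("score", "--bogus", "x"))), "unknown option")
})
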