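#' Configuration for the full survey analysis
#'
#' @param threshold Candidacy threshold on the GR index (default 2).
#' @param lifehistory_cutoff_years Fast/slow dichotomization cutoff (default 4).
#' @param alpha Significance level gating the Dunn post-hoc tests (default
#'   0.05): Dunn runs only when the parent Kruskal-Wallis is significant.
#' @param mw_first_level Orientation of the Mann-Whitney `W` statistic: which
#'   factor level is "first". Default `"sorted"` uses the first level in
#'   sorted label order; any explicit level name is honoured.
#' @param fisher_method,fisher_n_reps Settings forwarded to
#'   [fisher_exact_rxc()].
#' @param seed Seed for any Monte-Carlo path (Fisher fallback).
#' @param catalogue Ordered populations catalogue.
#' @return Object of class `"analysis_config"`.
#' @export
analysis_config <- function(threshold = 2L, lifehistory_cutoff_years = 4,
                            alpha = 0.05, mw_first_level = "sorted",
                            fisher_method = "auto", fisher_n_reps = 100000,
                            seed = 1L,
                            catalogue = default_populations_catalogue()) {
  structure(list(threshold = as.integer(threshold),
                 lifehistory_cutoff_years = lifehistory_cutoff_years,
                 alpha = alpha, mw_first_level = mw_first_level,
                 fisher_method = fisher_method, fisher_n_reps = fisher_n_reps,
                 seed = as.integer(seed), catalogue = catalogue),
            class = "analysis_config")
}

# wrap one test: run `fun` on complete cases, or mark skipped with a reason
run_test <- function(fun, n_total, n_effective, min_levels_ok = TRUE,
                     skip_reason = NULL) {
  if (!is.null(skip_reason) || !min_levels_ok) {
    return(list(result = NULL, skipped = TRUE,
                reason = skip_reason %||% "fewer than 2 non-empty levels",
                n_effective = n_effective, n_dropped = n_total - n_effective))
  }
  res <- tryCatch(fun(), error = function(e) e)
  if (inherits(res, "error")) {
    return(list(result = NULL, skipped = TRUE, reason = conditionMessage(res),
                n_effective = n_effective, n_dropped = n_total - n_effective))
  }
  list(result = res, skipped = FALSE, reason = NULL,
       n_effective = n_effective, n_dropped = n_total - n_effective)
}

group_test <- function(values, groups, n_total, fun = kruskal_wallis) {
  keep <- !is.na(values) & !is.na(groups)
  g <- split(values[keep], as.character(groups[keep]))
  g <- g[order(names(g))]
  run_test(function() fun(g), n_total, sum(keep),
           min_levels_ok = length(g) >= 2)
}

pair_test <- function(x, y, n_total, fun) {
  keep <- !is.na(x) & !is.na(y)
  run_test(function() fun(x[keep], y[keep]), n_total, sum(keep))
}

#' Run the full survey analysis
#'
#' Scores a cohort and runs the complete nonparametric battery, dropping
#' records missing a test's variable per test (complete-case per analysis)
#' and logging the effective n of every test:
#' Kruskal-Wallis of GR index by evaluator, taxonomic group, Lead Region,
#' populations-remaining category and translocation status (each followed by
#' Dunn's Bonferroni post-hoc when significant at `alpha`); Mann-Whitney of
#' GR by listing status and by fast/slow life history; Fisher's exact r x c
#' of translocation status by taxonomic group; Kendall's tau-b of GR against
#' the populations ordinal, the missing-answer count, and the priority
#' category ordinal (High < Moderate < Low); and Kruskal-Wallis of the
#' populations ordinal by translocation status with its own Dunn follow-up.
#' A grouping variable with fewer than two non-empty levels marks that test
#' skipped (with a reason), never a pipeline failure.
#'
#' @param cohort A `species_cohort`.
#' @param config An [analysis_config()].
#' @return List of class `"gr_analysis_report"`: `gr_distribution`,
#'   `candidate_fraction`, `observed_gr_range`, `n`, `threshold`, and a
#'   `tests` list keyed by test name, each entry with `result`, `skipped`,
#'   `reason`, `n_effective`, `n_dropped`.
#' @examples
#' report <- run_full_analysis(make_fixture_cohort())
#' names(report$tests)
#' @export
run_full_analysis <- function(cohort, config = analysis_config()) {
  stopifnot(is.data.frame(cohort))
  n <- nrow(cohort)
  scored <- score_cohort(cohort, config$threshold)
  gr <- scored$results$gr_index
  nmiss <- scored$results$n_missing

  evaluator <- cohort$evaluator_id
  eval_absent <- is.null(evaluator) || all(is.na(evaluator))
  pops_ord <- populations_ordinal(cohort$populations_remaining, config$catalogue)
  lh <- life_history_class(cohort$age_at_maturity_years,
                           config$lifehistory_cutoff_years)
  prio <- priority_category(cohort$recovery_priority_number)

  mw_oriented <- function(values, groups) {
    keep <- !is.na(values) & !is.na(groups)
    g <- split(values[keep], as.character(groups[keep]))
    g <- g[order(names(g))]
    if (config$mw_first_level != "sorted" && config$mw_first_level %in% names(g)) {
      g <- g[c(config$mw_first_level, setdiff(names(g), config$mw_first_level))]
    }
    run_test(function() {
      res <- mann_whitney(g[[1]], g[[2]])
      res$group_labels <- names(g)
      res$sample_sizes <- vapply(g, length, 1L)
      res
    }, n, sum(keep), min_levels_ok = length(g) == 2)
  }

  dunn_if_significant <- function(parent, values, groups) {
    if (parent$skipped || parent$result$p_value >= config$alpha) {
      reason <- if (parent$skipped) "parent test skipped" else
        sprintf("parent Kruskal-Wallis not significant (p = %.3g >= %.3g)",
                parent$result$p_value, config$alpha)
      return(list(result = NULL, skipped = TRUE, reason = reason,
                  n_effective = parent$n_effective,
                  n_dropped = parent$n_dropped))
    }
    group_test(values, groups, n, fun = dunn_posthoc)
  }

  tests <- list()
  tests$evaluator_kw <- if (eval_absent) {
    list(result = NULL, skipped = TRUE, reason = "evaluator column absent",
         n_effective = 0L, n_dropped = n)
  } else group_test(gr, evaluator, n)
  tests$taxon_kw <- group_test(gr, cohort$taxonomic_group, n)
  tests$region_kw <- group_test(gr, cohort$lead_region, n)
  tests$populations_kw <- group_test(gr, cohort$populations_remaining, n)
  tests$populations_tau <- pair_test(gr, as.numeric(pops_ord), n, kendall_tau_b)
  tests$translocation_kw <- group_test(gr, cohort$translocation_status, n)
  tests$translocation_dunn <- dunn_if_significant(tests$translocation_kw,
                                                  gr, cohort$translocation_status)
  tests$status_mw <- mw_oriented(gr, cohort$listing_status)
  tests$lifehistory_mw <- mw_oriented(gr, lh)
  tests$taxon_translocation_fisher <- {
    keep <- !is.na(cohort$translocation_status) & !is.na(cohort$taxonomic_group)
    tab <- table(cohort$translocation_status[keep], cohort$taxonomic_group[keep])
    run_test(function() {
      suppressWarnings(fisher_exact_rxc(tab, method = config$fisher_method,
                                        n_reps = config$fisher_n_reps,
                                        seed = config$seed))
    }, n, sum(keep),
    min_levels_ok = sum(rowSums(tab) > 0) >= 2 && sum(colSums(tab) > 0) >= 2)
  }
  tests$missing_tau <- pair_test(gr, as.numeric(nmiss), n, kendall_tau_b)
  tests$priority_tau <- pair_test(gr, as.numeric(prio), n, kendall_tau_b)
  tests$popsremaining_by_translocation_kw <-
    group_test(as.numeric(pops_ord), cohort$translocation_status, n)
  tests$popsremaining_by_translocation_dunn <-
    dunn_if_significant(tests$popsremaining_by_translocation_kw,
                        as.numeric(pops_ord), cohort$translocation_status)

  structure(list(gr_distribution = scored$distribution,
                 results = scored$results,
                 candidate_fraction = scored$distribution$candidate_fraction,
                 observed_gr_range = scored$distribution$observed_range,
                 theoretical_gr_range = scored$distribution$theoretical_range,
                 n = n, threshold = config$threshold, alpha = config$alpha,
                 tests = tests),
            class = "gr_analysis_report")
}

#' @export
print.gr_analysis_report <- function(x, ...) {
  cat(sprintf("GR survey analysis report (n = %d)\n", x$n))
  cat(sprintf("  candidate fraction (GR >= %d): %.3f; observed GR %d..%d\n",
              x$threshold, x$candidate_fraction,
              x$observed_gr_range[1], x$observed_gr_range[2]))
  for (nm in names(x$tests)) {
    t <- x$tests[[nm]]
    if (t$skipped) {
      cat(sprintf("  %-36s skipped (%s)\n", nm, t$reason))
    } else if (inherits(t$result, "gr_test")) {
      cat(sprintf("  %-36s %s = %.4g, p = %.4g (n = %d)\n", nm,
                  t$result$statistic_name, t$result$statistic,
                  t$result$p_value, t$n_effective))
    } else {
      cat(sprintf("  %-36s %d pairwise comparisons (n = %d)\n", nm,
                  nrow(t$result), t$n_effective))
    }
  }
  invisible(x)
}
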