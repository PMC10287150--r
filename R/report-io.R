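test_to_list <- function(t) {
  out <- list(skipped = t$skipped, reason = t$reason,
              n_effective = t$n_effective, n_dropped = t$n_dropped)
  r <- t$result
  if (is.null(r)) return(out)
  if (inherits(r, "gr_dunn")) {
    out$comparisons <- lapply(seq_len(nrow(r)), function(i) as.list(r[i, ]))
  } else {
    keep <- setdiff(names(r), "table")
    out$result <- r[keep]
    if (!is.null(r$table)) {
      out$result$table <- list(counts = unname(apply(r$table, 1, as.list)),
                               rows = rownames(r$table), cols = colnames(r$table))
    }
  }
  out
}

#' Convert an analysis report to plain lists
#'
#' Lossless plain-list view of a [run_full_analysis()] report, suitable for
#' JSON serialization (statistics, p-values, methods, seeds, effective sample
#' sizes and skip reasons all preserved).
#'
#' @param report A `"gr_analysis_report"`.
#' @return Nested list.
#' @export
report_to_list <- function(report) {
  d <- report$gr_distribution
  list(n = report$n, threshold = report$threshold, alpha = report$alpha,
       candidate_fraction = report$candidate_fraction,
       observed_gr_range = report$observed_gr_range,
       theoretical_gr_range = report$theoretical_gr_range,
       gr_distribution = list(
         overall = d$overall,
         by_group = d$by_group),
       tests = lapply(report$tests, test_to_list))
}

#' Render an analysis report to files
#'
#' `"json"` writes one lossless JSON file. `"csv_bundle"` writes a directory
#' of tables: the overall GR distribution, the stratified distributions
#' (by taxonomic group, Lead Region and translocation status — tabular
#' stand-ins for the usual distribution figures), per-species results, and a
#' one-row-per-test summary. `"markdown"` writes a human-readable report with
#' one section per test.
#'
#' @param report A `"gr_analysis_report"`.
#' @param format One of `"json"`, `"csv_bundle"`, `"markdown"`.
#' @param path Output file (json/markdown) or directory (csv_bundle).
#' @return Invisibly, the paths written.
#' @export
render_report <- function(report, format = c("json", "csv_bundle", "markdown"),
                          path) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
    return(invisible(path))
  }
  if (format == "csv_bundle") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    d <- report$gr_distribution
    files <- c(overall = "gr_distribution.csv",
               taxonomic_group = "gr_by_taxonomic_group.csv",
               lead_region = "gr_by_lead_region.csv",
               translocation_status = "gr_by_translocation_status.csv")
    utils::write.csv(d$overall, file.path(path, files["overall"]), row.names = FALSE)
    for (g in names(d$by_group)) {
      utils::write.csv(d$by_group[[g]], file.path(path, files[g]), row.names = FALSE)
    }
    utils::write.csv(report$results, file.path(path, "species_results.csv"),
                     row.names = FALSE)
    rows <- lapply(names(report$tests), function(nm) {
      t <- report$tests[[nm]]
      r <- t$result
      is_single <- inherits(r, "gr_test")
      data.frame(test = nm,
                 skipped = t$skipped,
                 reason = if (is.null(t$reason)) NA_character_ else t$reason,
                 statistic_name = if (is_single) r$statistic_name else NA_character_,
                 statistic = if (is_single) r$statistic else NA_real_,
                 df = if (is_single && !is.null(r$df)) r$df else NA_integer_,
                 p_value = if (is_single) r$p_value else NA_real_,
                 method = if (is_single) r$method else NA_character_,
                 n_effective = t$n_effective, n_dropped = t$n_dropped,
                 stringsAsFactors = FALSE)
    })
    utils::write.csv(do.call(rbind, rows), file.path(path, "tests.csv"),
                     row.names = FALSE)
    dunns <- Filter(function(nm) inherits(report$tests[[nm]]$result, "gr_dunn"),
                    names(report$tests))
    for (nm in dunns) {
      utils::write.csv(report$tests[[nm]]$result, file.path(path, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
    return(invisible(path))
  }
  # markdown
  lines <- c("# GR survey analysis report", "",
             sprintf("- n = %d species; candidate threshold GR >= %d", report$n,
                     report$threshold),
             sprintf("- candidate fraction: %.3f", report$candidate_fraction),
             sprintf("- observed GR range: %d..%d (theoretical %d..%d)",
                     report$observed_gr_range[1], report$observed_gr_range[2],
                     report$theoretical_gr_range[1], report$theoretical_gr_range[2]),
             "")
  for (nm in names(report$tests)) {
    t <- report$tests[[nm]]
    lines <- c(lines, sprintf("## %s", nm), "")
    if (t$skipped) {
      lines <- c(lines, sprintf("Skipped: %s.", t$reason), "")
    } else if (inherits(t$result, "gr_test")) {
      r <- t$result
      lines <- c(lines,
                 sprintf("%s = %.6g%s, p = %.4g (%s; effective n = %d, dropped = %d)",
                         r$statistic_name, r$statistic,
                         if (!is.null(r$df)) sprintf(", df = %d", r$df) else "",
                         r$p_value, r$method, t$n_effective, t$n_dropped), "")
    } else {
      r <- t$result
      lines <- c(lines,
                 "| group_a | group_b | z | p_unadjusted | p_adjusted |",
                 "|---|---|---|---|---|",
                 sprintf("| %s | %s | %.4g | %.4g | %.4g |", r$group_a, r$group_b,
                         r$z, r$p_unadjusted, r$p_adjusted), "")
    }
  }
  writeLines(lines, path)
  invisible(path)
}
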