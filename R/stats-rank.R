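#' Mid-ranks with tie bookkeeping
#'
#' Ranks a numeric vector assigning tied values the mean of the ranks they
#' occupy, and records the size of every tie group (runs of equal values of
#' size >= 2). The tie sizes feed the `sum(t^3 - t)` correction used by all
#' rank tests in the package.
#'
#' @param values Finite numeric vector, length >= 1.
#' @return List of class `"ranked_sample"` with elements `values`, `midranks`,
#'   `tie_groups` (integer vector of tie sizes, possibly empty) and `N`.
#'   `sum(midranks)` always equals `N(N+1)/2`.
#' @examples
#' midranks(c(5, 5, 7))
#' @export
midranks <- function(values) {
  if (length(values) == 0) stop("empty input")
  if (any(!is.finite(values))) stop("values must be finite")
  ord <- order(values)
  sorted <- values[ord]
  # walk runs of equal values, assigning the mean occupied rank to each run
  r <- numeric(length(values))
  runs <- rle(sorted)$lengths
  stops <- cumsum(runs)
  starts <- stops - runs + 1L
  mean_ranks <- (starts + stops) / 2
  r[ord] <- rep(mean_ranks, runs)
  structure(list(values = values, midranks = r,
                 tie_groups = as.integer(runs[runs >= 2]),
                 N = length(values)),
            class = "ranked_sample")
}

# sum(t^3 - t) over tie groups of a pooled ranking
tie_term <- function(tie_groups) {
  if (length(tie_groups) == 0) return(0)
  sum(as.numeric(tie_groups)^3 - as.numeric(tie_groups))
}

# shared container for test results ------------------------------------------

new_test_result <- function(test_name, statistic_name, statistic, p_value,
                            df = NULL, method = "normal_approx",
                            group_labels = NULL, sample_sizes = NULL,
                            tie_correction_applied = FALSE,
                            n_reps = NULL, seed = NULL, extra = list()) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(c(list(test_name = test_name, statistic_name = statistic_name,
                   statistic = statistic, df = df, p_value = p_value,
                   method = method, group_labels = group_labels,
                   sample_sizes = sample_sizes,
                   tie_correction_applied = tie_correction_applied,
                   n_reps = n_reps, seed = seed), extra),
            class = "gr_test")
}

#' @export
print.gr_test <- function(x, ...) {
  cat(sprintf("%s\n  %s = %.6g", x$test_name, x$statistic_name, x$statistic))
  if (!is.null(x$df)) cat(sprintf(", df = %d", x$df))
  cat(sprintf(", p = %.4g  [%s%s]\n", x$p_value, x$method,
              if (isTRUE(x$tie_correction_applied)) ", tie-corrected" else ""))
  if (!is.null(x$group_labels)) {
    cat("  groups:", paste(sprintf("%s (n=%d)", x$group_labels, x$sample_sizes),
                           collapse = ", "), "\n")
  }
  invisible(x)
}
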