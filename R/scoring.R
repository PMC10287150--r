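#' Compute the GR suitability index
#'
#' The GR index is the plain integer sum of the nine question codes, with
#' missing answers contributing zero. Questions 1-4 contribute 0..+2 each
#' (maximum total +5: 2+1+1+1), questions 5-9 contribute 0 or -1 each
#' (minimum total -5), so the index is bounded in \[-5, 5\]. No floating
#' arithmetic is involved.
#'
#' @param responses A data frame with integer columns `q1` .. `q9` (one row
#'   per species), or a single named list/vector of the nine codes.
#' @param validate Check codes against the code book first (default). Turning
#'   this off computes the raw sum; it exists so the NA-as-zero arithmetic can
#'   be exercised with explicit zeros even for Q9, whose code book defines an
#'   NA state but no 0 state.
#' @return Integer vector of GR indices.
#' @examples
#' compute_gr_index(data.frame(q1 = 2L, q2 = 1L, q3 = 1L, q4 = 1L, q5 = 0L,
#'                             q6 = 0L, q7 = 0L, q8 = 0L, q9 = NA_integer_))
#' @export
compute_gr_index <- function(responses, validate = TRUE) {
  responses <- as.data.frame(as.list(responses))[question_columns()]
  if (validate) {
    problems <- validate_responses(responses)
    if (length(problems) > 0) stop("invalid responses:\n  ", paste(problems, collapse = "\n  "))
  }
  m <- as.matrix(responses)
  m[is.na(m)] <- 0L
  as.integer(rowSums(m))
}

#' Count missing survey answers
#'
#' Counts how many of the six NA-capable questions (Q1, Q2, Q3, Q6, Q8, Q9)
#' were answered "NA". Q4, Q5 and Q7 define no missing state and can never
#' contribute. Zero means complete information across all survey questions.
#'
#' @inheritParams compute_gr_index
#' @return Integer vector in 0..6.
#' @export
count_missing <- function(responses) {
  responses <- as.data.frame(as.list(responses))[question_columns()]
  as.integer(rowSums(is.na(as.matrix(responses[na_capable_questions()]))))
}

#' Classify candidate species
#'
#' A species is a worthwhile candidate for assisted migration for genetic
#' rescue when its GR index reaches the threshold (default 2). The threshold
#' is configurable because the index is advisory, not prescriptive.
#'
#' @param gr_index Integer vector.
#' @param threshold Candidacy threshold, default 2.
#' @return Logical vector: `gr_index >= threshold`.
#' @examples
#' classify_candidate(c(-1, 1, 2, 4))
#' @export
classify_candidate <- function(gr_index, threshold = 2L) {
  gr_index >= threshold
}

#' Score a cohort
#'
#' Computes per-species GR results (index, missing-question count, candidate
#' flag) and the GR distribution summary: counts by index value overall and
#' stratified by taxonomic group, Lead Region and translocation status, plus
#' the candidate fraction and observed versus theoretical index range.
#'
#' @param cohort A `species_cohort` data frame.
#' @param threshold Candidacy threshold passed to [classify_candidate()].
#' @return List of class `"gr_scored_cohort"` with elements `results` (data
#'   frame: `species_id`, `gr_index`, `n_missing`, `candidate`) and
#'   `distribution` (class `"gr_distribution"`).
#' @examples
#' scored <- score_cohort(make_fixture_cohort())
#' scored$distribution$candidate_fraction
#' @export
score_cohort <- function(cohort, threshold = 2L) {
  stopifnot(is.data.frame(cohort))
  if (nrow(cohort) == 0) {
    results <- data.frame(species_id = character(0), gr_index = integer(0),
                          n_missing = integer(0), candidate = logical(0))
    dist <- structure(list(overall = data.frame(gr_index = integer(0), count = integer(0)),
                           by_group = list(), candidate_fraction = NA_real_,
                           observed_range = c(NA_integer_, NA_integer_),
                           theoretical_range = c(-5L, 5L), n = 0L, threshold = threshold),
                      class = "gr_distribution")
    return(structure(list(results = results, distribution = dist),
                     class = "gr_scored_cohort"))
  }
  gr <- compute_gr_index(cohort[question_columns()])
  results <- data.frame(species_id = cohort$species_id,
                        gr_index = gr,
                        n_missing = count_missing(cohort[question_columns()]),
                        candidate = classify_candidate(gr, threshold),
                        stringsAsFactors = FALSE)
  tab <- function(strata = NULL) {
    if (is.null(strata)) {
      agg <- as.data.frame(table(gr_index = gr), stringsAsFactors = FALSE)
    } else {
      agg <- as.data.frame(table(gr_index = gr, stratum = as.character(strata)),
                           stringsAsFactors = FALSE)
    }
    agg$gr_index <- as.integer(agg$gr_index)
    names(agg)[names(agg) == "Freq"] <- "count"
    agg[agg$count > 0, , drop = FALSE]
  }
  dist <- structure(list(
    overall = tab(),
    by_group = list(taxonomic_group = tab(cohort$taxonomic_group),
                    lead_region = tab(cohort$lead_region),
                    translocation_status = tab(cohort$translocation_status)),
    candidate_fraction = mean(results$candidate),
    observed_range = range(gr),
    theoretical_range = c(-5L, 5L),
    n = nrow(cohort),
    threshold = as.integer(threshold)), class = "gr_distribution")
  structure(list(results = results, distribution = dist), class = "gr_scored_cohort")
}

#' @export
print.gr_distribution <- function(x, ...) {
  cat(sprintf("GR index distribution (n = %d)\n", x$n))
  cat(sprintf("  observed range %d..%d (theoretical -5..5)\n",
              x$observed_range[1], x$observed_range[2]))
  cat(sprintf("  candidate fraction (GR >= %d): %.3f\n", x$threshold,
              x$candidate_fraction))
  print(x$overall, row.names = FALSE)
  invisible(x)
}
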