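#' Survey question code book
#'
#' The GR (genetic rescue) suitability survey asks nine questions per species.
#' Questions 1-4 capture "small population problems" (inbreeding depression,
#' low genetic variation, small population sizes, availability of population
#' genetic surveys) and can only add to the index; questions 5-9 capture risk
#' factors for outbreeding depression and logistic barriers (ploidy variation,
#' adaptive differentiation, distinct ecoregions, disease, population-specific
#' behaviour) and can only subtract. Missing ("NA") answers are permitted only
#' where the code book defines an NA state: Q1, Q2, Q3, Q6, Q8 and Q9.
#'
#' @return A named list, one entry per question (`q1` .. `q9`), each with
#'   elements `allowed` (integer codes) and `na_ok` (logical).
#' @examples
#' question_codes()$q1
#' @export
question_codes <- function() {
  list(
    q1 = list(allowed = c(0L, 1L, 2L),  na_ok = TRUE),   # inbreeding signs=2, concern=1
    q2 = list(allowed = c(0L, 1L),      na_ok = TRUE),   # low genetic variation
    q3 = list(allowed = c(0L, 1L),      na_ok = TRUE),   # small population sizes
    q4 = list(allowed = c(0L, 1L),      na_ok = FALSE),  # genetic survey performed
    q5 = list(allowed = c(0L, -1L),     na_ok = FALSE),  # ploidy variation = -1
    q6 = list(allowed = c(0L, -1L),     na_ok = TRUE),   # adaptive differentiation
    q7 = list(allowed = c(0L, -1L),     na_ok = FALSE),  # distinct ecoregions
    q8 = list(allowed = c(0L, -1L),     na_ok = TRUE),   # disease concerns
    q9 = list(allowed = -1L,            na_ok = TRUE)    # behavioural concerns (no 0 state)
  )
}

#' @rdname question_codes
#' @export
question_columns <- function() paste0("q", 1:9)

#' @rdname question_codes
#' @export
na_capable_questions <- function() c("q1", "q2", "q3", "q6", "q8", "q9")

# Categorical vocabularies of the survey schema -------------------------------

#' Controlled vocabularies for species records
#'
#' Levels for the categorical fields of a species record: the five vertebrate
#' taxonomic groups surveyed, US FWS Lead Regions 1-8, ESA listing statuses,
#' translocation status coding, genetic-rescue-mention coding and genetic
#' marker types.
#'
#' @name vocabularies
#' @return Character (or integer) vector of allowed values.
#' @export
taxonomic_groups <- function() c("Amphibians", "Birds", "Fishes", "Mammals", "Reptiles")

#' @rdname vocabularies
#' @export
lead_regions <- function() 1:8

#' @rdname vocabularies
#' @export
listing_statuses <- function() c("Endangered", "Threatened")

#' @rdname vocabularies
#' @export
translocation_levels <- function() c("implemented", "considered", "not_mentioned")

#' @rdname vocabularies
#' @export
gr_mention_levels <- function() c("mentioned", "considered_concept", "absent")

#' @rdname vocabularies
#' @export
marker_types <- function() c("mtdna_nuclear", "microsatellite", "snp")

#' Default populations-remaining catalogue
#'
#' Ordered range labels for the "estimated number of element occurrences"
#' (populations remaining) variable. Only the two lowest labels are fixed by
#' the survey convention; the rest follow NatureServe-style rank breaks. The
#' catalogue is configurable everywhere it is consumed because it is a dialect
#' of the data source, not part of the scoring model.
#'
#' @return Character vector ordered from fewest to most populations.
#' @examples
#' default_populations_catalogue()
#' @export
default_populations_catalogue <- function() {
  c("1 to 5", "6 to 20", "21 to 80", "81 to 300", ">300")
}

#' Validate a block of question responses against the code book
#'
#' @param responses A data frame (or list coercible to one) with integer
#'   columns `q1` .. `q9`; `NA` marks a missing answer.
#' @return Character vector of violation messages, empty when valid. Each
#'   message names the offending row and question.
#' @examples
#' validate_responses(data.frame(q1 = 2L, q2 = 1L, q3 = 1L, q4 = 1L, q5 = 0L,
#'                               q6 = 0L, q7 = 0L, q8 = 0L, q9 = NA_integer_))
#' @export
validate_responses <- function(responses) {
  responses <- as.data.frame(responses)
  codes <- question_codes()
  missing_cols <- setdiff(question_columns(), names(responses))
  if (length(missing_cols) > 0) {
    return(sprintf("missing question column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  problems <- character(0)
  for (q in question_columns()) {
    v <- responses[[q]]
    if (!is.numeric(v)) {
      problems <- c(problems, sprintf("%s: non-numeric codes", q))
      next
    }
    bad_na <- if (codes[[q]]$na_ok) rep(FALSE, length(v)) else is.na(v)
    bad_code <- !is.na(v) & !(v %in% codes[[q]]$allowed)
    for (i in which(bad_na)) {
      problems <- c(problems, sprintf("row %d, %s: NA is not an allowed state", i, q))
    }
    for (i in which(bad_code)) {
      problems <- c(problems, sprintf("row %d, %s: code %s not in {%s}", i, q,
                                      format(v[i]), paste(codes[[q]]$allowed, collapse = ", ")))
    }
  }
  problems
}
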