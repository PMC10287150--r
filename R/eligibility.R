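#' Eligibility rules for the species survey
#'
#' The survey restricts itself to species for which assisted migration for
#' genetic rescue is at least conceivable. With all defaults on, a record is
#' excluded if it is absent from NatureServe, has fewer than 2 populations or
#' is likely extinct, is an island or entirely marine species, or has no
#' remaining US populations. The island/marine/extinct/US-range calls are
#' record-level flags supplied with the data (they were made manually by the
#' surveyors), not derived from geography here.
#'
#' @param min_populations_rank Minimum 0-based catalogue rank of
#'   `populations_remaining` a species must reach to stay in (default 0: every
#'   catalogue category, whose lowest label already spans >= 2 populations,
#'   passes; single-population records are flagged via the optional
#'   `single_population` column instead).
#' @param exclude_single_population,exclude_islands,exclude_marine,exclude_extinct,require_us_range,require_natureserve
#'   Logical switches for the individual rules; all `TRUE` by default.
#' @return An object of class `"eligibility_rules"`.
#' @export
eligibility_rules <- function(min_populations_rank = 0L,
                              exclude_single_population = TRUE,
                              exclude_islands = TRUE,
                              exclude_marine = TRUE,
                              exclude_extinct = TRUE,
                              require_us_range = TRUE,
                              require_natureserve = TRUE) {
  structure(list(min_populations_rank = as.integer(min_populations_rank),
                 exclude_single_population = isTRUE(exclude_single_population),
                 exclude_islands = isTRUE(exclude_islands),
                 exclude_marine = isTRUE(exclude_marine),
                 exclude_extinct = isTRUE(exclude_extinct),
                 require_us_range = isTRUE(require_us_range),
                 require_natureserve = isTRUE(require_natureserve)),
            class = "eligibility_rules")
}

#' Apply eligibility filters to a cohort
#'
#' Rules are checked in a fixed order (NatureServe presence, then fewer-than-2
#' populations / likely extinct, then island, marine, and US range) and each
#' excluded record is logged with the first rule it violated. Records missing
#' a flag needed by an active rule are kept and logged as `"unassessable"`.
#' Filtering is idempotent: re-filtering the kept records removes nothing.
#'
#' @param cohort A `species_cohort` data frame.
#' @param rules An [eligibility_rules()] object.
#' @return List with elements `kept` (the filtered cohort) and
#'   `exclusion_log` (data frame of `species_id`, `reason`).
#' @examples
#' cohort <- make_fixture_cohort()
#' res <- apply_eligibility_filters(cohort)
#' nrow(res$kept)
#' @export
apply_eligibility_filters <- function(cohort, rules = eligibility_rules()) {
  stopifnot(is.data.frame(cohort))
  n <- nrow(cohort)
  flag <- function(name, default) {
    if (name %in% names(cohort)) cohort[[name]] else rep(default, n)
  }
  on_ns   <- flag("on_natureserve", TRUE)
  single  <- flag("single_population", FALSE)
  checks <- list(
    not_on_natureserve = if (rules$require_natureserve) !on_ns,
    fewer_than_2_populations = if (rules$exclude_single_population) {
      pr <- populations_ordinal(cohort$populations_remaining,
                                attr(cohort, "catalogue") %||% default_populations_catalogue())
      single | (!is.na(pr) & pr < rules$min_populations_rank)
    },
    likely_extinct = if (rules$exclude_extinct) cohort$likely_extinct,
    island_species = if (rules$exclude_islands) cohort$island_species,
    marine_species = if (rules$exclude_marine) cohort$marine_species,
    not_in_us_range = if (rules$require_us_range) !cohort$in_us_range
  )
  checks <- Filter(Negate(is.null), checks)

  reason <- rep(NA_character_, n)
  unassessable <- rep(FALSE, n)
  for (rule in names(checks)) {
    hit <- checks[[rule]]
    unassessable <- unassessable | (is.na(hit) & is.na(reason))
    take <- is.na(reason) & !is.na(hit) & hit
    reason[take] <- rule
  }
  excluded <- !is.na(reason)
  log <- data.frame(species_id = character(0), reason = character(0),
                    stringsAsFactors = FALSE)
  if (any(excluded)) {
    log <- data.frame(species_id = cohort$species_id[excluded],
                      reason = reason[excluded], stringsAsFactors = FALSE)
  }
  if (any(unassessable & !excluded)) {
    log <- rbind(log, data.frame(species_id = cohort$species_id[unassessable & !excluded],
                                 reason = "unassessable", stringsAsFactors = FALSE))
  }
  kept <- cohort[!excluded, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, exclusion_log = log)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
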