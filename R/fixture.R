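#' Deterministic 12-record fixture cohort
#'
#' A small hand-built cohort used throughout the test-suite and examples.
#' Response vectors were chosen so the hand-summed GR indices span -2..5
#' (including both observed-style extremes and the all-missing zero case),
#' recovery priority numbers include the category boundaries 6/7 and 12/13,
#' all five taxonomic groups and both listing statuses appear, and ages at
#' maturity straddle the 4-yr life-history cutoff (including 3.9 and 4.0
#' exactly). The same cohort ships as plain CSV in
#' `inst/extdata/fixture_cohort.csv` for reader round-trip tests.
#'
#' @return A `species_cohort` with 12 rows.
#' @examples
#' compute_gr_index(make_fixture_cohort()[paste0("q", 1:9)])
#' @export
make_fixture_cohort <- function() {
  q <- function(...) as.integer(c(...))
  resp <- rbind(
    q(2,  1,  1, 1,  0,  0,  0,  0, NA),   # FIX-01: maximum positive sum, GR 5
    q(1,  1,  1, 1,  0, NA, -1, -1, NA),   # FIX-02: GR 2
    q(NA, NA, NA, 0, 0, NA,  0, NA, NA),   # FIX-03: all-missing zero, GR 0
    q(2,  1,  1, 1,  0, NA,  0, NA, -1),   # FIX-04: GR 4
    q(0,  1,  1, 1,  0,  0,  0,  0, NA),   # FIX-05: GR 3
    q(1, NA,  1, 1,  0,  0,  0,  0, NA),   # FIX-06: GR 3
    q(NA, NA, NA, 0, -1, -1, 0, NA, NA),   # FIX-07: risk-only, GR -2
    q(0,  0,  1, 0,  0, NA,  0, -1, NA),   # FIX-08: GR 0
    q(NA, 1,  1, 0,  0, NA, -1, NA, -1),   # FIX-09: GR 0
    q(NA, NA, 1, 0,  0, NA, -1, -1, NA),   # FIX-10: GR -1
    q(NA, 1,  1, 0,  0, NA,  0, NA, NA),   # FIX-11: GR 2
    q(NA, NA, 1, 0,  0, NA,  0, NA, NA))   # FIX-12: GR 1
  colnames(resp) <- question_columns()
  cohort <- data.frame(
    species_id = sprintf("FIX-%02d", 1:12),
    scientific_name = paste("Fictus", c("primus", "secundus", "tertius", "quartus",
                                        "quintus", "sextus", "septimus", "octavus",
                                        "nonus", "decimus", "undecimus", "duodecimus")),
    common_name = paste("Fixture species", 1:12),
    lead_region = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 4L, 2L, 6L, 1L),
    listing_status = c("Endangered", "Threatened", "Endangered", "Threatened",
                       "Endangered", "Endangered", "Threatened", "Endangered",
                       "Threatened", "Endangered", "Threatened", "Endangered"),
    taxonomic_group = c("Birds", "Fishes", "Mammals", "Birds", "Amphibians",
                        "Fishes", "Fishes", "Mammals", "Reptiles", "Fishes",
                        "Amphibians", "Reptiles"),
    populations_remaining = c("6 to 20", "1 to 5", "21 to 80", "1 to 5", "6 to 20",
                              "81 to 300", "1 to 5", ">300", "6 to 20", NA,
                              "21 to 80", "1 to 5"),
    age_at_maturity_years = c(2, 3.9, 4, 1, 0.5, 6, 4, 2.5, 8, 3, NA, 5),
    lifespan_years = c(12, 8, 20, 6, 4, 30, 15, 10, 40, 7, NA, 25),
    recovery_priority_number = c(6L, 7L, 12L, 13L, 1L, 18L, 3L, 9L, 15L, NA, 5L, 11L),
    translocation_status = c("implemented", "considered", "not_mentioned",
                             "implemented", "implemented", "considered",
                             "not_mentioned", "not_mentioned", "considered",
                             "not_mentioned", "implemented", "not_mentioned"),
    genetic_rescue_mentioned = c("mentioned", "absent", "absent", "mentioned",
                                 "considered_concept", "absent", "absent", "absent",
                                 "absent", "absent", "absent", "absent"),
    marker_types = c("microsatellite;snp", "microsatellite", NA, "snp",
                     "mtdna_nuclear", "microsatellite", NA, NA, NA, NA, NA, NA),
    evaluator_id = rep(c("EV1", "EV2", "EV3"), 4),
    stringsAsFactors = FALSE)
  cohort <- cbind(cohort, as.data.frame(resp))
  cohort$island_species <- FALSE
  cohort$marine_species <- FALSE
  cohort$likely_extinct <- FALSE
  cohort$in_us_range <- TRUE
  species_cohort(cohort)
}
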