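#' Canonical species-record columns
#'
#' @return Character vector of the canonical column names of a species cohort
#'   table, in writing order.
#' @keywords internal
cohort_columns <- function() {
  c("species_id", "scientific_name", "common_name", "lead_region",
    "listing_status", "taxonomic_group", "populations_remaining",
    "age_at_maturity_years", "lifespan_years", "recovery_priority_number",
    "translocation_status", "genetic_rescue_mentioned", "marker_types",
    "evaluator_id", question_columns(),
    "island_species", "marine_species", "likely_extinct", "in_us_range")
}

# optional flag columns honoured by eligibility filtering when present
optional_flag_columns <- function() c("on_natureserve", "single_population")

#' File dialect for species tables
#'
#' Describes how a delimited species table maps onto the canonical schema:
#' which header spells each canonical field, the missing-value token, and the
#' field separator. The default dialect is the identity mapping with token
#' `"NA"` and comma separation.
#'
#' @param column_map Named character vector mapping canonical field names to
#'   file headers. Fields absent from the map keep their canonical name.
#' @param na_token Missing-value token used in the file.
#' @param sep Field separator.
#' @return An object of class `"species_dialect"`.
#' @examples
#' species_dialect(column_map = c(species_id = "ID", lead_region = "Region"))
#' @export
species_dialect <- function(column_map = character(0), na_token = "NA", sep = ",") {
  stopifnot(is.character(na_token), length(na_token) == 1)
  if (length(column_map) > 0 && is.null(names(column_map))) {
    stop("column_map must be a named character vector (field = header)")
  }
  unknown <- setdiff(names(column_map), c(cohort_columns(), optional_flag_columns()))
  if (length(unknown) > 0) {
    stop("column_map names unknown field(s): ", paste(unknown, collapse = ", "))
  }
  structure(list(column_map = column_map, na_token = na_token, sep = sep),
            class = "species_dialect")
}

resolve_header <- function(field, dialect) {
  if (field %in% names(dialect$column_map)) unname(dialect$column_map[[field]]) else field
}

#' Validate a species cohort table
#'
#' Checks a data frame of species records against the survey schema: question
#' codes against the code book, categorical fields against their vocabularies,
#' `lead_region` in 1..8, `recovery_priority_number` in 1..18 when present, and
#' `populations_remaining` membership of the ordered catalogue. Listing status
#' must be a single enum value: dual DPS listings are assumed collapsed to one
#' record upstream and multi-valued statuses are rejected rather than guessed.
#'
#' @param x A data frame with the canonical columns (see [read_species_table()]).
#' @param catalogue Ordered populations-remaining catalogue.
#' @return `x`, with class `"species_cohort"` prepended and the catalogue
#'   stored in the `"catalogue"` attribute. Errors aggregate all violations.
#' @export
species_cohort <- function(x, catalogue = default_populations_catalogue()) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  missing_cols <- setdiff(cohort_columns(), names(x))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  problems <- validate_responses(x[question_columns()])

  check_enum <- function(field, levels) {
    v <- x[[field]]
    bad <- !is.na(v) & !(v %in% levels)
    sprintf("row %d, %s: value %s not in {%s}", which(bad),
            field, dQuote(v[bad], FALSE), paste(levels, collapse = ", "))
  }
  problems <- c(problems,
    check_enum("listing_status", listing_statuses()),
    check_enum("taxonomic_group", taxonomic_groups()),
    check_enum("translocation_status", translocation_levels()),
    check_enum("genetic_rescue_mentioned", gr_mention_levels()),
    check_enum("lead_region", lead_regions()),
    check_enum("populations_remaining", catalogue))
  rpn <- x$recovery_priority_number
  bad_rpn <- !is.na(rpn) & !(rpn %in% 1:18)
  problems <- c(problems, sprintf("row %d, recovery_priority_number: %s outside 1..18",
                                  which(bad_rpn), rpn[bad_rpn]))
  bad_status_na <- is.na(x$listing_status)
  problems <- c(problems,
                sprintf("row %d, listing_status: missing", which(bad_status_na)))
  for (field in c("age_at_maturity_years", "lifespan_years")) {
    v <- x[[field]]
    bad <- !is.na(v) & v < 0
    problems <- c(problems, sprintf("row %d, %s: negative value", which(bad), field))
  }
  mk <- as.character(x$marker_types)
  mk[is.na(mk)] <- ""
  bad_mk <- vapply(strsplit(mk, ";", fixed = TRUE),
                   function(parts) any(!parts %in% marker_types()), logical(1))
  problems <- c(problems, sprintf("row %d, marker_types: unknown marker", which(bad_mk)))

  if (length(problems) > 0) {
    stop("invalid species cohort:\n  ", paste(problems, collapse = "\n  "))
  }
  for (q in question_columns()) x[[q]] <- as.integer(x[[q]])
  x$lead_region <- as.integer(x$lead_region)
  x$recovery_priority_number <- as.integer(x$recovery_priority_number)
  for (f in c("species_id", "scientific_name", "common_name", "listing_status",
              "taxonomic_group", "populations_remaining", "translocation_status",
              "genetic_rescue_mentioned", "marker_types", "evaluator_id")) {
    x[[f]] <- as.character(x[[f]])
  }
  for (f in c("age_at_maturity_years", "lifespan_years")) x[[f]] <- as.numeric(x[[f]])
  for (f in intersect(c("island_species", "marine_species", "likely_extinct",
                        "in_us_range", optional_flag_columns()), names(x))) {
    x[[f]] <- as.logical(x[[f]])
  }
  attr(x, "catalogue") <- catalogue
  class(x) <- c("species_cohort", "data.frame")
  x
}

#' Read a species survey table
#'
#' Parses a delimited species table into a validated cohort. Headers are
#' mapped through the dialect; the dialect's missing token becomes `NA`. All
#' question codes are validated against the code book, and every violation is
#' collected into a load report naming row and field before the function
#' stops (or, with `on_error = "report"`, returns the valid rows with the
#' report attached as an attribute).
#'
#' @param source Path to the file, or a connection.
#' @param dialect A [species_dialect()].
#' @param catalogue Ordered populations-remaining catalogue.
#' @param on_error `"stop"` (default) aggregates row errors into one error;
#'   `"report"` drops offending rows and attaches the messages as the
#'   `"load_report"` attribute.
#' @return A `species_cohort` data frame, one row per species.
#' @examples
#' path <- system.file("extdata", "fixture_cohort.csv", package = "grindex")
#' cohort <- read_species_table(path)
#' nrow(cohort)
#' @export
read_species_table <- function(source, dialect = species_dialect(),
                               catalogue = default_populations_catalogue(),
                               on_error = c("stop", "report")) {
  on_error <- match.arg(on_error)
  raw <- utils::read.table(source, header = TRUE, sep = dialect$sep,
                           colClasses = "character", na.strings = dialect$na_token,
                           check.names = FALSE, quote = "\"",
                           stringsAsFactors = FALSE)
  opt_present <- Filter(function(f) resolve_header(f, dialect) %in% names(raw),
                        optional_flag_columns())
  wanted <- c(cohort_columns(), opt_present)
  headers <- vapply(wanted, function(f) resolve_header(f, dialect), character(1))
  absent <- wanted[!(headers %in% names(raw))]
  if (length(absent) > 0) {
    stop("configuration error: header(s) not found in file: ",
         paste(vapply(absent, function(f) resolve_header(f, dialect), character(1)),
               collapse = ", "))
  }
  out <- stats::setNames(raw[headers], wanted)

  numeric_fields <- c("lead_region", "age_at_maturity_years", "lifespan_years",
                      "recovery_priority_number", question_columns())
  parse_problems <- character(0)
  for (field in intersect(numeric_fields, names(out))) {
    v <- out[[field]]
    parsed <- suppressWarnings(as.numeric(v))
    bad <- !is.na(v) & is.na(parsed)
    parse_problems <- c(parse_problems,
                        sprintf("row %d, %s: unparseable value %s",
                                which(bad), field, dQuote(v[bad], FALSE)))
    out[[field]] <- parsed
  }
  logical_fields <- intersect(c("island_species", "marine_species", "likely_extinct",
                                "in_us_range", optional_flag_columns()), names(out))
  for (field in logical_fields) {
    v <- toupper(trimws(out[[field]]))
    parsed <- rep(NA, length(v))
    parsed[v %in% c("TRUE", "T", "1")] <- TRUE
    parsed[v %in% c("FALSE", "F", "0")] <- FALSE
    bad <- !is.na(out[[field]]) & is.na(parsed)
    parse_problems <- c(parse_problems,
                        sprintf("row %d, %s: unparseable flag %s",
                                which(bad), field, dQuote(out[[field]][bad], FALSE)))
    out[[field]] <- parsed
  }
  if (length(parse_problems) > 0 && on_error == "stop") {
    stop("invalid species table:\n  ", paste(parse_problems, collapse = "\n  "))
  }
  validation <- tryCatch({ species_cohort(out, catalogue); character(0) },
                         error = function(e) conditionMessage(e))
  if (length(validation) > 0 && on_error == "stop") stop(validation)
  if (on_error == "report") {
    # keep rows not named in any message
    msgs <- c(parse_problems, validation)
    bad_rows <- unique(as.integer(unlist(regmatches(msgs,
                 gregexpr("(?<=row )[0-9]+", msgs, perl = TRUE)))))
    keep <- setdiff(seq_len(nrow(out)), bad_rows)
    cohort <- species_cohort(out[keep, , drop = FALSE], catalogue)
    attr(cohort, "load_report") <- msgs
    return(cohort)
  }
  species_cohort(out, catalogue)
}

#' Write a species cohort table
#'
#' Emits the canonical delimited form of a cohort; missing values become the
#' dialect's token. `read_species_table(write_species_table(x))` reproduces
#' `x` field for field.
#'
#' @param cohort A `species_cohort` (or conforming data frame).
#' @param sink File path or connection.
#' @param dialect A [species_dialect()].
#' @return Invisibly, the path or connection written to.
#' @export
write_species_table <- function(cohort, sink, dialect = species_dialect()) {
  cols <- c(cohort_columns(), intersect(optional_flag_columns(), names(cohort)))
  out <- as.data.frame(cohort)[cols]
  names(out) <- vapply(cols, function(f) resolve_header(f, dialect), character(1))
  utils::write.table(out, sink, sep = dialect$sep, na = dialect$na_token,
                     row.names = FALSE, qmethod = "double", quote = TRUE)
  invisible(sink)
}
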