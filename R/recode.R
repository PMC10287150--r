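#' Recovery Priority category
#'
#' Collapses the US FWS Recovery Priority number (1 = highest priority, 18 =
#' lowest; the number combines degree of threat, recovery potential and
#' taxonomic uniqueness) into the three broad priority categories: numbers
#' 1-6 are High, 7-12 Moderate, 13-18 Low.
#'
#' @param recovery_priority_number Integer vector in 1..18 (`NA` allowed and
#'   propagated).
#' @return Ordered factor with levels `High < Moderate < Low`.
#' @examples
#' priority_category(c(5, 12, 18))
#' @export
priority_category <- function(recovery_priority_number) {
  n <- recovery_priority_number
  if (any(!is.na(n) & (n < 1 | n > 18 | n != floor(n)))) {
    stop("recovery_priority_number must be an integer in 1..18")
  }
  out <- character(length(n))
  out[!is.na(n) & n <= 6] <- "High"
  out[!is.na(n) & n >= 7 & n <= 12] <- "Moderate"
  out[!is.na(n) & n >= 13] <- "Low"
  out[is.na(n)] <- NA
  factor(out, levels = c("High", "Moderate", "Low"), ordered = TRUE)
}

#' Fast/slow life-history class
#'
#' Dichotomizes age at maturity at 4 years: species maturing strictly before
#' 4 yr are "fast", at 4 yr or older "slow". Missing ages give a missing
#' class (such records are dropped from the life-history comparison).
#'
#' @param age_at_maturity_years Non-negative numeric vector, `NA` allowed.
#' @param cutoff_years Dichotomization cutoff, default 4.
#' @return Factor with levels `fast`, `slow`.
#' @examples
#' life_history_class(c(3.9, 4, 0.5, NA))
#' @export
life_history_class <- function(age_at_maturity_years, cutoff_years = 4) {
  a <- age_at_maturity_years
  if (any(!is.na(a) & a < 0)) stop("age_at_maturity_years must be non-negative")
  factor(ifelse(is.na(a), NA, ifelse(a < cutoff_years, "fast", "slow")),
         levels = c("fast", "slow"))
}

#' Ordinal rank of a populations-remaining category
#'
#' Converts a populations-remaining range label (e.g. `"1 to 5"`, `"6 to 20"`)
#' into its 0-based rank in the ordered catalogue, for use as an ordinal
#' variable in rank correlations and rank tests.
#'
#' @param category Character vector of catalogue labels (`NA` propagated).
#' @param catalogue Ordered catalogue; see [default_populations_catalogue()].
#' @return Integer vector of 0-based ranks.
#' @examples
#' populations_ordinal(c("1 to 5", "6 to 20"))
#' @export
populations_ordinal <- function(category, catalogue = default_populations_catalogue()) {
  idx <- match(category, catalogue)
  bad <- !is.na(category) & is.na(idx)
  if (any(bad)) {
    stop("unknown populations category: ",
         paste(unique(category[bad]), collapse = ", "))
  }
  idx - 1L
}
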