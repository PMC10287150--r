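default_question_tables <- function() {
  # probability over each question's codes plus NA mass; NA mass is zero where
  # the code book defines no missing state. Calibrated so the synthetic
  # candidate fraction sits near two-thirds (the magnitude typical of real
  # surveys of this kind); a default, not a claim about any particular cohort.
  list(
    q1 = c("0" = 0.05, "1" = 0.15, "2" = 0.10, "NA" = 0.70),
    q2 = c("0" = 0.05, "1" = 0.55, "NA" = 0.40),
    q3 = c("0" = 0.05, "1" = 0.80, "NA" = 0.15),
    q4 = c("0" = 0.40, "1" = 0.60),
    q5 = c("0" = 0.95, "-1" = 0.05),
    q6 = c("0" = 0.10, "-1" = 0.05, "NA" = 0.85),
    q7 = c("0" = 0.90, "-1" = 0.10),
    q8 = c("0" = 0.05, "-1" = 0.15, "NA" = 0.80),
    q9 = c("-1" = 0.10, "NA" = 0.90)
  )
}

check_prob <- function(p, what, tol = 1e-12) {
  if (any(p < 0) || abs(sum(p) - 1) > tol) {
    stop("configuration error: ", what, " is not a probability vector")
  }
}

#' Configuration for synthetic cohort generation
#'
#' Describes the generative model of a synthetic species cohort: marginal
#' distributions for every survey field, and a single association knob
#' linking translocation status to the GR index. Responses are sampled first
#' and the GR index computed; translocation status is then drawn from a
#' multinomial logit whose "implemented" logit is shifted by
#' `assoc * (GR - E[GR])`, so `assoc = 0` gives exact independence and
#' positive values make translocation more frequent among high-GR species.
#'
#' @param n_species Number of records to generate.
#' @param seed Integer seed; identical config + seed gives a bit-identical
#'   cohort.
#' @param question_tables Named list `q1` .. `q9` of probability vectors over
#'   each question's codes (names are the codes, `"NA"` for missing). NA mass
#'   must be zero for Q4, Q5 and Q7.
#' @param group_weights,region_weights Probabilities over the five taxonomic
#'   groups and eight Lead Regions.
#' @param status_weights Probabilities over Endangered/Threatened.
#' @param translocation_baseline Baseline probabilities over
#'   implemented/considered/not_mentioned (defaults near the frequencies
#'   typical of recovery documentation: 0.44 / 0.20 / 0.36).
#' @param translocation_assoc Association coefficient on the logit scale
#'   (default 0.5, a moderate positive association).
#' @param populations_weights Probabilities over the populations catalogue
#'   plus a trailing `"NA"` mass.
#' @param maturity_shape,maturity_scale Gamma parameters for age at maturity
#'   in years (defaults span both sides of the 4-yr life-history cutoff).
#' @param catalogue Ordered populations catalogue.
#' @return Object of class `"cohort_config"`.
#' @examples
#' cfg <- cohort_config(n_species = 50, seed = 1)
#' @export
cohort_config <- function(n_species = 222,
                          seed = 1,
                          question_tables = default_question_tables(),
                          group_weights = c(Amphibians = 0.12, Birds = 0.20,
                                            Fishes = 0.43, Mammals = 0.14,
                                            Reptiles = 0.11),
                          region_weights = c(0.18, 0.17, 0.06, 0.32, 0.08,
                                             0.10, 0.02, 0.07),
                          status_weights = c(Endangered = 0.7, Threatened = 0.3),
                          translocation_baseline = c(implemented = 0.44,
                                                     considered = 0.20,
                                                     not_mentioned = 0.36),
                          translocation_assoc = 0.5,
                          populations_weights = c(0.28, 0.28, 0.20, 0.10, 0.06,
                                                  "NA" = 0.08),
                          maturity_shape = 2, maturity_scale = 1.75,
                          catalogue = default_populations_catalogue()) {
  if (n_species < 0 || n_species != floor(n_species)) stop("n_species must be a non-negative integer")
  codes <- question_codes()
  stopifnot(identical(sort(names(question_tables)), sort(question_columns())))
  for (q in question_columns()) {
    p <- question_tables[[q]]
    allowed <- c(as.character(codes[[q]]$allowed), if (codes[[q]]$na_ok) "NA")
    if (!all(names(p) %in% allowed)) {
      stop("configuration error: ", q, " table has codes outside {",
           paste(allowed, collapse = ", "), "}")
    }
    check_prob(p, paste0("question table ", q))
  }
  check_prob(group_weights, "group_weights")
  check_prob(region_weights, "region_weights")
  check_prob(status_weights, "status_weights")
  check_prob(translocation_baseline, "translocation_baseline")
  check_prob(populations_weights, "populations_weights")
  stopifnot(length(group_weights) == 5, length(region_weights) == 8,
            length(populations_weights) == length(catalogue) + 1)
  structure(list(n_species = as.integer(n_species), seed = as.integer(seed),
                 question_tables = question_tables,
                 group_weights = group_weights, region_weights = region_weights,
                 status_weights = status_weights,
                 translocation_baseline = translocation_baseline,
                 translocation_assoc = translocation_assoc,
                 populations_weights = populations_weights,
                 maturity_shape = maturity_shape, maturity_scale = maturity_scale,
                 catalogue = catalogue),
            class = "cohort_config")
}

# analytic expectation of the GR index under the question tables
expected_gr <- function(config) {
  sum(vapply(config$question_tables, function(p) {
    codes <- suppressWarnings(as.numeric(names(p)))
    sum(p[!is.na(codes)] * codes[!is.na(codes)])
  }, numeric(1)))
}

sample_codes <- function(p, n) {
  lab <- sample(names(p), n, replace = TRUE, prob = p)
  out <- suppressWarnings(as.integer(lab))   # "NA" label becomes NA
  out
}

#' Generate a synthetic species cohort
#'
#' Draws `n_species` records from a [cohort_config()]: survey responses from
#' the per-question tables, taxonomy/region/status labels from their weights,
#' populations category, age at maturity (gamma) and lifespan, evaluator
#' labels, and translocation status from the GR-linked multinomial logit.
#' Generated records always pass code-book validation and the read/write
#' round trip; eligibility flags are emitted as already-eligible (the
#' generator emulates a post-filtering survey cohort).
#'
#' @param config A [cohort_config()].
#' @return A `species_cohort` data frame with `n_species` rows.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_species = 20, seed = 7))
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_species
  local_seed(config$seed, {
    q <- lapply(config$question_tables, sample_codes, n = n)
    responses <- as.data.frame(q)[question_columns()]
    gr <- compute_gr_index(responses)

    base <- config$translocation_baseline[translocation_levels()]
    logits <- matrix(log(base), nrow = n, ncol = 3, byrow = TRUE)
    logits[, 1] <- logits[, 1] + config$translocation_assoc * (gr - expected_gr(config))
    pr <- exp(logits); pr <- pr / rowSums(pr)
    transloc <- vapply(seq_len(max(n, 0)), function(i) {
      sample(translocation_levels(), 1, prob = pr[i, ])
    }, character(1))

    pops_labels <- c(config$catalogue, NA)
    maturity <- round(stats::rgamma(n, shape = config$maturity_shape,
                                    scale = config$maturity_scale), 1)
    has_age <- stats::runif(n) < 0.9          # ~10% missing ages
    lifespan <- round(maturity * stats::runif(n, 2, 6), 1)
    surveyed <- !is.na(responses$q4) & responses$q4 == 1L
    markers <- vapply(seq_len(max(n, 0)), function(i) {
      if (!surveyed[i]) return(NA_character_)
      paste(sample(marker_types(), sample(1:2, 1)), collapse = ";")
    }, character(1))

    cohort <- data.frame(
      species_id = sprintf("SYN-%04d", seq_len(n)),
      scientific_name = sprintf("Genus species%04d", seq_len(n)),
      common_name = sprintf("Synthetic species %d", seq_len(n)),
      lead_region = sample(lead_regions(), n, replace = TRUE,
                           prob = config$region_weights),
      listing_status = sample(names(config$status_weights), n, replace = TRUE,
                              prob = config$status_weights),
      taxonomic_group = sample(names(config$group_weights), n, replace = TRUE,
                               prob = config$group_weights),
      populations_remaining = sample(pops_labels, n, replace = TRUE,
                                     prob = config$populations_weights),
      age_at_maturity_years = ifelse(has_age, maturity, NA_real_),
      lifespan_years = ifelse(has_age, lifespan, NA_real_),
      recovery_priority_number = sample(c(1:18, NA), n, replace = TRUE,
                                        prob = c(rep(0.95 / 18, 18), 0.05)),
      translocation_status = transloc,
      genetic_rescue_mentioned = sample(gr_mention_levels(), n, replace = TRUE,
                                        prob = c(0.03, 0.02, 0.95)),
      marker_types = markers,
      evaluator_id = sample(c("EV1", "EV2", "EV3"), n, replace = TRUE),
      stringsAsFactors = FALSE)
    cohort <- cbind(cohort, responses)
    cohort$island_species <- FALSE
    cohort$marine_species <- FALSE
    cohort$likely_extinct <- FALSE
    cohort$in_us_range <- TRUE
    species_cohort(cohort, config$catalogue)
  })
}

#' Empirical check of a generated cohort against its configuration
#'
#' Compares per-question empirical code frequencies (including NA mass) with
#' the configured probabilities, flagging any frequency further than
#' `tolerance` binomial standard errors from its target, and reports the
#' pipeline's own Kruskal-Wallis of GR index by translocation status so the
#' direction of an injected association can be inspected.
#'
#' @param cohort Cohort generated from `config`.
#' @param config The generating [cohort_config()].
#' @param tolerance Allowed deviation in standard errors (default 4).
#' @return List with `questions` (data frame: question, code, expected,
#'   observed, se, within_tolerance), `all_within_tolerance`, and
#'   `gr_by_translocation` (a `"gr_test"` or `NULL` when undefined).
#' @export
empirical_check <- function(cohort, config, tolerance = 4) {
  n <- nrow(cohort)
  rows <- list()
  for (q in question_columns()) {
    p <- config$question_tables[[q]]
    v <- cohort[[q]]
    for (code in names(p)) {
      obs <- if (code == "NA") mean(is.na(v)) else mean(!is.na(v) & v == as.integer(code))
      se <- sqrt(p[[code]] * (1 - p[[code]]) / n)
      rows[[length(rows) + 1]] <- data.frame(
        question = q, code = code, expected = p[[code]], observed = obs, se = se,
        within_tolerance = abs(obs - p[[code]]) <= tolerance * max(se, .Machine$double.eps),
        stringsAsFactors = FALSE)
    }
  }
  questions <- do.call(rbind, rows)
  gr <- compute_gr_index(cohort[question_columns()])
  groups <- split(gr, cohort$translocation_status)
  groups <- groups[vapply(groups, length, 1L) > 0]
  kw <- tryCatch(if (length(groups) >= 2) kruskal_wallis(groups) else NULL,
                 error = function(e) NULL)
  list(questions = questions,
       all_within_tolerance = all(questions$within_tolerance),
       gr_by_translocation = kw)
}
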