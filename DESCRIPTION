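Package: grindex
Title: Genetic Rescue Suitability Scoring and Nonparametric Survey Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Scores structured species-survey records with a nine-question
    genetic rescue (GR) suitability index, classifies candidate species for
    assisted migration, and runs the full tie-corrected nonparametric test
    battery used to analyse such surveys: Kruskal-Wallis with tie correction,
    Dunn's post-hoc test with Bonferroni adjustment, Mann-Whitney U,
    Kendall's tau-b, and exact or Monte-Carlo Fisher r x c tests. Includes a
    seeded synthetic-cohort generator emulating the survey schema (per-question
    categorical response distributions with missingness, taxonomic groups,
    US FWS Lead Regions, ordinal populations-remaining categories, and a
    configurable association between translocation status and GR index) so the
    whole pipeline is testable without external data, plus a command-line
    interface for scoring, simulation and full-report analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
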