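Package: evigrade
Title: Cumulative-Evidence Grading for Genetic Association Field Synopses
Version: 1.0.0
Authors@R: person("evigrade", "maintainers", email = "maintainers@evigrade.org",
    role = c("aut", "cre"))
Description: Assesses the cumulative epidemiological evidence of case-control
    genetic association results collected in field synopses (umbrella
    reviews).  From summary records of published meta-analyses and GWAS it
    recovers the log odds-ratio standard error from the reported confidence
    interval, computes the statistical power to detect a target odds ratio
    and the false-positive report probability (FPRP) at a stated prior,
    assigns Venice-criteria grades for amount of evidence, replication and
    protection from bias, and combines both methods into a
    strong/moderate/weak cumulative-evidence level per variant.  Includes
    fixed-effect meta-analysis statistics (inverse-variance pooling,
    Cochran's Q, I-squared, Egger regression), a seeded synthetic
    case-control meta-analysis generator for end-to-end testing, curated
    reference tables from a published esophageal-cancer synopsis, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
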