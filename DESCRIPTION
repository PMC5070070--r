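Package: mapblood
Title: Blood Transcriptome Biomarker Discovery for Methamphetamine-Associated Psychosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative analysis pipeline for peripheral-blood RNA-seq
    biomarker discovery in methamphetamine-associated psychosis (MAP). Provides
    signed weighted gene co-expression network construction with topological
    overlap clustering and eigengene summaries, Bayes-regularized ANOVA of
    module eigengenes and brain-structure volumes, moderated t-tests with
    confounder-module exclusion, diagnostic panel construction by recursive
    feature elimination with diagonal linear discriminant analysis under
    leave-one-out cross-validation and permutation testing, and a Convergent
    Functional Genomics (CFG) scoring scheme that combines internal
    differential-expression evidence with capped external literature evidence.
    A synthetic-cohort generator with planted modules, group effects, coupled
    phenotypes, a polysubstance confounder module and a matched evidence
    database supports end-to-end recovery and calibration testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
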