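Package: ventqc
Title: Ventilation Quality Classification and Case-Control Analysis for
    Simulated CPR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing bag-mask ventilation quality in simulated
    cardiopulmonary resuscitation (CPR) training studies. Classifies
    individual ventilations into green/amber/red quality bands by
    insufflated volume and insufflation time, computes composite
    compression, ventilation and CPR quality scores, runs
    normality-routed repeated-measures comparisons (repeated-measures
    ANOVA or Friedman with Bonferroni-corrected pairwise tests and
    Cohen's d or Rosenthal's r effect sizes), and performs case-control
    contingency analysis across training-exposure levels with Pearson
    chi-square, Cramer's V effect sizes and odds ratios. Includes a
    discrete-event simulator of two-minute 30:2 CPR sessions with five
    initial rescue breaths, so the full pipeline can be exercised
    without access to manikin recordings.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
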