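Package: circabehave
Title: Circadian Locomotor Activity and Immobility-Defined Sleep Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for rodent circadian behavior: chi-square
    periodogram rhythm detection with free-running period (tau) and rhythm
    power, actogram-derived circadian metrics (nocturnality, activity amount,
    alpha, onset precision, bout fragmentation), photic phase-shift estimation
    from activity-onset regressions, immobility-defined sleep scoring from
    video mobility traces with bout and threshold-sensitivity analyses, the
    group statistics used to compare genotypes (one-way ANOVA, ANOVA on ranks,
    Bonferroni post hoc), and synthetic actogram and mobility-trace generators
    with known ground truth for validating every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, graphics, utils, car
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
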