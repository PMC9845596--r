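Package: simscore
Title: Continuous Quantification of Metabolic Syndrome with the siMS Score
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Computes the siMS score, a continuous composite quantifying
    metabolic syndrome severity from waist-to-height ratio, fasting glucose,
    triglycerides, systolic blood pressure and sex-specific HDL cholesterol,
    together with companion indices (HOMA-IR, fatty liver index, BMI, mean
    OGTT insulin). Applies IDF component criteria with the mandatory central
    obesity rule to label subjects as metabolic syndrome, pre-metabolic
    syndrome or no criteria, and categorises glycoregulation from a
    three-point OGTT (normal, IFG, IGT, newly detected diabetes). Ships a
    seeded Gaussian-copula synthetic cohort generator whose default marginals
    transcribe a published obese-cohort summary table, and an analysis stage
    producing baseline-characteristics group comparisons (t, Mann-Whitney,
    chi-square, Fisher) and correlation screens (Pearson, Spearman) of the
    siMS score against insulin-resistance, liver, inflammation and
    endothelial markers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
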