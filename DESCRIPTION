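Package: periorisk
Title: Fuzzy-Logic Periodontitis Risk Scoring from Routine Diabetes Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Two-level Mamdani fuzzy inference system that converts four
    routine type 2 diabetes biomarkers (body mass index, fasting glucose,
    total cholesterol, triglycerides) into a cumulative periodontitis risk
    score (PCRisk) on a 1-10 scale. A first level scores BMI + glycemia and
    cholesterol + triglycerides separately; a second level combines the two
    intermediate risks. Includes a generic triangular-partition fuzzy engine
    (min/max inference, centroid defuzzification), the configured clinical
    rule bases, a simple-regression validation stage relating PCRisk to
    periodontal pocket counts, a seeded synthetic-cohort generator for
    end-to-end testing, and a command-line interface for batch scoring.
License: MIT
Encoding: UTF-8
Imports:
    optparse,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
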