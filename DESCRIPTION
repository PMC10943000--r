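Package: hdpheno
Title: Rule-Based Phenotyping of Hypertensive Disorders of Pregnancy in Cohort Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies pregnant subjects from longitudinal prenatal-care
    records into subtypes of hypertensive disorders of pregnancy (HDP):
    gestational hypertension, preeclampsia and superimposed preeclampsia
    (each split into early- and late-onset), chronic hypertension, and
    normotensive.  Two configurable rule engines are provided, one following
    American (ACOG) clinical concepts and one following Japanese (JSOG)
    concepts that additionally recognise maternal organ dysfunction and
    light-for-date birth weight.  Includes dictionary-driven pattern matching
    over free-text clinical notes with negation handling, study-inclusion
    filtering, validation of phenotyped labels against reference-standard
    diagnoses (PPV, NPV, accuracy, sensitivity, specificity), and a
    synthetic pregnancy-cohort simulator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    stringi,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
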