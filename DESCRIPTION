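Package: resptyper
Title: Response-Type Fingerprinting of Likert Questionnaires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters Likert-scale questionnaires on the drivers of global
    biodiversity loss into response types and summarises groups of respondents
    (countries) as fingerprint vectors of type proportions. Implements
    co-observed-feature KNN imputation, feature engineering with a
    main-versus-minor-driver discrimination score, Ward agglomerative
    clustering with gap-statistic selection of the number of types, country
    fingerprints and Ward dendrograms of countries, and a Spearman rank
    correlation screen of fingerprint components against country-level
    indices. A synthetic-data module generates questionnaire populations with
    the mixture structure the analysis assumes, so every stage can be tested
    at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
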