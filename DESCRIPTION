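Package: iefs
Title: Iterative Ensemble Feature Selection for Imbalanced Multiclass Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-signature selection and one-versus-all ensemble classification
    for imbalanced multiclass gene-expression matrices. Implements an iterative
    framework that alternates balanced sampling (random undersampling or SMOTE
    oversampling) with filter feature selection (mutual-information ranking, the
    fast correlation-based filter with symmetric uncertainty, and
    minimum-redundancy maximum-relevance selection), trains one binary classifier
    per class, and predicts by majority vote. Includes stratified cross-validation
    with accuracy and macro one-vs-rest AUC, a benchmark grid over signature
    sizes, readers and writers for delimited and GCT 1.2 expression matrices, and
    a seeded synthetic-data generator with planted class-informative genes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    tools,
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
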