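Package: metamatchr
Title: Multilayer Meta-Matching for Cross-Dataset Phenotype Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Translates phenotypic prediction models trained on multiple
    unequally sized source datasets of resting-state functional connectivity
    to predict new phenotypes in a small target dataset. Implements
    correlation-kernel kernel ridge regression, linear ridge regression and
    multi-output feedforward-network base learners with masked losses,
    meta-matching with stacking, meta-matching with dataset stacking, and
    multilayer meta-matching, alongside a classical transfer-learning
    baseline, a K-shot evaluation protocol with paired bootstrap comparisons
    and FDR correction, Haufe-transform feature importance, and a latent-factor
    simulator of multi-dataset connectome-phenotype collections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr
Config/testthat/edition: 3
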