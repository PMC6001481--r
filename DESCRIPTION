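Package: dualpathL2
Title: Dual-Path Connectionist Simulations of Second-Language Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Implements a dual-path sentence-production network (a simple
    recurrent sequencing pathway coupled to a role-concept meaning pathway
    bound by fast message weights) together with miniature Korean and
    English message-sentence grammars, forward conditional-probability
    corpus statistics, age-dependent learning-rate schedules, and an
    evaluation suite (word-prediction accuracy, SSE-based grammaticality
    rule proportions, code-switching rates). Supports simulations of
    second-language acquisition across ages of acquisition, including
    sensitive-period schedules with separate lexical and syntactic
    learning rates and bilingual (interleaved Korean/English) input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lme4,
    Rcpp,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
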