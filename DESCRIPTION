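Package: raterkappa
Title: Two-Rater Agreement with Cohen's and Power-Weighted Kappa
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes chance-corrected agreement between two raters from
    square contingency tables or paired categorical ratings: Cohen's kappa
    and the power-weighted kappa family (linear and quadratic weighted
    kappa), with asymptotic (Fleiss-Cohen-Everitt) and bootstrap confidence
    intervals, Wald tests of zero agreement, qualitative interpretation on
    the Landis-Koch scale, and guidance on which statistic suits a given
    measurement scale. Includes a multinomial paired-ratings simulator with
    closed-form population kappas, a demonstration of the kappa prevalence
    paradox, bundled RECIST response-assessment confusion matrices, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils, graphics, grDevices, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
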