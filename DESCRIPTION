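Package: phosol
Title: Condensate-Specific Phosphorylation Analysis from Proteome Solubility Profiling
Version: 0.1.0
Authors@R: person("Maintainer", "Packaged", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for discovering biomolecular-condensate-specific
    protein phosphorylation from differential-detergent solubility proteomics.
    Implements calibration-subset variance-stabilizing normalization, solubility
    and RNA-bound-fraction computation, empirical-Bayes moderated differential
    testing, phosphopeptide quality control and pattern collapsing, rule-based
    phosphosite category assignment, windowed sequence physicochemistry
    (hydropathy, FCR, NCPR, kappa charge patterning, charge-hydropathy disorder
    classification), hypergeometric over-representation and phosphosite-activity
    inference, pulldown ratio correction, and condensate image quantification
    (partition coefficients, nuclear coefficient of variation). A synthetic-data
    module with planted ground truth makes the whole pipeline testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
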