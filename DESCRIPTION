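Package: dumpharm
Title: Quantification of Pharmacological Responses in DUM Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Seeded synthetic-data generators and analysis routines for a
    multi-approach neuropharmacology workflow on cockroach dorsal unpaired
    median (DUM) neurons: quantification of drug-induced hyperpolarization in
    intracellular voltage recordings via the relative size of hyperpolarization
    (RSH) area statistic, reduction of Ellman/Bradford microplate absorbances
    to specific acetylcholinesterase activities with log-logistic
    dose-inhibition (ED50) fitting, mean-gray-value quantification of
    calcium-indicator fluorescence in single-cell images, and the group
    statistics (one-way ANOVA, Tukey HSD with compact letter display) used to
    compare treatment arms.
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
    tiff,
    minpack.lm,
    EBImage,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
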