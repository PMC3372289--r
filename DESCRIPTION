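Package: tfstab
Title: Environment Stability and the Transcription-Factor Repertoire of
    Marine Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how the stability of the physico-chemical environment
    shapes the transcription-factor (TF) gene repertoire of marine microbial
    communities sampled by shotgun metagenomics. Interpolates gridded monthly
    ocean climatologies at sampling sites by inverse-distance weighting,
    derives per-site environment-stability measures (standard deviation of the
    twelve monthly values), parses HMMER3 per-domain tables and applies
    significance filtering, normalizes TF domain counts to genome equivalents
    using single-copy genes, and partitions TF-content variation between
    environment stability and space with redundancy analysis, permutation
    tests and forward/backward model selection, plus per-TF stepwise multiple
    linear regression. Includes a synthetic-data generator with known planted
    effect fractions so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
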