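Package: symcat
Title: Symmetry and Parity of Category Systems Across Languages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the symmetry of semantic category systems
    across languages. Represents domain structures as finite spaces acted on
    by transformation groups, enumerates connected category systems and
    classifies each structure's parity (odd, even, or both) by exhaustive
    search; derives category-system sizes from kin-term extension tables;
    curates cross-linguistic survey records (glottocode deduplication,
    largest-system-per-language, colour-naming consensus counts); estimates
    each domain's preference for even-sized systems with an intercept-only
    hierarchical Bayesian logistic model with family and language random
    intercepts (plus a frequentist analogue); and generates synthetic
    cross-linguistic surveys with the statistical structure the analyses
    assume, so the full pipeline runs without any field-data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    rjags
Config/testthat/edition: 3
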