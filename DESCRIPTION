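Package: formularyimpact
Title: Bounded-Range Impact Modeling of Pharmacy Formulary Exclusions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A deterministic burden-of-impact model for pharmacy formulary
    exclusions. Given a population coverage model, an indication prevalence
    interval, formulary and medication market shares, and literature-derived
    outcome rates, the package propagates coupled low/high scenario bounds
    through a multiplicative cascade to estimate how many patients would be
    affected by excluding a specific medication, how many would discontinue
    therapy, and how many would have adverse events. Includes packaged case
    studies (anticoagulants, migraine preventives, antipsoriatics) with
    printed reference tables and an erratum registry, golden-table
    comparison, factor-attribution sensitivity statistics, a seeded
    synthetic-scenario generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
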