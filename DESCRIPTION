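Package: pharmsub
Title: Scoring and Ranking of Substitutes for Medicinal Products in Shortage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for formulary decision support during medicine shortages.
    Each medicinal product is encoded as its WHO ATC code, five EDQM
    Standard Terms describing the dosage form (basic dose form,
    administration method, intended site, release characteristic,
    transformation), and the number of Defined Daily Doses per presentation
    unit (NDXUP). Given a product in shortage, marketed products sharing the
    same ATC code are scored with a degree of substitutability (DS) built
    from a penalty schedule on NDXUP differences and weighted normalized
    distances on the Standard-Term relative-position scales, and returned as
    a ranked list of pharmaceutical equivalents and alternatives. Includes
    fixed-combination NDXUP arithmetic and fictitious ATC coding, catalog
    and shortage-list file handling, internal-validation performance
    indicators, a synthetic-catalog generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
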