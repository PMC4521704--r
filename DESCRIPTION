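Package: lpsmap
Title: Mapping Extensive and Intensive Chicken and Pig Production Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the national proportion of extensively raised chickens and
    pigs as bounded logistic functions of log10 GDP per capita (purchasing
    power parity), quantifies uncertainty with a stock-weighted bootstrap, and
    disaggregates national or provincial livestock totals into gridded
    extensive, semi-intensive and intensive density maps by allocating
    extensive stock over the rural population under a biophysical suitability
    mask, with exact conservation of unit totals. Includes a synthetic-world
    generator so the whole pipeline can be exercised and validated without
    external global datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
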