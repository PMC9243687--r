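Package: mnmtool
Title: Maternal Near-Miss Surveillance with Multiple Criteria Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for facility-level maternal near-miss surveillance.
    Implements a declarative clinical rule engine for the WHO 2011
    near-miss tool and six alternative severe-maternal-morbidity criteria
    sets (Mantel 1998, Waterstone 2001, Roberts 2008, Indian national
    consensus 2014, Global Network 2016, CDC 2017), the WHO
    potentially-life-threatening-condition screen, the four WHO process
    indicators (maternal near-miss ratio, severe maternal outcome ratio,
    mortality index, near-miss to death ratio), case-fatality tables, a
    transfusion-threshold sensitivity analysis, and a seeded synthetic
    cohort generator calibrated to published marginal frequencies so the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
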